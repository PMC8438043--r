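# Independent brute-force oracles, kept deliberately naive and separate
# from the package's implementation paths.

# Pearson correlation straight from the definition
brute_pearson <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  den <- sqrt(sum(am^2) * sum(bm^2))
  if (den == 0) return(0)
  sum(am * bm) / den
}

# correlation-sum score components from the definition: full pairwise
# correlation table, best = argmax of row sums (first on ties), class sums
# excluding the best
brute_scores <- function(frag, ms1, ann, lo, hi, thr = 0.75) {
  W <- frag[lo:hi, , drop = FALSE]
  k <- ncol(W)
  C <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) C[i, j] <- brute_pearson(W[, i], W[, j])
    }
  }
  best <- which.max(rowSums(C))
  r <- C[best, ]
  r[best] <- NA
  mod <- ann$contains_mod_site
  oth <- ann$contains_other_candidate_site
  list(best = best, components = c(
    S_site_determining = sum(r[mod & !oth], na.rm = TRUE),
    S_site_containing = sum(r[mod & oth], na.rm = TRUE),
    S_other_site = sum(r[!mod & oth], na.rm = TRUE),
    S_shared = sum(r[!mod & !oth], na.rm = TRUE),
    ms1_corr = brute_pearson(ms1[lo:hi], W[, best]),
    n_corr_gt = sum(r > thr, na.rm = TRUE)))
}

# enumerate every subset of candidate variable mods directly
brute_form_count <- function(sequence, start = 1,
                             variable_mods = c("KGG", "OxM", "NtAc"),
                             max_variable = 2) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cand <- 0
  if ("KGG" %in% variable_mods) cand <- cand + sum(aa == "K" &
                                                     seq_len(n) < n)
  if ("OxM" %in% variable_mods) cand <- cand + sum(aa == "M")
  if ("NtAc" %in% variable_mods && start <= 2) cand <- cand + 1
  sum(choose(cand, 0:min(max_variable, cand)))
}

# minimal set cover size by exhaustive subset enumeration
brute_min_cover_size <- function(sets, universe) {
  n <- length(sets)
  for (size in seq_len(n)) {
    for (sel in utils::combn(n, size, simplify = FALSE)) {
      if (all(universe %in% unlist(sets[sel]))) return(size)
    }
  }
  n
}

# textbook Benjamini-Hochberg
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# target-decoy q-values straight from the definition: for every entry,
# minimum over all thresholds at or below its score of D(t)/max(1, T(t))
brute_qvalues <- function(score, decoy) {
  vapply(seq_along(score), function(i) {
    ts <- sort(unique(score[score <= score[i]]))
    min(vapply(ts, function(t) {
      min(sum(decoy & score >= t) / max(1, sum(!decoy & score >= t)), 1)
    }, numeric(1)))
  }, numeric(1))
}

# random chromatogram set with plausible annotation flags
random_chromset <- function(seed, n_points = 20, n_frag = 6) {
  set.seed(seed)
  frag <- matrix(stats::rlnorm(n_points * n_frag, 2, 1), n_points, n_frag)
  ann <- data.frame(
    frag_id = sprintf("f%d", seq_len(n_frag)),
    contains_mod_site = sample(c(TRUE, FALSE), n_frag, replace = TRUE),
    contains_other_candidate_site = sample(c(TRUE, FALSE), n_frag,
                                           replace = TRUE))
  list(frag = frag, ms1 = stats::rlnorm(n_points, 2, 1), ann = ann)
}

# small zero-noise benchmark configuration for end-to-end identity tests
micro_zero_noise_config <- function() {
  default_config(n_proteins = 25, n_present = 50, n_absent = 50,
                 noise_sdlog = 0, run_cv = 0, interference_rate = 0,
                 baseline = 0, min_train = 1e9,
                 tc_n_proteins = 100, tc_n_degradative = 10)
}
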