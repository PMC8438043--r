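#' Pearson correlation with degenerate-case contract
#'
#' Standard Pearson correlation; if either vector is constant (zero
#' variance) or shorter than 3 points the result is 0 (defined, never NaN),
#' so correlation sums over absent fragments stay well-defined.
#'
#' @param a,b Equal-length numeric vectors.
#' @return r in \[-1, 1\].
#' @export
pearson_cor <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) return(0)
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  r <- stats::cor(a, b)
  if (is.na(r)) 0 else r
}

# moving mean with partial windows at the edges (cumsum-based)
moving_mean <- function(x, width = 3) {
  if (width <= 1) return(x)
  n <- length(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Find candidate elution peaks in a chromatogram set
#'
#' Local maxima of the lightly smoothed summed fragment trace; each
#' candidate window extends to the surrounding minima, clipped to a maximum
#' half-width. Candidates are ordered by summed apex intensity.
#'
#' @param frag Matrix of fragment traces (cycles x fragments).
#' @param min_points Minimum number of grid points in a window (>= 3).
#' @param smooth_width Moving-mean width for peak picking.
#' @param max_halfwidth Maximum window half-width in grid points.
#' @param max_candidates Keep at most this many candidates.
#' @param restrict Optional `c(lo, hi)` grid-index range to search within
#'   (used by the second, retention-time-calibrated search pass).
#' @return A data.frame with `apex`, `lo`, `hi`, `apex_intensity`
#'   (zero rows if the traces are flat).
#' @export
find_candidate_peaks <- function(frag, min_points = 3, smooth_width = 3,
                                 max_halfwidth = 8, max_candidates = 3,
                                 restrict = NULL) {
  m <- .find_peaks(frag, min_points, smooth_width, max_halfwidth,
                   max_candidates, restrict)
  data.frame(apex = as.integer(m[, 1]), lo = as.integer(m[, 2]),
             hi = as.integer(m[, 3]), apex_intensity = m[, 4])
}

# matrix-returning core (columns apex, lo, hi, apex_intensity)
.find_peaks <- function(frag, min_points = 3, smooth_width = 3,
                        max_halfwidth = 8, max_candidates = 3,
                        restrict = NULL) {
  stopifnot(min_points >= 3)
  s <- rowSums(frag)
  n <- length(s)
  empty <- matrix(numeric(), 0, 4)
  if (n < min_points || all(s == 0)) return(empty)
  sm <- moving_mean(s, smooth_width)
  i <- 2:(n - 1)
  is_max <- sm[i] > sm[i - 1] & sm[i] >= sm[i + 1] & sm[i] > 0
  apex <- i[is_max]
  if (!is.null(restrict)) {
    apex <- apex[apex >= restrict[1] & apex <= restrict[2]]
  }
  if (!length(apex)) return(empty)
  ord <- order(sm[apex], decreasing = TRUE)
  apex <- apex[ord][seq_len(min(length(apex), max_candidates))]
  lo <- hi <- integer(length(apex))
  for (k in seq_along(apex)) {
    a <- apex[k]
    l <- a
    while (l > 1 && sm[l - 1] <= sm[l] && a - l < max_halfwidth) l <- l - 1
    h <- a
    while (h < n && sm[h + 1] <= sm[h] && h - a < max_halfwidth) h <- h + 1
    lo[k] <- l
    hi[k] <- h
  }
  keep <- (hi - lo + 1) >= min_points
  cbind(apex, lo, hi, sm[apex])[keep, , drop = FALSE]
}

# pairwise Pearson matrix on a window with the constancy contract (r = 0
# for flat traces); columns are fragment traces
cor_matrix <- function(W) {
  C <- suppressWarnings(stats::cor(W))
  C[is.na(C)] <- 0
  C
}

#' Designate the best fragment on a candidate window
#'
#' The best fragment maximizes the summed Pearson correlation of its
#' elution profile to the profiles of all other fragments; its trace is
#' taken as representative of the peptide's true elution profile. Ties are
#' broken by the lower fragment index (b before y, then series index, then
#' charge -- the construction order of the annotation table).
#'
#' @param frag Fragment trace matrix (cycles x fragments).
#' @param lo,hi Window bounds (grid indices).
#' @return A list with `best` (column index), `corr` (per-fragment Pearson
#'   r to the best fragment), `low_evidence` (single-fragment flag).
#' @export
best_fragment <- function(frag, lo, hi) {
  W <- frag[lo:hi, , drop = FALSE]
  k <- ncol(W)
  if (k == 1) {
    return(list(best = 1L, corr = 1, low_evidence = TRUE))
  }
  C <- cor_matrix(W)
  diag(C) <- 0
  sums <- colSums(C)
  best <- which.max(sums) # first index wins on ties
  corr <- C[, best]
  corr[best] <- 1
  list(best = as.integer(best), corr = corr, low_evidence = FALSE)
}

#' K-GG evidence score components for one candidate
#'
#' Sums of Pearson correlations to the best fragment, partitioned by
#' whether a fragment's span contains the modified residue and/or another
#' (unmodified) candidate site; the best fragment itself is excluded from
#' every sum. `ms1_corr` is the correlation of the MS1 precursor trace to
#' the best fragment; `n_corr_gt` counts fragments correlating above
#' `corr_threshold`.
#'
#' @param frag Fragment trace matrix.
#' @param ms1 MS1 trace vector.
#' @param ann Fragment annotation data.frame (see [fragment_ions()]).
#' @param lo,hi Candidate window.
#' @param corr_threshold Threshold for `n_corr_gt`.
#' @return Named numeric vector: `S_site_determining`, `S_site_containing`,
#'   `S_other_site`, `S_shared`, `ms1_corr`, `n_corr_gt`.
#' @export
kgg_evidence_scores <- function(frag, ms1, ann, lo, hi,
                                corr_threshold = 0.75) {
  bf <- best_fragment(frag, lo, hi)
  r <- bf$corr
  r[bf$best] <- NA # excluded from all sums
  mod <- ann$contains_mod_site
  oth <- ann$contains_other_candidate_site
  s <- function(mask) sum(r[mask], na.rm = TRUE)
  c(S_site_determining = s(mod & !oth),
    S_site_containing = s(mod & oth),
    S_other_site = s(!mod & oth),
    S_shared = s(!mod & !oth),
    ms1_corr = pearson_cor(ms1[lo:hi], frag[lo:hi, bf$best]),
    n_corr_gt = sum(r > corr_threshold, na.rm = TRUE))
}

SCORE_COMPONENTS <- c("S_site_determining", "S_site_containing",
                      "S_other_site", "S_shared", "ms1_corr", "n_corr_gt")

#' Score every candidate elution peak of every precursor in a run
#'
#' @param run A run from [simulate_dia_run()] (or [read_dia_run()]).
#' @param space The searched space (with decoys).
#' @param config Scoring configuration, see [default_config()].
#' @param restrict Optional named list of `c(lo, hi)` grid-index windows
#'   per precursor id; precursors absent from the list are skipped
#'   (second-pass semantics).
#' @return A data.frame with one row per candidate: ids, window, apex and
#'   the score components.
#' @export
score_run <- function(run, space, config = default_config(),
                      restrict = NULL) {
  ids <- names(run$chrom)
  if (!is.null(restrict)) ids <- intersect(ids, names(restrict))
  out <- vector("list", length(ids))
  nrows <- integer(length(ids))
  decoy <- space$precursors$decoy[match(ids, space$precursors$precursor_id)]
  for (i in seq_along(ids)) {
    id <- ids[i]
    cs <- run$chrom[[id]]
    ann <- space$fragments[[id]]
    peaks <- .find_peaks(cs$frag, config$min_points, config$smooth_width,
                         config$max_halfwidth, config$max_candidates,
                         restrict[[id]])
    np <- nrow(peaks)
    if (np == 0) next
    block <- matrix(0, np, 4 + length(SCORE_COMPONENTS))
    block[, 1:4] <- peaks
    for (k in seq_len(np)) {
      block[k, -(1:4)] <-
        kgg_evidence_scores(cs$frag, cs$ms1, ann, peaks[k, 2], peaks[k, 3],
                            corr_threshold = config$corr_threshold)
    }
    out[[i]] <- block
    nrows[i] <- np
  }
  keep <- nrows > 0
  mat <- if (any(keep)) do.call(rbind, out[keep]) else
    matrix(numeric(), 0, 4 + length(SCORE_COMPONENTS))
  colnames(mat) <- c("apex", "lo", "hi", "apex_intensity", SCORE_COMPONENTS)
  res <- data.frame(precursor_id = rep(ids, nrows),
                    decoy = rep(decoy, nrows),
                    mat, stringsAsFactors = FALSE)
  res$apex_rt <- run$rt[res$apex]
  res$run_id <- run$run_id
  rownames(res) <- NULL
  res
}

#' Train the composite discriminant score
#'
#' Percolator-style single iteration: candidates are first ranked by the
#' plain sum of correlation components; confident targets (q <= `train_q`)
#' against decoys train a logistic regression on the score components; the
#' linear predictor is the composite score. If the classes separate
#' degenerately (diverging weights) the scorer falls back to the fixed
#' equal-weight sum and is flagged.
#'
#' @param cands Candidate table from [score_run()] (best candidate per
#'   precursor is selected internally for training).
#' @param train_q q-value threshold defining confident targets.
#' @param min_class Minimum targets and decoys required to train.
#' @return A list with `score(df)` (function returning composite scores),
#'   `weights`, and `fallback` flag.
#' @export
train_composite <- function(cands, train_q = 0.01, min_class = 50) {
  naive <- function(df) {
    df$S_site_determining + df$S_site_containing + df$S_other_site +
      df$S_shared + df$ms1_corr + 0.25 * df$n_corr_gt
  }
  fallback <- list(score = naive, weights = NULL, fallback = TRUE)
  best <- best_per_precursor(cands, naive(cands))
  if (nrow(best) == 0 || sum(best$decoy) < min_class ||
      sum(!best$decoy) < min_class) {
    return(fallback)
  }
  q <- qvalues(best$composite, best$decoy)
  pos <- best[!best$decoy & q <= train_q, , drop = FALSE]
  if (nrow(pos) < min_class) {
    # fall back to the highest-scoring targets if the naive ranking is weak
    tg <- best[!best$decoy, , drop = FALSE]
    pos <- tg[order(tg$composite, decreasing = TRUE), , drop = FALSE]
    pos <- pos[seq_len(min(100, nrow(pos))), , drop = FALSE]
  }
  neg <- best[best$decoy, , drop = FALSE]
  train <- rbind(pos, neg)
  y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  X <- as.data.frame(train[, SCORE_COMPONENTS])
  fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, X),
                                     family = stats::binomial()))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta[-1]) > 50)) return(fallback)
  list(score = function(df) {
    as.numeric(beta[1] +
                 as.matrix(df[, SCORE_COMPONENTS]) %*% beta[-1])
  }, weights = beta, fallback = FALSE)
}

# retain the best-scoring candidate per precursor; returns the candidate
# rows with a `composite` column
best_per_precursor <- function(cands, composite) {
  if (nrow(cands) == 0) {
    cands$composite <- numeric(0)
    return(cands)
  }
  cands$composite <- composite
  ord <- order(cands$precursor_id, -cands$composite)
  cands <- cands[ord, , drop = FALSE]
  cands[!duplicated(cands$precursor_id), , drop = FALSE]
}
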