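# Deterministic sub-seed derivation so that each simulated entity gets an
# independent but reproducible stream (kept below 2^31).
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt * 104729) %% 2147483399) + 1L
}

#' Ground truth for one simulated DIA run series
#'
#' Chooses which target precursors are chromatographically present, their
#' apex retention times, peak widths, abundances and fragment relative
#' intensities (drawn once per precursor from a Dirichlet so they are
#' shared across runs). The cycle time is chosen so that peaks carry
#' roughly 4-5 data points per peak width.
#'
#' @param space Search space with decoys (see [with_decoys()]).
#' @param n_present Number of present target precursors.
#' @param gradient_length Gradient length in seconds.
#' @param cycle_time DIA cycle time in seconds (retention-time grid spacing).
#' @param peak_sigma Gaussian peak width (sigma, seconds).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model.
#' @param dirichlet_conc Concentration of the Dirichlet from which fragment
#'   relative intensities are drawn.
#' @param n_windows Number of uniform precursor isolation windows.
#' @param seed Integer seed.
#' @return A list with `present` (data.frame: `precursor_id`, `apex_rt`,
#'   `sigma`, `abundance`), `weights` (named list of fragment weights),
#'   `rt_grid`, `cycle_time`, `isolation_windows`, `seed`.
#' @export
make_run_truth <- function(space, n_present, gradient_length = 360,
                           cycle_time = 3, peak_sigma = 5.5,
                           abundance_meanlog = log(2e4),
                           abundance_sdlog = 0.8,
                           dirichlet_conc = 2, n_windows = 8, seed = 1) {
  set.seed(derive_seed(seed, 11))
  targets <- space$precursors$precursor_id[!space$precursors$decoy]
  if (n_present > length(targets)) stop("n_present exceeds target count")
  present_ids <- sample(targets, n_present)
  rt_grid <- seq(0, gradient_length, by = cycle_time)
  lo <- gradient_length * 0.1
  hi <- gradient_length * 0.9
  present <- data.frame(
    precursor_id = present_ids,
    apex_rt = stats::runif(n_present, lo, hi),
    sigma = peak_sigma * exp(stats::rnorm(n_present, 0, 0.08)),
    abundance = stats::rlnorm(n_present, abundance_meanlog, abundance_sdlog),
    stringsAsFactors = FALSE)
  weights <- lapply(present_ids, function(id) {
    k <- nrow(space$fragments[[id]])
    w <- stats::rgamma(k, shape = dirichlet_conc)
    w / sum(w)
  })
  names(weights) <- present_ids
  mz <- space$precursors$mz
  brk <- seq(min(mz) - 1e-6, max(mz) + 1e-6, length.out = n_windows + 1)
  windows <- data.frame(low = brk[-length(brk)], high = brk[-1])
  list(present = present, weights = weights, rt_grid = rt_grid,
       cycle_time = cycle_time, isolation_windows = windows, seed = seed)
}

#' Simulate one DIA run
#'
#' Generates, for every searched precursor (targets and decoys), one
#' chromatogram set: a Gaussian elution trace per annotated fragment plus an
#' MS1 precursor trace, sampled on the cycle grid. Present precursors get
#' co-eluting proportional Gaussians (abundance x fragment weight) with
#' multiplicative log-normal point noise and an additive noise baseline;
#' absent precursors and decoys get baseline-only traces. With probability
#' `interference_rate` a fragment additionally receives a displaced Gaussian
#' from a co-fragmenting interferer. Identical seeds give identical output.
#'
#' @param space Search space with decoys.
#' @param truth Output of [make_run_truth()].
#' @param run_id Run label.
#' @param seed Integer seed for this run's noise.
#' @param noise_sdlog Log-sd of the multiplicative point noise.
#' @param run_cv Between-run log-normal abundance variation (CV scale).
#' @param interference_rate Per-fragment interference probability in [0, 1].
#' @param interference_scale Relative abundance of interfering peaks.
#' @param baseline Additive baseline intensity scale (exponential draws).
#' @param rt_shift Linear retention-time map `c(intercept, slope)` applied
#'   to true apexes in this run (exercises cross-run calibration).
#' @param abundance_scale Scalar or per-present-precursor named vector of
#'   multiplicative abundance factors for this run (for planted ratios).
#' @return A run object: list with `run_id`, `rt`, `chrom` (named list with
#'   `frag` matrix \[cycles x fragments\] and `ms1` vector per precursor),
#'   `rt_shift`, `seed`.
#' @export
simulate_dia_run <- function(space, truth, run_id = "run1", seed = 1,
                             noise_sdlog = 0.15, run_cv = 0.10,
                             interference_rate = 0.15,
                             interference_scale = 1, baseline = 30,
                             rt_shift = c(0, 1), abundance_scale = 1) {
  stopifnot(interference_rate >= 0, interference_rate <= 1)
  grid <- truth$rt_grid
  L <- length(grid)
  if (L == 0) stop("empty retention-time grid")
  set.seed(derive_seed(seed, 101))
  prec <- space$precursors
  pres <- truth$present
  pres_idx <- match(prec$precursor_id, pres$precursor_id)
  if (length(abundance_scale) > 1) {
    sc <- abundance_scale[pres$precursor_id]
    sc[is.na(sc)] <- 1
  } else {
    sc <- rep(abundance_scale, nrow(pres))
  }
  chrom <- vector("list", nrow(prec))
  names(chrom) <- prec$precursor_id
  sd_run <- sqrt(log(1 + run_cv^2))
  for (i in seq_len(nrow(prec))) {
    id <- prec$precursor_id[i]
    k <- nrow(space$fragments[[id]])
    M <- matrix(0, L, k)
    ms1 <- numeric(L)
    pi <- pres_idx[i]
    if (!is.na(pi)) {
      apex <- rt_shift[1] + rt_shift[2] * pres$apex_rt[pi]
      sg <- pres$sigma[pi]
      ab <- pres$abundance[pi] * sc[pi] *
        (if (run_cv > 0) stats::rlnorm(1, 0, sd_run) else 1)
      w <- truth$weights[[id]]
      span <- which(grid >= apex - 4 * sg & grid <= apex + 4 * sg)
      if (length(span)) {
        shape <- exp(-(grid[span] - apex)^2 / (2 * sg^2))
        M[span, ] <- outer(shape, ab * w * k / 2)
        ms1[span] <- 0.8 * ab * shape
      }
    }
    if (interference_rate > 0) {
      hit <- which(stats::runif(k + 1) < interference_rate)
      for (h in hit) {
        iapex <- stats::runif(1, grid[1], grid[L])
        isg <- stats::runif(1, 4, 8)
        iab <- interference_scale *
          stats::rlnorm(1, log(2e4), 0.8)
        span <- which(grid >= iapex - 4 * isg & grid <= iapex + 4 * isg)
        if (!length(span)) next
        ishape <- iab * exp(-(grid[span] - iapex)^2 / (2 * isg^2))
        if (h <= k) M[span, h] <- M[span, h] + ishape
        else ms1[span] <- ms1[span] + ishape
      }
    }
    if (noise_sdlog > 0) {
      nz <- M > 0
      if (any(nz)) M[nz] <- M[nz] * stats::rlnorm(sum(nz), 0, noise_sdlog)
      nz1 <- ms1 > 0
      if (any(nz1)) {
        ms1[nz1] <- ms1[nz1] * stats::rlnorm(sum(nz1), 0, noise_sdlog)
      }
    }
    if (baseline > 0) {
      M <- M + matrix(baseline * stats::rexp(L * k), L, k)
      ms1 <- ms1 + baseline * stats::rexp(L)
    }
    chrom[[i]] <- list(frag = M, ms1 = ms1)
  }
  list(run_id = run_id, rt = grid, chrom = chrom, rt_shift = rt_shift,
       seed = seed)
}

#' Serialize a simulated run to a structured TSV
#'
#' One row per trace (`ms1` or a fragment id), columns `precursor_id`,
#' `trace`, then one intensity column per cycle. Header comment lines
#' record the seed, cycle time and retention-time grid.
#'
#' @param run A run from [simulate_dia_run()].
#' @param path Output file.
#' @export
write_dia_run <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# ubidia dia-run %s seed=%d", run$run_id, run$seed),
               sprintf("# rt=%s", paste(signif(run$rt, 10), collapse = ","))),
             con)
  rows <- lapply(names(run$chrom), function(id) {
    cs <- run$chrom[[id]]
    m <- rbind(cs$ms1, t(cs$frag))
    data.frame(precursor_id = id,
               trace = c("ms1", sprintf("f%d", seq_len(ncol(cs$frag)))),
               m, stringsAsFactors = FALSE, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run written by [write_dia_run()]
#'
#' @param path TSV file.
#' @return A run object (without `rt_shift` provenance).
#' @export
read_dia_run <- function(path) {
  hdr <- readLines(path, n = 2)
  seed <- as.integer(sub(".*seed=", "", hdr[1]))
  run_id <- sub("^# ubidia dia-run (\\S+) .*", "\\1", hdr[1])
  rt <- as.numeric(strsplit(sub("^# rt=", "", hdr[2]), ",")[[1]])
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  ids <- unique(df$precursor_id)
  chrom <- lapply(ids, function(id) {
    d <- df[df$precursor_id == id, , drop = FALSE]
    vals <- as.matrix(d[, -(1:2), drop = FALSE])
    list(frag = t(vals[d$trace != "ms1", , drop = FALSE]),
         ms1 = as.numeric(vals[d$trace == "ms1", ]))
  })
  names(chrom) <- ids
  list(run_id = run_id, rt = rt, chrom = chrom, rt_shift = c(0, 1),
       seed = seed)
}

#' Ground truth for a multi-condition time-course experiment
#'
#' Defines the planted effects of a deubiquitinase-inhibition time course:
#' vehicle (DMSO) and drug arms sampled at several time points with
#' replicates. A subset of proteins is planted as *degradative* substrates
#' (ubiquitination up more than twofold at the earliest time point, protein
#' later dropping to at most 0.8x of control), others as non-degradative
#' (sites up, protein stable), plus protein-down-only and weak-site
#' distractors; the rest are null.
#'
#' @param n_proteins Number of ubiquitinated proteins.
#' @param n_degradative,n_nondegradative,n_down_only,n_weak Planted class
#'   sizes.
#' @param sites_range Range of K-GG sites per protein (uniform integer).
#' @param times Time points in minutes (earliest is the "early" time).
#' @param n_replicates Replicates per condition x time point (>= 2).
#' @param cv Fractional log-normal noise scale (0.10 = 10% CV).
#' @param dropout_mid,dropout_scale Logistic intensity-dependent dropout:
#'   midpoint intensity and slope on log10 intensity; `dropout_mid = 0`
#'   disables missingness.
#' @param seed Integer seed.
#' @return A list describing design, planted site/protein effect matrices
#'   (drug arm; DMSO is 1 everywhere), the class table and the seed.
#' @export
timecourse_truth <- function(n_proteins = 500, n_degradative = 40,
                             n_nondegradative = 60, n_down_only = 30,
                             n_weak = 50, sites_range = c(1, 5),
                             times = c(15, 60, 120, 240, 360),
                             n_replicates = 4, cv = 0.10,
                             dropout_mid = 1e4, dropout_scale = 0.5,
                             seed = 1) {
  if (n_replicates < 2) {
    warning("fewer than 2 replicates per arm: downstream moderated ",
            "statistics will refuse this design")
  }
  set.seed(derive_seed(seed, 211))
  nt <- length(times)
  prot <- sprintf("TCP%04d", seq_len(n_proteins))
  cls <- rep("null", n_proteins)
  planted <- n_degradative + n_nondegradative + n_down_only + n_weak
  stopifnot(planted <= n_proteins)
  cls[seq_len(planted)] <- rep(c("degradative", "nondegradative",
                                 "down_only", "weak"),
                               c(n_degradative, n_nondegradative,
                                 n_down_only, n_weak))
  cls <- sample(cls)
  site_counts <- seq(sites_range[1], sites_range[2])
  nsites <- if (length(site_counts) == 1) {
    rep(site_counts, n_proteins)
  } else {
    sample(site_counts, n_proteins, replace = TRUE)
  }
  feature_map <- data.frame(
    feature = unlist(lapply(seq_len(n_proteins), function(i) {
      sprintf("%s_K%d", prot[i], sort(sample(20:800, nsites[i])))
    })),
    protein = rep(prot, nsites), stringsAsFactors = FALSE)
  nf <- nrow(feature_map)
  site_lfc <- matrix(0, nf, nt, dimnames = list(feature_map$feature, times))
  protein_level <- matrix(1, n_proteins, nt, dimnames = list(prot, times))
  decay <- function() pmax(0.3, 1 - 0.14 * (seq_len(nt) - 1) *
                             stats::runif(1, 0.8, 1.2))
  sustained <- function() c(1, pmax(0.6, 1 + stats::rnorm(nt - 1, 0, 0.1)))
  for (i in seq_len(n_proteins)) {
    rows <- which(feature_map$protein == prot[i])
    if (cls[i] == "degradative") {
      amp <- stats::runif(length(rows), 1.5, 3)
      site_lfc[rows, ] <- amp %o% decay()
      lvl_end <- stats::runif(1, 0.5, 0.7)
      protein_level[i, ] <- 1 - (1 - lvl_end) * (seq_len(nt) - 1) / (nt - 1)
    } else if (cls[i] == "nondegradative") {
      amp <- stats::runif(length(rows), 1.2, 2.5)
      site_lfc[rows, ] <- amp %o% sustained()
    } else if (cls[i] == "down_only") {
      lvl_end <- stats::runif(1, 0.6, 0.78)
      protein_level[i, ] <- 1 - (1 - lvl_end) * (seq_len(nt) - 1) / (nt - 1)
    } else if (cls[i] == "weak") {
      amp <- stats::runif(length(rows), 0.2, 0.9)
      site_lfc[rows, ] <- amp %o% sustained()
    }
  }
  design <- expand.grid(replicate = seq_len(n_replicates), time = times,
                        condition = c("DMSO", "drug"),
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_t%d_r%d", design$condition, design$time,
                           design$replicate)
  list(design = design[, c("sample", "condition", "time", "replicate")],
       feature_map = feature_map, classes = data.frame(
         protein = prot, class = cls, stringsAsFactors = FALSE),
       site_lfc = site_lfc, protein_level = protein_level, cv = cv,
       dropout_mid = dropout_mid, dropout_scale = dropout_scale,
       times = times, seed = seed)
}

# intensity-dependent (MNAR) logistic dropout on log10 intensity
apply_dropout <- function(mat, mid, scale) {
  if (mid <= 0) return(mat)
  p <- stats::plogis((log10(mid) - log10(mat)) / scale)
  mat[stats::runif(length(mat)) < p] <- NA
  mat
}

#' Simulate time-course ubiquitinome and proteome quant tables
#'
#' Intensities are baseline x planted effect x log-normal noise, with
#' intensity-dependent dropout; with `cv = 0` and dropout disabled the
#' planted log2 fold changes are recovered exactly.
#'
#' @param truth Output of [timecourse_truth()].
#' @return A list with `ubi` and `prot` [quant_table()]s and `truth`.
#' @export
simulate_timecourse <- function(truth) {
  set.seed(derive_seed(truth$seed, 307))
  design <- truth$design
  ns <- nrow(design)
  sdlog <- if (truth$cv > 0) sqrt(log(1 + truth$cv^2)) else 0
  make_mat <- function(effect_log2, baselines) {
    nf <- nrow(effect_log2)
    mat <- matrix(NA_real_, nf, ns,
                  dimnames = list(rownames(effect_log2), design$sample))
    for (j in seq_len(ns)) {
      eff <- if (design$condition[j] == "DMSO") rep(0, nf)
             else effect_log2[, as.character(design$time[j])]
      mu <- baselines * 2^eff
      noise <- if (sdlog > 0) stats::rlnorm(nf, 0, sdlog) else 1
      mat[, j] <- mu * noise
    }
    apply_dropout(mat, truth$dropout_mid, truth$dropout_scale)
  }
  nf <- nrow(truth$site_lfc)
  np <- nrow(truth$protein_level)
  site_base <- stats::rlnorm(nf, log(3e5), 1)
  prot_base <- stats::rlnorm(np, log(1e6), 1)
  ubi_mat <- make_mat(truth$site_lfc, site_base)
  prot_mat <- make_mat(log2(truth$protein_level), prot_base)
  feats <- truth$feature_map
  rownames(feats) <- feats$feature
  list(ubi = quant_table(ubi_mat, "peptide", features = feats,
                         samples = design),
       prot = quant_table(prot_mat, "protein",
                          features = data.frame(
                            protein = rownames(prot_mat),
                            row.names = rownames(prot_mat)),
                          samples = design),
       truth = truth)
}
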