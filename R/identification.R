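#' Target-decoy q-values
#'
#' For each score threshold t (descending), the FDR estimate is
#' `#decoys >= t / max(1, #targets >= t)` (no +1 correction); the q-value
#' is the minimum FDR over all thresholds at or below the entry's score,
#' which makes q monotone non-decreasing as the score decreases. Decoys
#' receive the q of their own threshold. Tied scores share one threshold.
#'
#' @param score Numeric composite scores.
#' @param decoy Logical decoy flags, same length.
#' @return Numeric q-values in \[0, 1\], aligned with `score`.
#' @export
qvalues <- function(score, decoy) {
  stopifnot(length(score) == length(decoy))
  if (!length(score)) return(numeric(0))
  if (sum(!decoy) < 1) stop("at least one target required")
  if (!any(decoy)) {
    warning("no decoys: q-values are uninformative (all 0)")
    return(rep(0, length(score)))
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  d <- cumsum(decoy[ord])
  t <- cumsum(!decoy[ord])
  fdr <- pmin(d / pmax(1, t), 1)
  # tied scores form one threshold: use the counts at the tie's last position
  grp <- cumsum(!duplicated(s))
  last_idx <- as.integer(tapply(seq_along(s), grp, max))
  fdr <- fdr[last_idx][grp]
  q <- rev(cummin(rev(fdr)))
  out <- numeric(length(score))
  out[ord] <- q
  out
}

#' Realized false-discovery proportion against ground truth
#'
#' Fraction of reported target precursors that are absent from the ground
#' truth, at one or more q-value thresholds (synthetic-data validation
#' harness).
#'
#' @param report Data.frame with `precursor_id`, `decoy` and a q-value
#'   column.
#' @param truth_ids Character vector of truly present target precursor ids.
#' @param q_thresholds q-value cut-offs to evaluate.
#' @param q_col Which q-value column to threshold.
#' @return Data.frame with `q_nominal`, `n_reported`, `n_false`, `fdp`.
#' @export
empirical_fdr <- function(report, truth_ids,
                          q_thresholds = c(0.01, 0.05, 0.1),
                          q_col = "q_global") {
  tg <- report[!report$decoy, , drop = FALSE]
  out <- lapply(q_thresholds, function(qt) {
    keep <- tg[tg[[q_col]] <= qt, , drop = FALSE]
    ids <- unique(keep$precursor_id)
    n_false <- sum(!ids %in% truth_ids)
    data.frame(q_nominal = qt, n_reported = length(ids), n_false = n_false,
               fdp = if (length(ids)) n_false / length(ids) else 0)
  })
  do.call(rbind, out)
}

# best candidate per precursor for each run, with composite scores
score_pass <- function(runs, space, config, scorer = NULL, restrict = NULL) {
  per_run <- lapply(runs, function(run) {
    cands <- score_run(run, space, config,
                       restrict = if (is.null(restrict)) NULL
                                  else restrict[[run$run_id]])
    if (is.null(scorer)) return(cands)
    best_per_precursor(cands, scorer$score(cands))
  })
  per_run
}

# q_global: on the best composite per precursor across runs;
# q_run: within each run separately. Returns the row-bound table.
attach_qvalues <- function(per_run) {
  all <- do.call(rbind, per_run)
  if (nrow(all) == 0) {
    all$q_run <- all$q_global <- numeric(0)
    return(all)
  }
  all$q_run <- unlist(lapply(per_run, function(df) {
    q <- qvalues(df$composite, df$decoy)
    validate_qvalue_monotone(df$composite, q)
    q
  }))
  ord <- order(all$precursor_id, -all$composite)
  first <- !duplicated(all$precursor_id[ord])
  glob <- all[ord, ][first, , drop = FALSE]
  qg <- qvalues(glob$composite, glob$decoy)
  validate_qvalue_monotone(glob$composite, qg)
  all$q_global <- qg[match(all$precursor_id, glob$precursor_id)]
  all
}

# sanity check used on every report: q non-decreasing as composite decreases
validate_qvalue_monotone <- function(score, q) {
  ord <- order(score, decreasing = TRUE)
  if (is.unsorted(q[ord] + 1e-12)) stop("q-values not monotone in score")
  invisible(TRUE)
}

#' Two-pass library-free search with global and run-specific FDR control
#'
#' Pass 1 scores every searched precursor (targets and decoys) in every
#' run. An internal library is built from precursors passing the global
#' (experiment-wide) q-value filter and the run-specific filter in at least
#' one run, storing each precursor's reference retention time (apex in its
#' best-scoring run); the paired decoy of every library target enters the
#' library too, preserving the 1:1 pairing. Pass 2 re-scores only library
#' precursors inside retention-time windows narrowed around the calibrated
#' reference (per-run linear fit of pass-1 apexes against reference,
#' window +/- 3 residual SD with a floor of 3 grid steps), so a precursor
#' may be reported in runs where only pass 2 found it (match-between-runs
#' semantics). The final report is filtered at the global q threshold and
#' annotated with run-level q.
#'
#' @param runs List of run objects.
#' @param space Searched space with decoys.
#' @param config See [default_config()].
#' @return A list: `report` (final filtered report), `all` (unfiltered
#'   pass-2 table), `pass1` (unfiltered pass-1 table, used for calibration
#'   curves), `library` (library precursor table), `calibration` (per-run
#'   linear fits), `scorer` (trained composite scorer).
#' @export
two_pass_search <- function(runs, space, config = default_config()) {
  stopifnot(length(runs) >= 1)
  fdr <- config$fdr_level
  cands1 <- lapply(runs, function(run) score_run(run, space, config))
  scorer <- train_composite(do.call(rbind, cands1),
                            train_q = fdr, min_class = config$min_train)
  per_run1 <- lapply(cands1, function(cc) {
    best_per_precursor(cc, scorer$score(cc))
  })
  pass1 <- attach_qvalues(per_run1)
  # library selection (targets), then add paired decoys
  byid <- split(pass1, pass1$precursor_id)
  lib_ok <- vapply(byid, function(df) {
    df$q_global[1] <= fdr && any(df$q_run <= fdr)
  }, logical(1))
  lib_ids <- names(byid)[lib_ok]
  lib_targets <- lib_ids[!grepl("^DECOY_", lib_ids)]
  lib_all <- unique(c(lib_targets, paste0("DECOY_", lib_targets)))
  lib_all <- intersect(lib_all, space$precursors$precursor_id)
  ref_rt <- vapply(lib_all, function(id) {
    df <- byid[[id]]
    if (is.null(df)) return(NA_real_)
    df$apex_rt[which.max(df$composite)]
  }, numeric(1))
  lib <- data.frame(precursor_id = lib_all, ref_rt = ref_rt,
                    stringsAsFactors = FALSE)
  lib <- lib[!is.na(lib$ref_rt), , drop = FALSE]
  if (nrow(lib) == 0) {
    rep0 <- pass1[0, , drop = FALSE]
    return(list(report = rep0, all = rep0, pass1 = pass1, library = lib,
                calibration = NULL, scorer = scorer))
  }
  # per-run RT calibration and pass-2 windows
  calibration <- list()
  restrict <- list()
  for (run in runs) {
    df <- pass1[pass1$run_id == run$run_id, , drop = FALSE]
    conf <- df[!df$decoy &
                 df$precursor_id %in% lib$precursor_id &
                 df$q_run <= fdr, , drop = FALSE]
    conf$ref <- lib$ref_rt[match(conf$precursor_id, lib$precursor_id)]
    cycle <- run$rt[2] - run$rt[1]
    if (nrow(conf) < 2) {
      fit <- list(intercept = 0, slope = 1, sd = 3 * cycle,
                  identity_fallback = TRUE)
    } else {
      lmfit <- stats::lm(apex_rt ~ ref, data = conf)
      fit <- list(intercept = unname(stats::coef(lmfit)[1]),
                  slope = unname(stats::coef(lmfit)[2]),
                  sd = max(stats::sd(stats::resid(lmfit)), 1e-9),
                  identity_fallback = FALSE)
    }
    calibration[[run$run_id]] <- fit
    half_rt <- max(3 * fit$sd, 3 * cycle)
    centre <- fit$intercept + fit$slope * lib$ref_rt
    wins <- lapply(seq_len(nrow(lib)), function(i) {
      c(max(1L, floor((centre[i] - half_rt) / cycle) + 1L),
        min(length(run$rt), ceiling((centre[i] + half_rt) / cycle) + 1L))
    })
    names(wins) <- lib$precursor_id
    restrict[[run$run_id]] <- wins
  }
  per_run2 <- score_pass(runs, space, config, scorer = scorer,
                         restrict = restrict)
  pass2 <- attach_qvalues(per_run2)
  report <- pass2[!pass2$decoy & pass2$q_global <= fdr, , drop = FALSE]
  prec <- space$precursors
  m <- match(report$precursor_id, prec$precursor_id)
  report$sequence <- prec$sequence[m]
  report$mods <- prec$mods[m]
  report$charge <- prec$charge[m]
  report$quantity <- NA_real_
  list(report = report, all = pass2, pass1 = pass1, library = lib,
       calibration = calibration, scorer = scorer)
}
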