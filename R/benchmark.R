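#' Default pipeline configuration
#'
#' All tunable thresholds, simulator settings and benchmark sizes in one
#' declarative list. Fields are documented in the methods vignette;
#' `fdr_level` is the precursor FDR applied both experiment-wide and per
#' run (1%), `fc_thresh`/`down_thresh`/`sig_q` are the substrate-calling
#' thresholds (twofold site induction, 20% protein loss, 5% FDR).
#'
#' @param ... Named overrides of individual fields.
#' @return A named list.
#' @export
default_config <- function(...) {
  config <- list(
    # scoring
    min_points = 3, smooth_width = 3, max_halfwidth = 8,
    max_candidates = 3, corr_threshold = 0.75, min_train = 50,
    # identification
    fdr_level = 0.01,
    # quantification
    quant_k = 3,
    # differential statistics / substrate calling
    presence_min = 0.5, sig_q = 0.05, fc_thresh = 1, down_thresh = 0.2,
    # simulator / benchmark sizes
    n_proteins = 320, n_present = 2000, n_absent = 2000,
    charges = 2, gradient_length = 360, cycle_time = 3, peak_sigma = 5.5,
    noise_sdlog = 0.15, run_cv = 0.10, interference_rate = 0.15,
    baseline = 30, rt_shift2 = c(15, 1.02), planted_ratio_log2 = 1,
    tc_n_proteins = 500, tc_n_degradative = 40, tc_cv = 0.10)
  over <- list(...)
  config[names(over)] <- over
  config
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

#' Build the peptide universe for the identification benchmark
#'
#' Random proteome plus its K-GG search space; deterministic given
#' (config, seed) and reusable across Monte Carlo replicates.
#'
#' @param config See [default_config()].
#' @param seed Integer seed for the proteome.
#' @return A list with `proteome` and `space` (targets only).
#' @export
benchmark_universe <- function(config = default_config(), seed = 1) {
  proteome <- random_proteome(config$n_proteins, seed = derive_seed(seed, 1))
  space <- build_search_space(proteome, charges = config$charges,
                              variable_mods = c("KGG", "OxM"),
                              kgg_only = TRUE)
  list(proteome = proteome, space = with_decoys(space))
}

#' Build the default synthetic identification benchmark
#'
#' Random proteome, K-GG search space subsampled to the requested number
#' of target precursors, 1:1 decoys, a two-run ground truth with a linear
#' retention-time shift in the second run and a planted twofold abundance
#' change for half of the present precursors.
#'
#' @param config See [default_config()].
#' @param seed Integer seed.
#' @param universe Optional prebuilt peptide universe (list with
#'   `proteome` and `space`) from [benchmark_universe()]; building it is
#'   the expensive deterministic part, so Monte Carlo replicates over
#'   seeds can share one universe while truth and noise vary.
#' @return A list with `space` (with decoys), `truth`, `runs`,
#'   `present_ids` and `ratio` (named planted log2 ratios, run2/run1).
#' @export
benchmark_inputs <- function(config = default_config(), seed = 1,
                             universe = NULL) {
  if (is.null(universe)) universe <- benchmark_universe(config, seed)
  proteome <- universe$proteome
  space <- universe$space
  n_target <- config$n_present + config$n_absent
  targets <- which(!space$precursors$decoy)
  if (length(targets) < n_target) {
    stop("search space too small for the requested benchmark size")
  }
  set.seed(derive_seed(seed, 2))
  keep <- sort(sample(targets, n_target))
  prec <- space$precursors[keep, , drop = FALSE]
  ids <- c(prec$precursor_id, paste0("DECOY_", prec$precursor_id))
  full_prec <- space$precursors[match(ids, space$precursors$precursor_id), ,
                                drop = FALSE]
  rownames(full_prec) <- NULL
  full <- list(precursors = full_prec,
               links = space$links[space$links$peptide_id %in%
                                     prec$peptide_id, , drop = FALSE],
               fragments = space$fragments[ids])
  truth <- make_run_truth(full, n_present = config$n_present,
                          gradient_length = config$gradient_length,
                          cycle_time = config$cycle_time,
                          peak_sigma = config$peak_sigma,
                          seed = derive_seed(seed, 3))
  present_ids <- truth$present$precursor_id
  set.seed(derive_seed(seed, 4))
  ratio <- stats::setNames(rep(0, length(present_ids)), present_ids)
  ratio[sample(length(ratio), length(ratio) %/% 2)] <-
    config$planted_ratio_log2
  runs <- list(
    simulate_dia_run(full, truth, run_id = "run1",
                     seed = derive_seed(seed, 11),
                     noise_sdlog = config$noise_sdlog,
                     run_cv = config$run_cv,
                     interference_rate = config$interference_rate,
                     baseline = config$baseline),
    simulate_dia_run(full, truth, run_id = "run2",
                     seed = derive_seed(seed, 12),
                     noise_sdlog = config$noise_sdlog,
                     run_cv = config$run_cv,
                     interference_rate = config$interference_rate,
                     baseline = config$baseline,
                     rt_shift = config$rt_shift2,
                     abundance_scale = 2^ratio))
  list(space = full, truth = truth, runs = runs, proteome = proteome,
       present_ids = present_ids, ratio = ratio)
}

#' Run the reference synthetic benchmark end to end
#'
#' Simulate, search (two passes), quantify, map sites, run the
#' time-course statistics and substrate calls, and measure everything
#' against the planted truth: realized false-discovery proportion, FDR
#' calibration curve, log2-ratio recovery, CV precision and substrate
#' sensitivity/precision.
#'
#' @param config See [default_config()].
#' @param seed Integer seed for every stochastic stage.
#' @param metrics_path Optional path for a machine-readable metrics JSON
#'   (requires jsonlite).
#' @return A list with `metrics` (named numerics) and the intermediate
#'   objects (`search`, `quant`, `sites`, `substrates`).
#' @export
run_benchmark <- function(config = default_config(), seed = 1,
                          metrics_path = NULL) {
  inp <- benchmark_inputs(config, seed)
  search <- two_pass_search(inp$runs, inp$space, config)
  fdp_final <- empirical_fdr(search$report, inp$present_ids,
                             q_thresholds = config$fdr_level)
  calib <- empirical_fdr(search$pass1, inp$present_ids,
                         q_thresholds = c(0.01, 0.05, 0.1))
  qt <- quantify_report(search, inp$runs, k = config$quant_k)
  both <- rownames(qt$mat)[rowSums(!is.na(qt$mat)) == 2 &
                             rownames(qt$mat) %in% inp$present_ids]
  ratio_err <- if (length(both)) {
    measured <- log2(qt$mat[both, "run2"] / qt$mat[both, "run1"])
    stats::median(abs(measured - inp$ratio[both]))
  } else NA_real_
  # site mapping of reported K-GG peptides back onto the synthetic proteome
  rep_pep <- search$report[!duplicated(search$report$precursor_id),
                           c("sequence", "mods"), drop = FALSE]
  rep_pep$peptide_id <- paste(rep_pep$sequence, rep_pep$mods, sep = "|")
  sites <- map_kgg_sites(rep_pep, inp$space$links, inp$proteome)
  # timecourse stage
  nd <- config$tc_n_degradative
  tc_truth <- timecourse_truth(n_proteins = config$tc_n_proteins,
                               n_degradative = nd,
                               n_nondegradative = round(1.5 * nd),
                               n_down_only = round(0.75 * nd),
                               n_weak = round(1.25 * nd),
                               cv = config$tc_cv,
                               seed = derive_seed(seed, 5))
  tc <- simulate_timecourse(tc_truth)
  ubi_diff <- moderated_ttest(median_scale(tc$ubi))
  prot_diff <- moderated_ttest(median_scale(tc$prot))
  fmap <- stats::setNames(tc$truth$feature_map$protein,
                          tc$truth$feature_map$feature)
  calls <- classify_substrates(ubi_diff, fmap, prot_diff,
                               fc_thresh = config$fc_thresh,
                               down_thresh = config$down_thresh,
                               sig_q = config$sig_q)
  truth_deg <- tc$truth$classes$protein[
    tc$truth$classes$class == "degradative"]
  called_deg <- calls$protein_group[calls$verdict == "degradative"]
  sens <- if (length(truth_deg)) {
    length(intersect(called_deg, truth_deg)) / length(truth_deg)
  } else NA_real_
  prec_deg <- if (length(called_deg)) {
    length(intersect(called_deg, truth_deg)) / length(called_deg)
  } else NA_real_
  cvs <- feature_cvs(tc$ubi, groups = paste(tc$ubi$samples$condition,
                                            tc$ubi$samples$time))
  metrics <- c(
    fdp_at_1pct = fdp_final$fdp[1],
    n_reported = fdp_final$n_reported[1],
    calibration_slope = sum(calib$fdp * calib$q_nominal) /
      sum(calib$q_nominal^2),
    median_abs_log2_ratio_error = ratio_err,
    n_sites_mapped = nrow(sites),
    substrate_sensitivity = sens,
    substrate_precision = prec_deg,
    median_cv_percent = stats::median(cvs, na.rm = TRUE),
    frac_cv_below_20 = mean(cvs < 20, na.rm = TRUE))
  if (!is.null(metrics_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required to write the metrics JSON")
    }
    payload <- list(tool = "ubidia",
                    version = as.character(utils::packageVersion("ubidia")),
                    seed = seed, config_hash = config_hash(config),
                    metrics = as.list(metrics))
    jsonlite::write_json(payload, metrics_path, auto_unbox = TRUE,
                         digits = NA)
  }
  list(metrics = metrics, search = search, quant = qt, sites = sites,
       substrates = calls, inputs = inp, timecourse = tc)
}
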