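split_group <- function(x) strsplit(x, ";", fixed = TRUE)

#' Peaking time of the ubiquitin signal
#'
#' Averages the log2 fold-change profiles of each protein's significant
#' features pointwise across time and returns the time of the maximum
#' (ties resolved to the earliest time).
#'
#' @param profiles Numeric matrix of log2 fold changes, features x times,
#'   with time points as column names.
#' @param membership Named list mapping protein -> character vector of
#'   feature rownames (each protein needs >= 1 feature).
#' @return Named numeric vector of peaking times per protein.
#' @export
peaking_time <- function(profiles, membership) {
  times <- as.numeric(colnames(profiles))
  vapply(membership, function(feats) {
    prof <- colMeans(profiles[feats, , drop = FALSE], na.rm = TRUE)
    times[which.max(prof)] # which.max takes the first (earliest) maximum
  }, numeric(1))
}

#' Call degradative and non-degradative substrates
#'
#' Integrates the ubiquitinome with the proteome: a protein group is a
#' *degradative* substrate when at least one of its K-GG features is
#' significantly up more than `fc_thresh` (log2) at the earliest treatment
#' time AND the protein is significantly down below `1 - down_thresh` of
#' control at some (by default any, optionally only the last) treatment
#' time; *non-degradative* when only the site condition holds;
#' *unregulated* otherwise. Groups whose protein is absent from the
#' proteome table are reported distinctly (`degradation_unknown`).
#' Matching across tables disaggregates protein groups into individual
#' accessions.
#'
#' @param ubi_diff [moderated_ttest()] output for the ubiquitinome.
#' @param ubi_protein Named character vector: ubiquitinome feature ->
#'   protein group (";"-joined accessions).
#' @param prot_diff [moderated_ttest()] output for the proteome.
#' @param prot_protein Named character vector: proteome feature -> protein
#'   group; defaults to the feature ids themselves.
#' @param early_time Earliest treatment time; defaults to the minimum time
#'   in `ubi_diff`.
#' @param fc_thresh Site log2 fold-change threshold (1 = twofold).
#' @param down_thresh Protein loss threshold (0.2 = "down by more than
#'   20%", i.e. relative level < 0.8).
#' @param sig_q Significance threshold on BH q-values.
#' @param endpoint_only Evaluate the degradation condition at the last
#'   time point only.
#' @return A data.frame of substrate calls with supporting evidence
#'   columns (`verdict`, `earliest_up_time`, `max_site_log2fc`,
#'   `min_protein_relative_level`, `peaking_time`, `n_sig_sites`).
#' @export
classify_substrates <- function(ubi_diff, ubi_protein, prot_diff,
                                prot_protein = NULL,
                                early_time = min(ubi_diff$time),
                                fc_thresh = 1, down_thresh = 0.2,
                                sig_q = 0.05, endpoint_only = FALSE) {
  ubi_diff$protein_group <- unname(ubi_protein[ubi_diff$feature])
  if (is.null(prot_protein)) {
    prot_protein <- stats::setNames(unique(prot_diff$feature),
                                    unique(prot_diff$feature))
  }
  # accession -> proteome rows (disaggregated)
  prot_acc <- data.frame(
    feature = rep(names(prot_protein),
                  lengths(split_group(unname(prot_protein)))),
    accession = unlist(split_group(unname(prot_protein))),
    stringsAsFactors = FALSE)
  groups <- unique(ubi_diff$protein_group)
  groups <- groups[!is.na(groups)]
  deg_times <- if (endpoint_only) max(prot_diff$time) else
    unique(prot_diff$time)
  lfc_down <- log2(1 - down_thresh)
  # per-feature profile matrix for peaking times
  times <- sort(unique(ubi_diff$time))
  prof <- matrix(NA_real_, length(unique(ubi_diff$feature)), length(times),
                 dimnames = list(unique(ubi_diff$feature), times))
  prof[cbind(match(ubi_diff$feature, rownames(prof)),
             match(ubi_diff$time, times))] <- ubi_diff$log2fc
  out <- lapply(groups, function(g) {
    feats <- unique(ubi_diff$feature[ubi_diff$protein_group %in% g])
    early <- ubi_diff[ubi_diff$feature %in% feats &
                        ubi_diff$time == early_time, , drop = FALSE]
    sig_up <- early[early$q < sig_q & early$log2fc > fc_thresh, ,
                    drop = FALSE]
    site_ok <- nrow(sig_up) > 0
    all_up <- ubi_diff[ubi_diff$feature %in% feats &
                         ubi_diff$q < sig_q &
                         ubi_diff$log2fc > fc_thresh, , drop = FALSE]
    accs <- split_group(g)[[1]]
    prot_rows <- prot_diff[prot_diff$feature %in%
                             prot_acc$feature[prot_acc$accession %in% accs] &
                             prot_diff$time %in% deg_times, , drop = FALSE]
    in_proteome <- nrow(prot_rows) > 0
    deg_ok <- in_proteome && any(prot_rows$q < sig_q &
                                   prot_rows$log2fc < lfc_down)
    verdict <- if (!site_ok) "unregulated"
               else if (!in_proteome) "degradation_unknown"
               else if (deg_ok) "degradative"
               else "non-degradative"
    pk <- if (nrow(sig_up)) {
      unname(peaking_time(prof, stats::setNames(
        list(unique(sig_up$feature)), g)))
    } else NA_real_
    data.frame(
      protein_group = g, verdict = verdict,
      earliest_up_time = if (nrow(all_up)) min(all_up$time) else NA_real_,
      max_site_log2fc = if (nrow(early)) max(early$log2fc) else NA_real_,
      min_protein_relative_level =
        if (in_proteome) 2^min(prot_rows$log2fc) else NA_real_,
      peaking_time = pk, n_sig_sites = nrow(sig_up),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multi-inhibitor consensus substrate set
#'
#' A protein qualifies when at least `k` of the tested compounds show at
#' least one site significantly up more than `fc_thresh`; the overlap
#' fraction against a reference set is
#' `|consensus intersect reference| / |reference|`.
#'
#' @param diff_list Named list of [moderated_ttest()] outputs, one per
#'   compound (same feature space).
#' @param feature_protein Named character vector: feature -> protein group.
#' @param k Minimum number of supporting compounds.
#' @param fc_thresh,sig_q Site thresholds.
#' @param reference Optional character vector of reference proteins.
#' @return A list with `consensus` (character vector of protein groups),
#'   `per_compound` (logical matrix protein x compound) and `overlap`
#'   (fraction, `NA` without a reference).
#' @export
inhibitor_consensus <- function(diff_list, feature_protein, k = 3,
                                fc_thresh = 1, sig_q = 0.05,
                                reference = NULL) {
  if (k > length(diff_list)) stop("k exceeds the number of compounds")
  hit_sets <- lapply(diff_list, function(d) {
    sig <- d[d$q < sig_q & d$log2fc > fc_thresh, , drop = FALSE]
    unique(unname(feature_protein[sig$feature]))
  })
  prots <- sort(unique(unlist(hit_sets)))
  hits <- vapply(hit_sets, function(h) prots %in% h,
                 logical(length(prots)))
  hits <- matrix(hits, nrow = length(prots),
                 dimnames = list(prots, names(diff_list)))
  consensus <- prots[rowSums(hits) >= k]
  overlap <- if (is.null(reference)) NA_real_ else {
    if (!length(reference)) NA_real_ else
      length(intersect(consensus, reference)) / length(reference)
  }
  list(consensus = consensus, per_compound = hits, overlap = overlap)
}

#' Annotate high-confidence interactors with ubiquitination dynamics
#'
#' Filters an interaction table for partners with at least `min_evidence`
#' supporting studies and joins the substrate-call evidence (peaking time,
#' significant-site flag). Partners without significant sites stay in the
#' table with empty annotation; this is a plain table operation, no graph
#' rendering.
#'
#' @param interactions Data.frame with `accession` and `evidence` (study
#'   count).
#' @param substrate_calls Output of [classify_substrates()].
#' @param min_evidence Minimum number of supporting studies.
#' @return The filtered, annotated interactor table.
#' @export
annotate_interactors <- function(interactions, substrate_calls,
                                 min_evidence = 4) {
  keep <- interactions[interactions$evidence >= min_evidence, ,
                       drop = FALSE]
  acc_map <- data.frame(
    accession = unlist(split_group(substrate_calls$protein_group)),
    idx = rep(seq_len(nrow(substrate_calls)),
              lengths(split_group(substrate_calls$protein_group))),
    stringsAsFactors = FALSE)
  m <- match(keep$accession, acc_map$accession)
  idx <- acc_map$idx[m]
  keep$verdict <- substrate_calls$verdict[idx]
  keep$peaking_time <- substrate_calls$peaking_time[idx]
  keep$significant_site <- !is.na(idx) &
    substrate_calls$n_sig_sites[idx] > 0
  rownames(keep) <- NULL
  keep
}
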