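#' Precursor quantity from a candidate elution peak
#'
#' Documented peak-area rule: the sum over the candidate window of the
#' mean trace of the `k` fragments most correlated with the best fragment
#' (the best fragment included). Deterministic; with fewer than `k`
#' fragments all are used and the value is flagged.
#'
#' @param frag Fragment trace matrix (cycles x fragments).
#' @param lo,hi Candidate window (grid indices); an empty window gives 0.
#' @param k Number of top-correlated fragments to average (default 3).
#' @param use_fragments Optional fixed set of fragment column indices to
#'   average (overrides the correlation ranking); used for cross-run
#'   consistency, where the set is chosen once in a precursor's
#'   best-scoring run.
#' @return Numeric quantity with attribute `flag` when degraded
#'   ("few_fragments" or "empty_window").
#' @export
precursor_quantity <- function(frag, lo, hi, k = 3, use_fragments = NULL) {
  if (is.na(lo) || is.na(hi) || hi < lo) {
    return(structure(0, flag = "empty_window"))
  }
  flag <- NULL
  if (is.null(use_fragments)) {
    kk <- min(k, ncol(frag))
    if (ncol(frag) < k) flag <- "few_fragments"
    use_fragments <- top_quant_fragments(frag, lo, hi, kk)
  }
  val <- sum(rowMeans(frag[lo:hi, use_fragments, drop = FALSE]))
  if (is.null(flag)) val else structure(val, flag = flag)
}

# top-k fragments by correlation to the best fragment; correlations are
# rounded for ranking so exact ties (noise-free proportional traces)
# resolve by fragment index, not float jitter
top_quant_fragments <- function(frag, lo, hi, k) {
  bf <- best_fragment(frag, lo, hi)
  order(-round(bf$corr, 9), seq_along(bf$corr))[seq_len(min(k, ncol(frag)))]
}

#' Attach quantities to a search report and build a precursor quant table
#'
#' @param result A [two_pass_search()] result.
#' @param runs The runs that were searched.
#' @param k See [precursor_quantity()].
#' @return A precursor-level [quant_table()] (runs as samples).
#' @export
quantify_report <- function(result, runs, k = 3) {
  rep <- result$report
  run_ids <- vapply(runs, `[[`, "", "run_id")
  ids <- unique(rep$precursor_id)
  mat <- matrix(NA_real_, length(ids), length(run_ids),
                dimnames = list(ids, run_ids))
  # fragment set fixed per precursor in its best-scoring run, then reused
  # across runs (cross-run consistent quantification)
  frag_sets <- lapply(ids, function(id) {
    rows <- rep[rep$precursor_id == id, , drop = FALSE]
    b <- which.max(rows$composite)
    run <- runs[[match(rows$run_id[b], run_ids)]]
    top_quant_fragments(run$chrom[[id]]$frag, rows$lo[b], rows$hi[b], k)
  })
  names(frag_sets) <- ids
  for (r in seq_len(nrow(rep))) {
    run <- runs[[match(rep$run_id[r], run_ids)]]
    q <- precursor_quantity(run$chrom[[rep$precursor_id[r]]]$frag,
                            rep$lo[r], rep$hi[r], k = k,
                            use_fragments =
                              frag_sets[[rep$precursor_id[r]]])
    mat[rep$precursor_id[r], rep$run_id[r]] <- as.numeric(q)
  }
  mat[!is.na(mat) & mat <= 0] <- NA
  feats <- rep[!duplicated(rep$precursor_id),
               c("precursor_id", "sequence", "mods", "charge"), drop = FALSE]
  feats <- feats[match(ids, feats$precursor_id), , drop = FALSE]
  rownames(feats) <- ids
  quant_table(mat, "precursor", features = feats)
}

#' Median sample scaling
#'
#' Multiplies each sample by (global median of per-sample medians) /
#' (that sample's median), medians over present values only, so that all
#' samples end up with equal medians. Idempotent.
#'
#' @param qt A [quant_table()].
#' @return The normalized [quant_table()].
#' @export
median_scale <- function(qt) {
  mat <- qt$mat
  med <- apply(mat, 2, stats::median, na.rm = TRUE)
  if (any(is.na(med))) {
    stop("sample(s) without any present value: ",
         paste(colnames(mat)[is.na(med)], collapse = ", "))
  }
  target <- stats::median(med)
  qt$mat <- sweep(mat, 2, target / med, "*")
  qt
}

# peptide key for aggregation: modified sequence without the charge
peptide_key <- function(features) {
  paste(features$sequence, features$mods, sep = "|")
}

#' Aggregate precursors to peptides by averaging
#'
#' Peptide intensity per sample is the arithmetic mean over that peptide's
#' precursors present in the sample (missing precursors are skipped;
#' all-missing gives missing).
#'
#' @param qt A precursor-level [quant_table()] (normalize first).
#' @param group Character vector assigning each feature row to a peptide;
#'   defaults to the modified sequence from the feature metadata.
#' @return A peptide-level [quant_table()].
#' @export
aggregate_mean <- function(qt, group = peptide_key(qt$features)) {
  stopifnot(length(group) == nrow(qt$mat))
  groups <- unique(group)
  out <- matrix(NA_real_, length(groups), ncol(qt$mat),
                dimnames = list(groups, colnames(qt$mat)))
  for (g in groups) {
    rows <- qt$mat[group == g, , drop = FALSE]
    v <- colMeans(rows, na.rm = TRUE)
    v[is.nan(v)] <- NA
    out[g, ] <- v
  }
  quant_table(out, "peptide", samples = qt$samples)
}

# MaxLFQ solve for one peptide: log-intensity matrix L (precursors x
# samples, NA allowed) -> per-sample log-abundance profile (free scale).
maxlfq_profile <- function(L, min_shared = 1) {
  ns <- ncol(L)
  present <- colSums(!is.na(L)) > 0
  a <- rep(NA_real_, ns)
  if (!any(present)) {
    return(list(a = a, component = rep(NA_integer_, ns)))
  }
  # pairwise median log-ratios
  pairs <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  ri <- rj <- integer(0)
  rr <- numeric(0)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]
    j <- pairs[p, 2]
    shared <- !is.na(L[, i]) & !is.na(L[, j])
    if (sum(shared) >= min_shared) {
      ri <- c(ri, i)
      rj <- c(rj, j)
      rr <- c(rr, stats::median(L[shared, i] - L[shared, j]))
    }
  }
  # connected components of the ratio graph; isolated present samples get
  # their own (mean) value
  comp <- seq_len(ns)
  repeat {
    changed <- FALSE
    for (p in seq_along(ri)) {
      m <- min(comp[ri[p]], comp[rj[p]])
      if (comp[ri[p]] != m || comp[rj[p]] != m) {
        comp[c(ri[p], rj[p])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (cc in unique(comp[present])) {
    samples <- which(comp == cc & present)
    eqs <- which(ri %in% samples & rj %in% samples)
    if (length(samples) == 1 || !length(eqs)) {
      for (s in samples) a[s] <- mean(L[, s], na.rm = TRUE)
      next
    }

    # least squares on a_i - a_j = r_ij with a sum-to-zero gauge row
    k <- length(samples)
    idx <- match(seq_len(ns), samples)
    A <- matrix(0, length(eqs) + 1, k)
    b <- c(rr[eqs], 0)
    for (e in seq_along(eqs)) {
      A[e, idx[ri[eqs[e]]]] <- 1
      A[e, idx[rj[eqs[e]]]] <- -1
    }
    A[length(eqs) + 1, ] <- 1
    a[samples] <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  }
  list(a = a, component = ifelse(present, comp, NA_integer_))
}

#' Aggregate precursors to peptides with the MaxLFQ algorithm
#'
#' Per peptide, pairwise sample log-ratios are estimated as the median of
#' per-precursor log-ratios over precursors present in both samples
#' (requiring at least `min_shared` shared precursors); the per-sample
#' log-abundances solving the least-squares ratio system give the relative
#' profile. The free scale is fixed so the summed output intensity equals
#' the summed input intensity over present samples (per connected
#' component; disconnected components are solved separately).
#'
#' @inheritParams aggregate_mean
#' @param min_shared Minimum precursors shared by a sample pair for its
#'   ratio to enter the system.
#' @return A peptide-level [quant_table()].
#' @export
aggregate_maxlfq <- function(qt, group = peptide_key(qt$features),
                             min_shared = 1) {
  stopifnot(length(group) == nrow(qt$mat))
  groups <- unique(group)
  out <- matrix(NA_real_, length(groups), ncol(qt$mat),
                dimnames = list(groups, colnames(qt$mat)))
  for (g in groups) {
    X <- qt$mat[group == g, , drop = FALSE]
    sol <- maxlfq_profile(log(X), min_shared = min_shared)
    prof <- exp(sol$a)
    # scale fixing per connected component of the ratio graph
    for (cc in unique(sol$component[!is.na(sol$component)])) {
      s <- which(!is.na(sol$component) & sol$component == cc)
      total_in <- sum(X[, s, drop = FALSE], na.rm = TRUE)
      prof[s] <- prof[s] * total_in / sum(prof[s])
    }
    out[g, ] <- prof
  }
  quant_table(out, "peptide", samples = qt$samples)
}

#' Percent coefficient of variation
#'
#' 100 x sample standard deviation (n-1 denominator) / mean, computed on
#' raw (unlogged) intensities; fewer than 2 present values gives `NA`.
#'
#' @param values Numeric vector (NAs dropped).
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) return(NA_real_)
  100 * stats::sd(v) / mean(v)
}

#' Per-feature CVs of a quant table
#'
#' @param qt A [quant_table()].
#' @param groups Optional sample grouping (e.g. condition x time); CVs are
#'   computed within each group and averaged per feature when given.
#' @return Numeric vector of per-feature CVs in percent.
#' @export
feature_cvs <- function(qt, groups = NULL) {
  if (is.null(groups)) {
    return(apply(qt$mat, 1, cv_percent))
  }
  stopifnot(length(groups) == ncol(qt$mat))
  per <- sapply(unique(groups), function(g) {
    apply(qt$mat[, groups == g, drop = FALSE], 1, cv_percent)
  })
  rowMeans(as.matrix(per), na.rm = TRUE)
}
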