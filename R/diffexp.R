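#' Moderated two-group differential tests per time point
#'
#' For each time point, treatment samples are compared against the
#' time-matched vehicle controls on log2 intensities: per-feature ordinary
#' least squares (two-group mean difference), residual variances shrunk by
#' empirical Bayes towards a prior estimated from all features in the
#' contrast (Smyth-style scaled-F moments, via [limma::squeezeVar()]), a
#' moderated t with `df + d0` degrees of freedom, two-sided p-values and
#' Benjamini-Hochberg q-values within the contrast. Features present in at
#' most half of the contrast's samples, or with fewer than 2 present
#' values in either arm, are skipped.
#'
#' @param qt A [quant_table()] of raw intensities (log2 taken internally
#'   unless `log2_input = TRUE`).
#' @param samples Sample metadata data.frame with `sample`, `condition`,
#'   `time`; defaults to `qt$samples`.
#' @param control Name of the vehicle condition.
#' @param presence_min Strict minimum fraction of present values among the
#'   contrast's samples.
#' @param prior_df Optional override of the prior degrees of freedom d0:
#'   `0` gives the ordinary t-test, `Inf` fully shrinks every variance to
#'   the prior variance (estimated as the mean residual variance unless
#'   `prior_var` is given), `NULL` (default) estimates d0 from the data.
#' @param prior_var Prior variance used with `prior_df = Inf`.
#' @param log2_input Intensities are already log2.
#' @return A data.frame with one row per feature x contrast: `feature`,
#'   `condition`, `time`, `log2fc` (treatment - control), `t`, `df_total`,
#'   `p`, `q`, `n_control`, `n_treat`, `s2`, `s2_post`; attributes
#'   `df_prior` and `s2_prior` record the shrinkage prior per contrast.
#' @export
moderated_ttest <- function(qt, samples = qt$samples, control = "DMSO",
                            presence_min = 0.5, prior_df = NULL,
                            prior_var = NULL, log2_input = FALSE) {
  stopifnot(!is.null(samples), all(c("sample", "condition", "time") %in%
                                     names(samples)))
  mat <- qt$mat[, samples$sample, drop = FALSE]
  if (!log2_input) mat <- log2(mat)
  treatments <- setdiff(unique(samples$condition), control)
  out <- list()
  for (tr in treatments) {
    for (tp in sort(unique(samples$time[samples$condition == tr]))) {
      ctrl_cols <- samples$sample[samples$condition == control &
                                    samples$time == tp]
      trt_cols <- samples$sample[samples$condition == tr &
                                   samples$time == tp]
      if (length(ctrl_cols) < 2 || length(trt_cols) < 2) {
        stop(sprintf("contrast %s@%s needs >= 2 replicates per arm", tr, tp))
      }
      X <- mat[, c(ctrl_cols, trt_cols), drop = FALSE]
      nc <- rowSums(!is.na(X[, ctrl_cols, drop = FALSE]))
      nt <- rowSums(!is.na(X[, trt_cols, drop = FALSE]))
      pres <- (nc + nt) / ncol(X)
      keep <- pres > presence_min & nc >= 2 & nt >= 2
      if (!any(keep)) next
      Xk <- X[keep, , drop = FALSE]
      nck <- nc[keep]
      ntk <- nt[keep]
      mc <- rowMeans(Xk[, ctrl_cols, drop = FALSE], na.rm = TRUE)
      mt <- rowMeans(Xk[, trt_cols, drop = FALSE], na.rm = TRUE)
      ssc <- rowSums((Xk[, ctrl_cols, drop = FALSE] - mc)^2, na.rm = TRUE)
      sst <- rowSums((Xk[, trt_cols, drop = FALSE] - mt)^2, na.rm = TRUE)
      df <- nck + ntk - 2
      ok <- df > 0
      s2 <- ifelse(ok, (ssc + sst) / pmax(df, 1), NA)
      if (is.null(prior_df)) {
        sq <- limma::squeezeVar(s2[ok], df[ok])
        d0 <- sq$df.prior
        s2p <- sq$var.prior
        s2_post <- s2
        s2_post[ok] <- sq$var.post
      } else if (is.infinite(prior_df)) {
        d0 <- Inf
        s2p <- if (is.null(prior_var)) mean(s2[ok]) else prior_var
        s2_post <- ifelse(ok, s2p, NA)
      } else if (prior_df == 0) {
        d0 <- 0
        s2p <- NA_real_
        s2_post <- s2
      } else {
        d0 <- prior_df
        s2p <- if (is.null(prior_var)) mean(s2[ok]) else prior_var
        s2_post <- ifelse(ok, (d0 * s2p + df * s2) / (d0 + df), NA)
      }
      lfc <- mt - mc
      se <- sqrt(s2_post * (1 / nck + 1 / ntk))
      tstat <- lfc / se
      df_total <- df + (if (length(d0) == 1) d0 else {
        dd <- rep(NA_real_, length(df))
        dd[ok] <- d0
        dd
      })
      p <- 2 * stats::pt(-abs(tstat), df_total)
      res <- data.frame(
        feature = rownames(Xk), condition = tr, time = tp,
        log2fc = lfc, t = tstat, df_total = df_total, p = p,
        q = stats::p.adjust(p, "BH"),
        n_control = nck, n_treat = ntk, s2 = s2, s2_post = s2_post,
        row.names = NULL, stringsAsFactors = FALSE)
      res <- res[ok, , drop = FALSE]
      attr(res, "df_prior") <- d0
      attr(res, "s2_prior") <- s2p
      out[[sprintf("%s@%s", tr, tp)]] <- res
    }
  }
  combined <- do.call(rbind, out)
  rownames(combined) <- NULL
  attr(combined, "contrasts") <- lapply(out, function(x) {
    list(df_prior = attr(x, "df_prior"), s2_prior = attr(x, "s2_prior"))
  })
  combined
}
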