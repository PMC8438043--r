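test_that("K-GG peptides map onto protein lysine coordinates", {
  proteins <- data.frame(
    accession = c("P1", "P2"),
    sequence = c("AAAAGGKAAR", "CCAAGGKAAR"))
  peptides <- data.frame(peptide_id = c("pepA", "pepB"),
                         sequence = c("GGKAAR", "AAGGKAAR"),
                         mods = c("KGG@3", "KGG@5"))
  links <- data.frame(peptide_id = c("pepA", "pepA", "pepB"),
                      accession = c("P1", "P2", "P1"),
                      start = c(5L, 5L, 3L))
  sites <- map_kgg_sites(peptides, links, proteins)
  # pepA: start 5 + position 3 - 1 = K7 in both isoforms, one record
  shared <- sites[sites$protein_group == "P1;P2", ]
  expect_equal(nrow(shared), 1)
  expect_equal(shared$positions, "7;7")
  # pepB covers the same K7 of P1 from a different span
  solo <- sites[sites$protein_group == "P1", ]
  expect_equal(solo$positions, "7")
  expect_equal(solo$n_peptides, 1)
  # wrong residue is a hard, contextual error
  bad_links <- data.frame(peptide_id = "pepA", accession = "P1",
                          start = 2L)
  expect_error(map_kgg_sites(peptides[1, ], bad_links, proteins),
               "P1.*not K")
})

test_that("distinct peptides covering one K merge their evidence", {
  proteins <- data.frame(accession = "P1", sequence = "AAAAGGKAARLL")
  peptides <- data.frame(peptide_id = c("short", "long"),
                         sequence = c("GGKAAR", "GGKAARLL"),
                         mods = c("KGG@3", "KGG@3"))
  links <- data.frame(peptide_id = c("short", "long"),
                      accession = "P1", start = 5L)
  sites <- map_kgg_sites(peptides, links, proteins)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$n_peptides, 2)
  expect_equal(sites$peptide_ids, "long;short")
})

test_that("site mapping round-trips through digestion and enumeration", {
  for (seed in 1:4) {
    prot <- random_proteome(3, c(120, 220), seed = seed)
    space <- build_search_space(prot, charges = 2, kgg_only = TRUE)
    peps <- space$precursors[!duplicated(space$precursors$peptide_id), ]
    sites <- map_kgg_sites(peps, space$links, prot)
    # every mapped position is a lysine in its protein (validated inside
    # map_kgg_sites); additionally the planted positions round-trip
    for (i in seq_len(nrow(sites))) {
      accs <- strsplit(sites$protein_group[i], ";")[[1]]
      pos <- as.integer(strsplit(sites$positions[i], ";")[[1]])
      for (j in seq_along(accs)) {
        expect_equal(substring(prot$sequence[prot$accession == accs[j]],
                               pos[j], pos[j]), "K")
      }
    }
    expect_gt(nrow(sites), 0)
  }
})

test_that("protein inference collapses, covers and absorbs", {
  # greedy/exact cover by hand: P2 is a subset of P1, P3 stands alone
  inc <- data.frame(
    peptide_id = c("a", "b", "c", "a", "d"),
    accession = c("P1", "P1", "P1", "P2", "P3"))
  out <- infer_proteins(inc)
  expect_setequal(out$groups$group_id, c("P1", "P3"))
  # indistinguishable proteins form one group
  inc2 <- data.frame(peptide_id = c("a", "b", "a", "b"),
                     accession = c("P1", "P1", "P2", "P2"))
  expect_equal(infer_proteins(inc2)$groups$group_id, "P1;P2")
  # disjoint sets: one group per protein, all peptides unique
  inc3 <- data.frame(peptide_id = c("a", "b"), accession = c("P1", "P2"))
  out3 <- infer_proteins(inc3)
  expect_equal(nrow(out3$groups), 2)
  expect_false(any(out3$assignment$shared))
  # shared peptides are flagged
  inc4 <- data.frame(peptide_id = c("a", "b", "a", "c"),
                     accession = c("P1", "P1", "P2", "P2"))
  out4 <- infer_proteins(inc4)
  sh <- out4$assignment
  expect_true(all(sh$shared[sh$peptide_id == "a"]))
})

test_that("inference matches the exhaustive minimal cover on small
           instances", {
  set.seed(202)
  for (i in 1:60) {
    n_prot <- sample(3:12, 1)
    n_pep <- sample(4:15, 1)
    inc <- expand.grid(peptide_id = sprintf("pep%02d", seq_len(n_pep)),
                       accession = sprintf("PR%02d", seq_len(n_prot)),
                       stringsAsFactors = FALSE)
    inc <- inc[runif(nrow(inc)) < 0.25, ]
    if (nrow(inc) == 0) next
    out <- infer_proteins(inc)
    sets <- split(inc$peptide_id, inc$accession)
    # indistinguishable proteins count once, as in the implementation
    usets <- unique(lapply(sets, sort))
    expect_equal(nrow(out$groups),
                 brute_min_cover_size(usets, unique(inc$peptide_id)))
    # chosen groups explain every peptide
    expect_setequal(unique(out$assignment$peptide_id),
                    unique(inc$peptide_id))
  }
})

test_that("moderated t reduces to its closed-form limits", {
  tt <- timecourse_truth(n_proteins = 120, n_degradative = 10,
                         n_nondegradative = 10, n_down_only = 5,
                         n_weak = 5, times = c(15, 360), seed = 13)
  tc <- simulate_timecourse(tt)
  qt <- median_scale(tc$ubi)
  d0 <- moderated_ttest(qt, prior_df = 0)
  dinf <- moderated_ttest(qt, prior_df = Inf)
  dhat <- moderated_ttest(qt)
  # d0 = 0: ordinary two-sample pooled t, feature by feature
  mat <- log2(qt$mat)
  ctrl <- qt$samples$sample[qt$samples$condition == "DMSO" &
                              qt$samples$time == 15]
  trt <- qt$samples$sample[qt$samples$condition == "drug" &
                             qt$samples$time == 15]
  sub <- d0[d0$time == 15, ]
  for (f in sub$feature[1:20]) {
    a <- stats::na.omit(mat[f, trt])
    b <- stats::na.omit(mat[f, ctrl])
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(sub$t[sub$feature == f], unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(sub$p[sub$feature == f], ref$p.value, tolerance = 1e-12)
  }
  # d0 = Inf: every variance equals the prior variance
  s2p <- attr(dinf, "contrasts")[[1]]$s2_prior
  subi <- dinf[dinf$time == 15, ]
  expect_true(all(abs(subi$s2_post - s2p) < 1e-12))
  expect_equal(subi$t,
               subi$log2fc / sqrt(s2p * (1 / subi$n_control +
                                           1 / subi$n_treat)),
               tolerance = 1e-12)
  # the estimated prior lies between the limits and shrinks towards it
  d0_hat <- attr(dhat, "contrasts")[[1]]$df_prior
  expect_gt(d0_hat, 0)
  sub_h <- dhat[dhat$time == 15, ]
  m <- match(sub_h$feature, sub$feature)
  between <- (sub_h$s2_post >= pmin(sub$s2[m], s2p) - 1e-12) &
    (sub_h$s2_post <= pmax(sub$s2[m], s2p) + 1e-12)
  expect_true(mean(between, na.rm = TRUE) > 0.99)
})

test_that("BH q-values agree with the textbook computation", {
  set.seed(19)
  p <- runif(500)^2
  expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  tt <- timecourse_truth(n_proteins = 60, n_degradative = 5,
                         n_nondegradative = 5, n_down_only = 3, n_weak = 3,
                         times = c(15), seed = 3)
  tc <- simulate_timecourse(tt)
  d <- moderated_ttest(median_scale(tc$ubi))
  expect_equal(d$q, brute_bh(d$p), tolerance = 1e-12)
})

fake_diff <- function(feature, time, log2fc, q) {
  data.frame(feature = feature, condition = "drug", time = time,
             log2fc = log2fc, t = 0, df_total = 6, p = q, q = q,
             n_control = 4, n_treat = 4, s2 = 1, s2_post = 1)
}

test_that("substrate verdicts follow the site and degradation gates", {
  ubi <- rbind(
    fake_diff("siteA", 15, 1.5, 0.01), # strong early site, protein drops
    fake_diff("siteB", 15, 2.0, 0.001), # strong site, protein stable
    fake_diff("siteC", 15, 0.4, 0.30), # no significant site
    fake_diff("siteD", 15, 1.8, 0.004)) # site up, protein not measured
  prot <- rbind(
    fake_diff("PA", 360, log2(0.65), 0.02),
    fake_diff("PB", 360, log2(0.95), 0.6),
    fake_diff("PC", 360, log2(0.5), 0.001))
  fmap <- c(siteA = "PA", siteB = "PB", siteC = "PC", siteD = "PD")
  calls <- classify_substrates(ubi, fmap, prot)
  v <- setNames(calls$verdict, calls$protein_group)
  expect_equal(unname(v["PA"]), "degradative")
  expect_equal(unname(v["PB"]), "non-degradative")
  expect_equal(unname(v["PC"]), "unregulated") # gate ordering
  expect_equal(unname(v["PD"]), "degradation_unknown")
  expect_equal(calls$min_protein_relative_level[
    calls$protein_group == "PA"], 0.65, tolerance = 1e-12)
  # endpoint-only switch: a drop before the last time point is ignored
  prot2 <- rbind(fake_diff("PA", 60, log2(0.6), 0.01),
                 fake_diff("PA", 360, log2(0.95), 0.8))
  calls2 <- classify_substrates(ubi[1, ], fmap[1], prot2,
                                endpoint_only = TRUE)
  expect_equal(calls2$verdict, "non-degradative")
  calls3 <- classify_substrates(ubi[1, ], fmap[1], prot2)
  expect_equal(calls3$verdict, "degradative")
})

test_that("protein groups disaggregate for proteome matching", {
  ubi <- fake_diff("siteA", 15, 1.6, 0.01)
  prot <- fake_diff("Q2", 360, log2(0.7), 0.01)
  calls <- classify_substrates(ubi, c(siteA = "Q1;Q2"), prot,
                               prot_protein = c(Q2 = "Q2"))
  expect_equal(calls$verdict, "degradative")
})

test_that("peaking time is the argmax of the averaged profile", {
  prof <- rbind(f1 = c(0.5, 2.0, 1.0), f2 = c(1.0, 1.0, 3.0))
  colnames(prof) <- c(15, 60, 360)
  expect_equal(unname(peaking_time(prof, list(p = "f1"))), 60)
  expect_equal(unname(peaking_time(prof, list(p = "f2"))), 360)
  # two features: argmax of the pointwise mean, checked directly
  expect_equal(unname(peaking_time(prof, list(p = c("f1", "f2")))),
               c(15, 60, 360)[which.max(colMeans(prof))])
  # ties resolve to the earliest time
  tied <- rbind(f = c(2, 2, 1))
  colnames(tied) <- c(15, 60, 360)
  expect_equal(unname(peaking_time(tied, list(p = "f"))), 15)
})

test_that("inhibitor consensus requires k of n compounds", {
  mk <- function(q1, q2) rbind(fake_diff("s1", 60, 1.5, q1),
                               fake_diff("s2", 60, 1.5, q2))
  diffs <- list(FT671 = mk(0.01, 0.01), FT827 = mk(0.01, 0.2),
                GNE6640 = mk(0.01, 0.2), GNE6776 = mk(0.2, 0.01))
  fmap <- c(s1 = "PA", s2 = "PB")
  out <- inhibitor_consensus(diffs, fmap, k = 3)
  expect_equal(out$consensus, "PA") # PA in 3 of 4, PB in 2 of 4
  expect_equal(inhibitor_consensus(diffs, fmap, k = 3,
                                   reference = "PA")$overlap, 1)
  expect_equal(inhibitor_consensus(diffs, fmap, k = 3,
                                   reference = c("PA", "PX"))$overlap, 0.5)
  expect_error(inhibitor_consensus(diffs, fmap, k = 5), "exceeds")
})

test_that("interactor tables filter on evidence and keep empty
           annotations", {
  calls <- data.frame(protein_group = c("PA", "PB;PC"),
                      verdict = c("degradative", "unregulated"),
                      earliest_up_time = c(15, NA),
                      max_site_log2fc = c(2, 0.1),
                      min_protein_relative_level = c(0.6, 1),
                      peaking_time = c(15, NA), n_sig_sites = c(2, 0))
  inter <- data.frame(accession = c("PA", "PB", "PZ", "PQ"),
                      evidence = c(5, 4, 6, 3))
  out <- annotate_interactors(inter, calls, min_evidence = 4)
  expect_setequal(out$accession, c("PA", "PB", "PZ"))
  expect_equal(out$peaking_time[out$accession == "PA"], 15)
  expect_true(out$significant_site[out$accession == "PA"])
  expect_false(out$significant_site[out$accession == "PZ"]) # no calls
  expect_false(out$significant_site[out$accession == "PB"])
})
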