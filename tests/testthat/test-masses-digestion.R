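test_that("tryptic digestion with trypsin/P semantics enumerates spans", {
  d0 <- digest_protein("MKGGAKR", max_missed = 0, length_filter = FALSE)
  expect_equal(d0$sequence, c("MK", "GGAK", "R"))
  expect_equal(d0$start, c(1, 3, 7))
  expect_equal(d0$missed_cleavages, c(0, 0, 0))

  d1 <- digest_protein("MKGGAKR", max_missed = 1, length_filter = FALSE)
  expect_setequal(d1$sequence, c("MK", "GGAK", "R", "MKGGAK", "GGAKR"))
  expect_equal(d1$start[d1$sequence == "GGAKR"], 3)

  # cleavage happens before proline too
  dp <- digest_protein("AKPGGR", max_missed = 0, length_filter = FALSE)
  expect_true("AK" %in% dp$sequence)

  # no cleavage sites: the whole sequence is one span
  expect_equal(
    digest_protein("GGAGGA", max_missed = 0, length_filter = FALSE)$sequence,
    "GGAGGA")

  expect_equal(nrow(digest_protein("", length_filter = FALSE)), 0)
  expect_error(digest_protein("GGXGG"), "unknown residue 'X' at position 3")
})

test_that("digestion tiles the protein exactly at zero missed cleavages", {
  for (seed in 1:5) {
    prot <- random_proteome(1, length_range = c(80, 150), seed = seed)
    d <- digest_protein(prot$sequence, max_missed = 0,
                        length_filter = FALSE)
    d <- d[order(d$start), ]
    expect_equal(d$start[1], 1)
    expect_equal(d$end[nrow(d)], nchar(prot$sequence))
    if (nrow(d) > 1) {
      expect_equal(d$start[-1], d$end[-nrow(d)] + 1)
    }
    expect_equal(paste(d$sequence, collapse = ""), prot$sequence)
    # idempotent / deterministic
    expect_identical(d, {
      d2 <- digest_protein(prot$sequence, max_missed = 0,
                           length_filter = FALSE)
      d2[order(d2$start), ]
    })
  }
})

test_that("variable-modification enumeration respects the rules", {
  # internal K gets the remnant, C-terminal R is not a site
  f <- enumerate_modified_forms("GGAKR", start = 3)
  expect_setequal(f$mods, c("", "KGG@4"))
  # C-terminal K never carries the remnant
  expect_equal(enumerate_modified_forms("GGAK", start = 3)$mods, "")
  # binomial enumeration with the cap: 1 + 3 + 3 forms
  f2 <- enumerate_modified_forms("MKMK", start = 3,
                                 variable_mods = c("KGG", "OxM"))
  expect_equal(nrow(f2), 7)
  # N-terminal acetylation only for protein position 1 or 2
  expect_true("NtAc@1" %in%
                enumerate_modified_forms("MAGR", start = 1)$mods)
  expect_false(any(grepl("NtAc",
                         enumerate_modified_forms("MAGR", start = 5)$mods)))
})

test_that("enumeration count matches the combinatorial oracle", {
  set.seed(42)
  aa <- names(residue_masses())
  for (i in 1:25) {
    span <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    start <- sample(c(1, 2, 50), 1)
    f <- enumerate_modified_forms(span, start = start)
    expect_equal(nrow(f), brute_form_count(span, start), info = span)
    expect_equal(anyDuplicated(f$mods), 0)
  }
})

test_that("masses come from atomic composition", {
  expect_equal(peptide_mass("GG"), 132.05349, tolerance = 1e-4 / 132)
  # the K-GG remnant delta equals two glycine residues, ~114.0429 Da
  gg <- 2 * unname(residue_masses()["G"])
  expect_equal(peptide_mass("GGAKR", "KGG@4") - peptide_mass("GGAKR"), gg)
  expect_equal(unname(modification_deltas()["KGG"]), gg, tolerance = 1e-12)
  # fixed carbamidomethylation on every C
  expect_equal(peptide_mass("ACA") - peptide_mass("AAA"),
               residue_masses()[["C"]] - residue_masses()[["A"]] +
                 modification_deltas()[["CAM"]])
  expect_error(peptide_mass("GGZ"), "unknown residue")
})

test_that("b/y fragment arithmetic satisfies the conservation identity", {
  cases <- list(c("GGAKR", "KGG@4"), c("MKGGAKR", "KGG@2;OxM@1"),
                c("LVEYK", ""))
  for (cs in cases) {
    f <- fragment_ions(cs[1], cs[2])
    nm <- peptide_mass(cs[1], cs[2])
    n <- nchar(cs[1])
    for (i in seq_len(n - 1)) {
      b <- f$mz[f$series == "b" & f$index == i & f$charge == 1]
      y <- f$mz[f$series == "y" & f$index == n - i & f$charge == 1]
      expect_equal(b + y, nm + 2 * 1.00727646688, tolerance = 1e-12)
    }
  }
})

test_that("fragment site flags follow span membership", {
  f <- fragment_ions("GGAKR", "KGG@4")
  expect_true(f$contains_mod_site[f$frag_id == "y2^1"])
  expect_false(f$contains_mod_site[f$frag_id == "b2^1"])
  expect_false(any(f$contains_other_candidate_site)) # single K, modified
  # unmodified K elsewhere flags the other-candidate-site bit
  f2 <- fragment_ions("MKGGAKR", "KGG@6")
  expect_true(f2$contains_other_candidate_site[f2$frag_id == "b2^1"])
  expect_false(f2$contains_mod_site[f2$frag_id == "b2^1"])
  expect_true(f2$contains_mod_site[f2$frag_id == "y2^1"])
  expect_error(fragment_ions("G", ""), "too short")
})

test_that("K-GG peptides always carry a missed cleavage in the space", {
  space <- build_search_space(random_proteome(5, c(150, 250), seed = 3),
                              charges = 2, kgg_only = TRUE)
  expect_gt(nrow(space$precursors), 0)
  expect_true(all(space$precursors$missed_cleavages >= 1))
  # precursor m/z consistency: (M + z * proton) / z
  i <- seq_len(min(50, nrow(space$precursors)))
  m <- vapply(i, function(k) {
    peptide_mass(space$precursors$sequence[k], space$precursors$mods[k])
  }, numeric(1))
  z <- space$precursors$charge[i]
  expect_equal(space$precursors$mz[i], (m + z * 1.00727646688) / z,
               tolerance = 1e-9)
})

test_that("FASTA round trip parses UniProt-style headers", {
  prot <- random_proteome(4, c(60, 90), seed = 9)
  prot$description <- paste("synthetic protein", seq_len(4))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(prot, path)
  back <- read_protein_fasta(path)
  expect_equal(back$accession, prot$accession)
  expect_equal(back$sequence, prot$sequence)
  # plain headers fall back to the first token
  writeLines(c(">simple_id some description", "PEPTIDEK"), path)
  expect_equal(read_protein_fasta(path)$accession, "simple_id")
  writeLines(c(">bad", "PEPTXDEK"), path)
  expect_error(read_protein_fasta(path), "non-canonical")
  writeLines(c(">bad", "PEPTXDEK", ">ok|ACC2|N", "PEPTIDEK"), path)
  expect_warning(kept <- read_protein_fasta(path, strict = FALSE),
                 "dropping")
  expect_equal(kept$accession, "ACC2")
})

test_that("pseudo-reverse decoys preserve composition and flag collisions", {
  prot <- data.frame(accession = "P1",
                     sequence = "MAGGAKRGGAKRLVEYKAGAR")
  space <- build_search_space(prot, charges = 2, length_filter = FALSE,
                              min_length = 4)
  dec <- generate_decoys(space)
  tg <- space$precursors
  dc <- dec$precursors
  # C-terminal residue fixed, rest reversed
  expect_equal(substring(dc$sequence, nchar(dc$sequence)),
               substring(tg$sequence, nchar(tg$sequence)))
  expect_equal(vapply(strsplit(dc$sequence, ""), function(x) {
    paste(sort(x), collapse = "")
  }, ""), vapply(strsplit(tg$sequence, ""), function(x) {
    paste(sort(x), collapse = "")
  }, ""))
  # the named example: GGAKR with the remnant turns into KAGGR, KGG on K
  i <- which(tg$sequence == "GGAKR" & tg$mods == "KGG@4")[1]
  expect_equal(dc$sequence[i], "KAGGR")
  expect_equal(dc$mods[i], "KGG@1")
  expect_true(all(dc$decoy))
  # mass shift applies iff the reversal collides with a target sequence
  coll <- dc$collision
  if (any(coll)) {
    j <- which(coll)[1]
    expect_gt(dc$mz[j],
              precursor_mz(peptide_mass(dc$sequence[j], dc$mods[j]),
                           dc$charge[j]))
  }
  # decoy-of-decoy is refused
  expect_error(generate_decoys(dec), "targets only")
})
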