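Package: ubidia
Title: Correlation-Based Identification and Quantification of
    Ubiquitination Sites in DIA Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for diglycine-remnant (K-GG) ubiquitinomics with
    data-independent acquisition (DIA) mass spectrometry: in-silico tryptic
    digestion and modified-peptide enumeration with composition-derived
    monoisotopic masses, fragment co-elution correlation scoring of candidate
    elution peaks with site-aware score components, two-pass target-decoy
    identification with global and run-specific FDR control, label-free
    quantification with mean and MaxLFQ aggregation, K-GG peptide-to-site
    mapping with parsimonious protein inference, moderated differential
    statistics for inhibitor time courses, and integration of ubiquitinome
    with proteome dynamics to separate degradative from non-degradative
    deubiquitinase substrates. A seeded synthetic DIA simulator with known
    ground truth allows the whole pipeline to be exercised and validated
    without raw instrument data.
License: MIT + file LICENSE
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
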