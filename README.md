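# ubidia

Correlation-based identification and quantification of ubiquitination
sites in DIA proteomics, with time-resolved substrate calling.

## What it does, and for whom

Ubiquitination is read out by mass spectrometry through the di-glycine
remnant (K-GG) left on the modified lysine after tryptic digestion. In
data-independent acquisition (DIA), every fragment ion of a peptide traces
an elution profile across consecutive cycles, and co-elution — high
Pearson correlation between fragment profiles — is the primary evidence
that a peptide is really there. `ubidia` is for computational proteomics
researchers who want a transparent, fully testable implementation of that
evidence model specialized to ubiquitinomics:

* in-silico tryptic digestion (trypsin/P) and modified-peptide
  enumeration with composition-derived monoisotopic masses;
* candidate elution-peak scoring: a "best" fragment `f*` maximizing
  `sum_g r(f, g)` over fragment profiles, and correlation-sum score
  components partitioned by site content —
  `S_site_determining = sum r(f, f*)` over fragments containing the
  modified K and no other candidate K, and its three companion classes,
  plus MS1 corroboration;
* two-pass target-decoy search with global and run-specific 1% FDR
  (`q(t) = min_{t' <= t} #decoys(t') / max(1, #targets(t'))`), pseudo-
  reversed decoys, and match-between-runs via per-run linear
  retention-time calibration;
* label-free quantification: median sample scaling, presence-aware mean
  aggregation, and MaxLFQ (median pairwise log-ratios `r_ij`, least
  squares on `a_i - a_j = r_ij` per connected component);
* K-GG peptide-to-site mapping, parsimonious protein inference
  (ID-Picker-style, exact on small components), moderated t-statistics
  with empirical-Bayes variance shrinkage (`t = b / (s_post * SE)`,
  `df = d + d0`), BH q-values per contrast;
* substrate integration: a protein is a *degradative* substrate when a
  site is significantly up more than twofold at the earliest treatment
  time and the protein is significantly down below 0.8x of control later;
  *non-degradative* when only the site condition holds — plus peaking
  times, k-of-n inhibitor consensus and interactor annotation.

A seeded synthetic DIA simulator with planted ground truth (co-eluting
Gaussian traces at 4-5 points per peak, interference, log-normal noise at
10% CV, intensity-dependent dropout, planted time-course effects) makes
every stage testable without instrument data.

## Worked example

```r
library(ubidia)

cfg <- default_config(n_proteins = 40, n_present = 100, n_absent = 100)
bm  <- run_benchmark(cfg, seed = 1)
round(bm$metrics, 4)
#>                 fdp_at_1pct                  n_reported
#>                      0.0000                     95.0000
#>           calibration_slope median_abs_log2_ratio_error
#>                      0.4636                      0.1316
#>              n_sites_mapped       substrate_sensitivity
#>                     92.0000                      0.9500
#>         substrate_precision           median_cv_percent
#>                      1.0000                      9.0385
#>            frac_cv_below_20
#>                      1.0000
```

Reading: at a nominal 1% precursor FDR, 95 of the 100 truly present
precursors are reported with zero false discoveries; the realized FDP
tracks roughly half the nominal q across 1-10% (the usual target-decoy
conservatism when half the targets are real); quantification recovers the
planted twofold between-run changes to ~0.13 log2 units at this noise
level; planted degradative substrates are recovered at 95% sensitivity
with no false calls; per-feature CVs center near the simulated 10%. At the full
benchmark scale (2,000 present + 2,000 absent precursors) the same
quantities are tighter; `scripts/acceptance.R` reports them.

There is also a thin command-line wrapper:

```sh
Rscript inst/cli/ubidia simulate --seed 7 --dir work/
Rscript inst/cli/ubidia search   --dir work/
Rscript inst/cli/ubidia quant    --dir work/
Rscript inst/cli/ubidia benchmark --seed 7 --out work/metrics.json
```

## Package layout

* `R/` — digestion/masses, simulator, scoring, identification,
  quantification, site analysis, statistics, substrate calling,
  benchmark orchestration
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
* `vignettes/ubidia-methods.Rmd` — the model, its assumptions, tunable
  parameters, generator design and known limitations
* `inst/cli/ubidia` — command-line wrapper
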