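---
title: "Correlation-based K-GG site identification and time-resolved substrate calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based K-GG site identification and time-resolved substrate calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubidia)
```

## The problem

Ubiquitination leaves a di-glycine stump (the K-GG remnant) on the modified
lysine after tryptic digestion of the conjugate; detecting and quantifying
K-GG peptides is how mass spectrometry reads out ubiquitin signaling. In
data-independent acquisition (DIA), every precursor in a wide isolation
window co-fragments in each cycle, so a peptide is not matched to a single
spectrum but to a *series* of consecutive spectra in which each fragment
ion traces an elution profile. Fragments of the same peptide co-elute, so
their profiles correlate; interfering signal from co-fragmenting peptides
does not. `ubidia` implements this evidence model end to end for
ubiquitinomics: search-space construction, correlation scoring with
site-aware components, two-pass target-decoy FDR control, label-free
quantification, site mapping and protein inference, moderated time-course
statistics, and the integration of ubiquitinome with proteome dynamics
that separates degradative from non-degradative deubiquitinase substrates.

Everything is validated on a seeded synthetic DIA simulator with known
ground truth, so no instrument data is required to exercise or test any
stage.

## Masses and the search space

All residue and modification masses are computed from a single table of
monoisotopic element masses; nothing downstream hard-codes a peptide- or
modification-level constant. The di-glycine remnant delta is therefore
`2 x 57.02146 = 114.04293` Da (composition C4H6N2O2). Literature sometimes
quotes 114.0249 Da for this delta when comparing it to
di-carbamidomethylation; composition arithmetic does not support that
value for two glycine residues, and this package always uses the
composition-derived mass.

Digestion uses trypsin/P semantics (cleavage C-terminal to K/R, including
before proline), a default of one missed cleavage for the DIA search
space, and length bounds of 7-30 residues. A remnant-bearing lysine is
treated as a blocked cleavage site, with two consequences: the K-GG
remnant is never placed on a span's C-terminal lysine, and every
K-GG-bearing peptide necessarily carries at least one missed cleavage.
Variable modifications (at most two per peptide) are the K-GG remnant,
methionine oxidation and protein N-terminal acetylation; the latter is
offered only to spans starting at protein position 1 or 2 (the
Met-cleavage convention). Carbamidomethyl-cysteine is fixed. "Other
candidate site" in the fragment annotations means an *unmodified,
non-C-terminal* lysine: a residue that could in principle have carried the
remnant. A C-terminal lysine cannot (cleavage would have been blocked), so
it is not counted as a candidate.

Decoys are pseudo-reversed (sequence reversed with the C-terminal residue
fixed, modifications carried with their residues), which preserves tryptic
character, length, fragment count and modification content — the decoy and
its target differ only in fragment-span geometry. Decoys colliding with a
target sequence are mass-shifted by a fixed 11 Da offset and flagged.

## Scoring

For each candidate elution peak of each precursor (local maxima of the
lightly smoothed summed fragment trace; smoothing width 3 cycles, windows
extended to the surrounding minima and clipped at 8 cycles half-width),
one fragment is designated *best*: the one whose profile maximizes the
summed Pearson correlation to all other fragments. Its trace stands in
for the peptide's true elution profile. Evidence for the modified peptide
is then summarized as sums of correlations to the best fragment,
partitioned by the two site flags into four disjoint classes:

* `S_site_determining` — fragments containing the modified lysine and no
  other candidate site (the class that uniquely localizes the site),
* `S_site_containing` — containing the modified lysine and another
  candidate site,
* `S_other_site` — containing only other candidate sites,
* `S_shared` — containing neither,

plus the MS1-to-best-fragment correlation and the count of fragments
correlating above 0.75. The four-way partition is one concrete reading of
"fragments that contain / do not contain the modified residue / other
potential sites in different combinations"; it spans all combinations of
the two binary conditions. Correlations are computed on the candidate
window only, localizing the evidence; constant traces get r = 0 by
contract (not NaN), which keeps sums over absent fragments well defined.
Ties in the best-fragment argmax resolve to the lower fragment index
(b before y, then series index, then charge) so that floating-point ties
cannot make results run-order dependent.

The composite score is a transparent substitute for the reference
engine's neural network, which is out of scope here: a logistic
regression on the six components, trained Percolator-style (rank by the
equal-weight sum, take targets confident at 1% against decoys, fit,
re-score). If the classes separate degenerately — which routinely happens
on clean synthetic data — the scorer falls back to the flagged
equal-weight sum. Only the best-scoring candidate per precursor and run
is retained.

## Two-pass FDR control

Q-values use the plain target-decoy estimator `#decoys / max(1, #targets)`
above each score threshold, monotonized by taking the minimum over more
permissive thresholds; no +1 correction is applied, matching the
large-list regime the tool targets. The two-pass workflow mirrors
library-free DIA practice: pass 1 scores everything; precursors passing
the global (experiment-wide) *and* at least one run-specific 1% filter
form an internal library with a reference retention time (apex in the
best-scoring run); pass 2 re-scores only library precursors inside
retention-time windows of +/- 3 residual SD around a per-run linear
calibration fitted on pass-1 apexes (floor: 3 cycles). A precursor can
therefore be reported in a run where only pass 2 found it — the
match-between-runs semantics. The run-specific filter is applied at both
passes. The paired decoy of every library target enters pass 2 with a
reference from its own pass-1 apex, preserving the 1:1 pairing and the
exchangeability between decoys and absent targets on which the FDR
estimate rests.

Two measurement choices matter when validating calibration on synthetic
data. First, half of the benchmark's targets are truly present, so the
decoy count over-estimates the number of false candidates by roughly the
inverse of the null fraction; the realized false-discovery proportion
(FDP) tracks about half the nominal q, which is the familiar conservatism
of target-decoy FDR at low null fractions, not a defect. Second, the
calibration *curve* (FDP versus nominal q at 1, 5 and 10%) is measured on
the single-pass q-values over the full searched space: after the
library truncation at 1%, almost no null precursors survive into pass 2,
so realized FDP at looser thresholds is structurally deflated there and
would not measure the estimator.

## Quantification

The reference engine's internal quantification is unpublished; the
documented substitute is deliberately simple: the precursor quantity is
the window sum of the mean trace of the k = 3 fragments most correlated
with the best fragment (correlations rounded to 9 decimals before
ranking, so exact ties resolve by fragment index rather than float
jitter). The fragment set is chosen once per precursor, in its
best-scoring run, and reused in every run: fragment relative intensities
differ several-fold, so letting each run pick its own top-k under noise
would inject fragment-set mismatch straight into between-run ratios. Matrices are normalized by median sample scaling (each sample
multiplied by the ratio of the grand median of sample medians to its own
median — an idempotent map), and precursors aggregate to peptides two
ways: presence-aware arithmetic means of normalized intensities, and
MaxLFQ (median pairwise log-ratios over shared precursors, least-squares
solve per connected component of the ratio graph). MaxLFQ leaves the
overall scale free; it is fixed here so that the summed output intensity
equals the summed input intensity over each component's samples, an
auditable rule that reduces to the identity for single-precursor
peptides. The minimum number of shared precursors per sample pair
defaults to 1 (peptide-level aggregation rarely has more), unlike
protein-level conventions. Coefficients of variation are computed on raw,
unlogged intensities, as is conventional for MS precision diagnostics.

## Moderated statistics

Each time point is tested as an unpaired two-arm contrast (drug versus
its time-matched vehicle control) on log2 intensities, with features
required to be present in strictly more than half of the contrast's
samples and at least twice per arm. Residual variances are shrunk by
empirical Bayes towards a prior estimated from all features in the
contrast by the scaled-F moment method (trigamma inversion, via
`limma::squeezeVar`); the moderated t has `df + d0` degrees of freedom
and Benjamini-Hochberg q-values are computed within each contrast,
matching the per-time-point volcano convention. The `prior_df` argument
exposes the two closed-form limits — `0` gives the ordinary pooled t-test
exactly, `Inf` fully shrinks to the prior variance — which the test suite
uses as anchors. A shared prior per contrast (not a global
multi-time-point model) keeps each time point's inference
self-contained.

## Substrate calling

A protein group is called a *degradative* substrate when at least one of
its K-GG features is significant (q < 0.05) with log2 fold change > 1 at
the earliest treatment time, and the protein is significant and below
0.8x of control ("downregulated by more than 20%") at some treatment
time; *non-degradative* when only the site condition holds; *unregulated*
otherwise. Whether the degradation condition should consider any time
point or only the endpoint is ambiguous in the field's phrasing "over the
time course"; the default is any post-treatment time point, switchable to
endpoint-only (`endpoint_only = TRUE`). Ubiquitinome and proteome tables
are matched by disaggregating protein groups into individual accessions.
Proteins whose parent is absent from the proteome (a rapidly degraded
protein can fall below the detection limit) are reported distinctly as
`degradation_unknown` rather than silently failing the condition. The
peaking time of the ubiquitin signal is the argmax of the pointwise mean
of the significant features' fold-change profiles, ties to the earliest
time. Multi-inhibitor consensus requires k of n compounds (default 3 of
4) to show a significant, more-than-twofold site; interactor tables are
filtered at >= 4 supporting studies and annotated, with partners lacking
significant sites retained with empty annotation.

Protein inference collapses proteins with identical peptide sets into
indistinguishable groups and then selects a minimal explaining set per
connected component: exhaustively (deterministic tie-breaks: larger total
peptide set, then lexicographic accessions) for components of up to 14
groups, greedily (most unexplained peptides first, same tie-breaks) for
larger ones. Plain greedy cover can be suboptimal on small adversarial
instances, and parsimony is the stated goal of the ID-Picker-style
procedure, so exactness on small components is preferred where it is
affordable; the greedy path is retained for scale.

## The synthetic-data generator

The simulator emulates what the scoring model needs from DIA data, and
deliberately nothing more:

* tryptic K-GG peptides from a random proteome with realistic K/R
  content;
* Gaussian co-eluting fragment traces (relative fragment intensities
  drawn once per precursor from a Dirichlet, concentration 2) sampled on
  a 3-s cycle grid with peak sigma ~5.5 s, i.e. 4-5 data points per peak
  width (FWHM), over a 360-s gradient;
* multiplicative log-normal point noise (sdlog 0.15), ~10% between-run
  abundance variation, an additive exponential baseline and, with
  probability 0.15 per fragment, an interfering Gaussian at a random
  apex (the interference statistics of real runs are unknown; these are
  free parameters of the configuration);
* a second run with a linear retention-time shift (intercept 15 s, slope
  1.02) to exercise pass-2 calibration, and a planted twofold abundance
  change for half of the present precursors to exercise quantification;
* time-course matrices: intensities are baseline x planted effect x
  log-normal noise (CV 10%), with logistic intensity-dependent (MNAR)
  dropout; the default design is DMSO versus drug at 15, 60, 120, 240
  and 360 min with 4 replicates, 500 ubiquitinated proteins of which 40
  are planted degradative (site induction 1.5-3 log2 at the earliest
  time, protein declining linearly to 50-70% of control by the end —
  clearly past the 20% calling threshold, as real degraded substrates
  are), 60 non-degradative, 30 protein-down-only and 50 weak-site
  distractors.

What the generator does *not* emulate — profile-mode spectra, centroiding,
mass-calibration drift, nonlinear retention-time distortion, structured
interference from an actual peptide background, or missing-value
mechanisms beyond intensity-dependent dropout — bounds what passing tests
show: they validate the algorithms against their own stated models, not
instrument physics. Benchmark sizes (2,000 present plus 2,000 absent
targets with 1:1 decoys across 2 runs; 10,000-feature nulls; 5-10 Monte
Carlo replicates) were chosen so the full validation runs comfortably on
a laptop-class single core.

## Numerical choices and degenerate inputs

Constant traces correlate 0 by contract; windows shorter than 3 points
are not scored; empty candidate windows quantify as 0 with a flag; a
sample with no present values is a hard error in normalization (naming
the sample); zero residual degrees of freedom skip a feature; fewer than
two decoys' worth of training data, or degenerate separation, drop the
composite scorer to the equal-weight sum; fewer than two confident
calibration points drop the retention-time map to the identity, flagged.
Sample CVs at n = 4 are biased low (the median sample CV under a 10%
log-normal is ~8.9%, not 10%); tests against the generator use the
sampling-distribution value, not the population CV.

## A worked micro-example

```{r micro, eval = FALSE}
cfg <- default_config(n_proteins = 40, n_present = 100, n_absent = 100)
bm <- run_benchmark(cfg, seed = 1)
round(bm$metrics, 4)
```

`run_benchmark()` simulates, searches, quantifies, maps sites, runs the
time-course statistics and substrate calls, and reports the realized FDP,
calibration slope, ratio-recovery error, CV summaries and substrate
sensitivity/precision against the planted truth. `scripts/acceptance.R`
runs the same stages at the reference benchmark sizes and writes the
headline numbers as JSON.

## Known limitations

* The composite scorer is linear; it will not reproduce the ranking
  quality of a trained neural network on real data.
* Site localization between alternative lysines within one peptide form
  is not computed; each positional isomer is scored as its own precursor.
* The two-run benchmark exercises the two-pass machinery but not
  many-run study designs; retention-time calibration is linear by
  construction.
* mzML ingestion is not implemented; the simulator's documented
  run format is the only ingestion path.
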