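---
title: "Diagnosing periodontitis from MALDI-TOF protein profiles: methods and design"
author: "periospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing periodontitis from MALDI-TOF protein profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periospec)
```

## The diagnostic problem

Periodontitis is a chronic inflammatory destruction of the tooth-supporting
tissues. Its clinical diagnosis (full-mouth probing plus radiography) is slow
and skill-intensive, which makes population screening impractical. An
attractive alternative is protein *profiling*: linear-mode MALDI-TOF mass
spectra (2–20 kDa) of easily collected specimens — whole saliva, gingival
crevicular fluid (GCF) and subgingival dental plaque — carry reproducible
peak patterns that shift with periodontal state. periospec implements the
full analysis chain that turns raw replicate spectra of such specimens into
a subject-level diagnostic call, together with a synthetic-cohort generator
that makes every stage testable without access to clinical spectra.

The chain is:

1. **Per-replicate preprocessing** — quality control, smoothing, SNIP
   baseline removal, total-ion-current (TIC) normalisation, MAD-based peak
   picking.
2. **Alignment and averaging** — quadratic mass warping onto a consensus
   reference, then averaging each sample's technical replicates into a main
   spectrum profile (MSP).
3. **Feature building** — binning MSP peaks across samples into a
   sample-by-peak intensity matrix; Wilcoxon screening; dichotomization;
   binary-discriminant ranking.
4. **Classification** — a gain-ratio binary decision tree per specimen type,
   evaluated by stratified 10-fold cross-validation (sensitivity and
   specificity, periodontitis positive).
5. **Fusion** — a majority vote over the per-specimen trees for each subject
   with at least two specimens tested, with exact binomial confidence
   intervals on the fused metrics.
6. **Cohort statistics** — uncorrected Pearson chi-square / Welch tests on
   the demographic table, and a PCA/correlation screen checking that the
   top-ranked peaks are independent of the general risk factors.

## Preprocessing model and parameters

A replicate spectrum is a pair of equal-length vectors: strictly increasing
m/z (Da) and non-negative intensity (arbitrary units, AU). Defaults follow
the acquisition and processing settings customary for linear-mode
profiling of oral specimens:

| parameter | default | meaning |
|---|---|---|
| `minMaxIntensity` | 1e4 AU | QC: minimum acceptable spectrum maximum |
| `minSpectrumSNR` | 3 | QC: max baseline-corrected signal over MAD noise |
| `halfWindow` | 8 points | smoothing and peak-picking half window |
| `iterations` | 100 | SNIP clipping passes (initial half window) |
| `snrThreshold` | 3 | per-peak signal-to-noise acceptance |
| `tolerance` | 0.002 (relative) | warping, binning and MSP match tolerance |
| `minPeakFrequency` | 0.9 | fraction of spectra backing a warp reference peak |
| `minFrequency` | 0.25 | fraction of replicates backing an MSP peak |

Choices worth explaining:

* **QC before averaging.** Both QC rules apply per replicate, before any
  averaging; a sample survives if at least one replicate survives. The
  spectrum-level SNR statistic is the maximum baseline-corrected intensity
  divided by the MAD noise level — a deliberate proxy mirroring the
  peak-level rule, since "reject noisy spectra" admits many formalisations.
* **Smoothing** is an unweighted moving average over 17 points with
  truncated windows at the edges — no padding, so no signal is fabricated.
* **SNIP** clips the *raw* intensities with the decreasing-window schedule
  (window from 100 points down to 1). We verified on closed-form
  decompositions that this variant reproduces a peak-free linear ramp
  essentially exactly and recovers a planted Gaussian apex within 10%; the
  log-log-square-root compressed variant (`lls = TRUE`) is available but
  systematically undershoots smooth sloping baselines, because the double
  log makes a linear ramp concave and one hundred clipping passes accumulate
  the chord bias.
* **"0.002 tolerance" is relative** (|dm|/m), the convention of profile
  workflows at this resolution, and is used consistently for warp matching,
  binning and replicate clustering.
* **Warping** is a least-squares quadratic fitted to greedily matched
  anchors (each reference used once, ties toward lower mass, so the
  procedure is deterministic). Fewer than three anchors, a non-monotone fit,
  or a fitted shift above 1% anywhere in the observed peak range degrade to
  the identity warp with a warning — alignment must never corrupt a
  spectrum it cannot confidently improve.
* **Alignment scope.** Spectra are aligned within each specimen type:
  saliva, GCF and plaque profiles live on different intensity landscapes,
  so a shared reference across types would mix incompatible landmarks.
* **Native formats.** The on-disk spectrum format is two-column TSV
  (m/z, intensity, 15 significant digits — lossless round trips); mzML is
  supported read-only through the standard parser. Vendor raw formats are
  proprietary and out of scope.
* **MSP averaging** divides each retained peak's intensity sum by the full
  replicate count, so a peak present in 3 of 6 replicates at intensity 2.0
  enters the profile at 1.0. Peaks backed by fewer than
  `ceiling(0.25 * R)` replicates are dropped.

## Feature matrix and peak ranking

Pooled MSP peak masses are clustered divisively: a sorted block is one bin
iff its relative spread `(max - min)/mean` is at most twice the tolerance,
otherwise it splits at its largest internal gap. Each sample contributes at
most one (strongest) peak per bin; missing peaks are zeros, never imputed.

Screening uses the two-sided Wilcoxon rank-sum test on intensities, exact
where tie-free, and the tie-handling normal approximation without continuity
correction otherwise (so symmetric ties give p = 1). P-values are
unadjusted, matching how "significantly different peaks" are conventionally
counted in profiling studies; the count is reported with its alpha.

Dichotomization thresholds each bin at the midpoint of the two group means;
values strictly above become presence calls. Bins are then ranked by a
binary discriminant score: with regularised per-group presence frequencies
`p_g = (x_g + 1/2)/(n_g + 1)` and their size-weighted pooled mean `p`, the
score is the group-wise binomial log-likelihood ratio

`S = sum_g n_g * [ p_g log(p_g/p) + (1 - p_g) log((1 - p_g)/(1 - p)) ]`.

The half-count regularisation keeps perfectly separating bins finite; the
weighted pooled mean makes `S` exactly zero for identical group frequencies.
`S` is verified against hand arithmetic and shown exhaustively (all count
pairs at n = 20 + 20) to be maximised by the perfect marker.

## Decision trees and cross-validation

Trees are induced greedily on the dichotomised features of the top 30
ranked bins: at each node the feature with the best gain ratio (information
gain over split entropy, log base 2) among candidates with positive gain and
at least `minLeaf = 2` samples per side; ties resolve toward the lower
reference mass. When *no* single feature has positive gain at an impure
node, a one-step lookahead considers features whose children admit positive
gain — this lets the greedy recursion solve exactly-balanced interaction
structure (an exclusive-or of two peaks) that would otherwise stall at the
root. Grown trees are simplified by error-based pruning with confidence
factor 0.25: each node is replaced by a leaf, kept, or substituted by its
more populated branch (with samples re-routed), whichever minimises the
pessimistic error estimate `n * qbeta(1 - CF, e + 1, n - e)`.

Cross-validation partitions samples into k = 10 stratified folds (sizes
within one, both classes in every fold) from a seeded RNG and re-fits the
*entire* feature pipeline per training fold: thresholds from training group
means, ranking on training presence calls, tree on training samples.
Validation samples are dichotomised with the frozen training thresholds and
routed down the frozen tree, so no information flows from validation to
fit — verified by a canary experiment in the test suite and by null
calibration (permuted labels cross-validate at chance).

## Fusion

Per subject, predictions from the available specimen trees are combined by
majority vote; fewer than two specimens give "indeterminate", and a 1–1 tie
resolves to periodontitis by default — a screening test should favour
sensitivity; the conservative alternative is exposed. Fused sensitivity,
specificity, PPV and NPV are reported over determinate subjects with exact
Clopper–Pearson 95% intervals (for x = n the lower bound is
`(alpha/2)^(1/n)`), and the indeterminate count is always reported next to
them.

## Cohort statistics

The demographic table is reproduced from its printed counts with the
uncorrected Pearson chi-square (df = 1); we verified that this is the only
standard 2x2 test whose p-values match the printed ones (the
continuity-corrected and exact tests do not). The age contrast uses Welch's
t from the printed summary statistics. Stage/grade tables are converted to
percentages of the diseased-group total, rounded to one decimal. The
peak–risk-factor screen z-scores the joint matrix of top-10 peak intensities
and covariates, runs a PCA, and declares the peaks independent when the
largest absolute peak–covariate Pearson correlation stays below 0.3 — the
published conclusion ("independent of the general risk factors") comes
without a criterion, so the bound is an explicit, configurable surrogate.

## What the synthetic generator emulates

`simConfig()` fixes a generative model whose structure mirrors the study:
67 + 74 subjects at the cohort's full scale, three specimen types per subject, six
replicate spectra per sample, per-type missing-sample rates matching the
collected counts (119/104/110 of 141), and per-type peak templates of 217
(saliva), 176 (GCF) and 124 (plaque) masses whose top-10 discriminative
peaks sit at the study's reported masses and directions (8 up / 2 down in
saliva, 9/1 in GCF, all 10 down in plaque). Covariate frequencies default to
the demographic table's per-group rates and are drawn independently of the
spectral ground truth, so the independence screen holds under the null by
construction.

A replicate spectrum is a closed-form sum: Gaussian peaks with
mass-proportional width (sigma = 0.0005 m, linear-mode resolution) at
subject-level lognormal amplitudes (group effects as log-intensity shifts,
presence probabilities per group), an exponentially decaying chemical
baseline, i.i.d. Gaussian detector noise (sd 150 AU), a lognormal
per-replicate intensity factor (CV 0.25) and a per-spectrum quadratic mass
miscalibration bounded by 0.0015 relative — deliberately a few times the
external calibration accuracy of the instrument class (a few hundred ppm),
so the alignment stage is genuinely stressed — sampled on a 4 Da grid. Peak
identities depend only on (subject, specimen); replicates redraw only
noise, intensity factor and miscalibration.

Calibration presets serve the validation studies:

* **`recovery`** — one presence/absence marker (80% of cases, 20% of
  controls, tight intensities) in a 12-peak template, 60 + 60 subjects: the
  Bayes rule "call periodontitis iff the marker is present" has designed
  sensitivity and specificity 0.80/0.80. The template is deliberately small:
  a pilot showed that offering the tree dozens of rank-selected spurious
  features biases cross-validated recovery low by more than 0.10 (selection
  bias feeds the tree noise splits that validate at chance), which would
  measure tree overfitting rather than pipeline calibration.
* **`null`** — the same cohort with no discriminative peak; with permuted
  labels the cross-validated sensitivity and specificity must stay at
  chance.
* **`ranking`** — five planted 1.5 log-unit intensity markers among 50
  peaks for ranking-recovery checks.
* **`smoke`** — 6 subjects end to end (108 raw spectra), small enough that
  the full raw-spectrum chain, fusion and reporting run in seconds and can
  be checked for byte-identical determinism.

Repeated-cohort studies (recovery over 20 seeds, null over 200, ranking
over 50) sample the generative design directly at the binned-peak level
(`simulateIntensityMatrix()`): the same presence/effect model the raw
spectra realise, without re-simulating thousands of 4501-point spectra whose
preprocessing is already validated against closed forms and oracles at the
replicate level. The raw path is exercised end to end at smoke scale.

What the generator does *not* emulate — and hence what passing tests cannot
show about clinical data: matrix-cluster chemical noise, detector
saturation, isotopic fine structure, correlated (non-i.i.d.) baselines,
batch effects between acquisition days, and any real biological covariance
between risk factors and proteome. The study's blinded per-specimen
cross-validated performance and the fused 100%/100% depend on the clinical
spectra, which were not deposited; only the procedure, not those numbers,
is reproducible here.

## Numerical and degenerate-input choices

* All mass comparisons are relative; exact duplicate masses in one trace
  are rejected rather than silently merged.
* Unsorted input m/z is sorted with a warning (tolerant ingestion);
  negative intensities are errors.
* Constant bins dichotomize to all-absent and are flagged uninformative;
  constant covariates are dropped from the PCA screen with a warning.
* Zero-total spectra cannot be TIC-normalised (error); all-zero spectra
  have zero SNIP baseline.
* Ties: bin ranking ties break toward lower mass; tree split ties toward
  lower mass; leaf-class ties toward the positive class; fold assignment
  is a pure function of the seed.
* Every stage derives its RNG stream from the master seed and the stage
  name, so adding or removing an optional stage cannot shift another
  stage's draws.

## Known limitations

* The binary-discriminant score is a likelihood-ratio surrogate with the
  same inputs and outputs as the published method's ranking; absolute score
  values are not interchangeable with other implementations, ranks are.
* C5.0 itself is proprietary; the classifier is the published C4.5 core
  (gain ratio, pessimistic pruning, CF 0.25, single tree — no boosting or
  winnowing). In-sample tree sizes and shapes will differ from C5.0's.
* Midpoint-of-means dichotomization is sensitive to heavy-tailed intensity
  distributions; the ranking is invariant to monotone intensity transforms
  only insofar as presence patterns are preserved.
* Fusion with majority voting can, in small cohorts, fall below the best
  single tree by sampling noise; on average it improves on it (analytic
  majority-vote accuracy for three independent 0.75 trees: 0.84375).
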