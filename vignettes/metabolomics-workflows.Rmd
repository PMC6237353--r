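---
title: "Models and methods behind MetaboBench"
author: "MetaboBench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind MetaboBench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboBench)
```

MetaboBench implements the computation layer of a combined
targeted/non-targeted metabolomics study. This vignette documents the
models, the assumptions they rest on, the tunable parameters with their
defaults, the numerical choices, what the synthetic-data generators do and
do not emulate, and the design decisions that were genuinely open.

## Data model

All signal tables are features/analytes × samples. `MetaboExperiment`
extends `SummarizedExperiment`: the `"intensity"` assay holds peak areas or
feature intensities, `colData` carries the `SampleSheet` (sample id, role,
injection order, batch, tissue, replicate group, dilution factor), and
`rowData` carries feature m/z (Th), retention time (minutes) and optional
annotation (library match score in [0, 100], `;`-separated database hits).
Missing intensities are kept distinct from literal zeros throughout,
because blank subtraction and LOD logic need true zeros while drift and
RSD logic must not mistake an absent measurement for one.

Sample roles: `sample`, `blank`, `cal_standard`, `qc_train` (pooled
technical-replicate injections that *train* drift models) and `qc_test`
(extraction-replicate injections that *evaluate* a correction). Keeping
the two QC roles separate is what makes the drift benchmark honest: the
model never sees the samples it is scored on.

## Internal-standard quantification

`quantifyIS()` implements the ratio rule
\[
\mathrm{Conc}_{analyte} =
\frac{\mathrm{Area}_{analyte}}{\mathrm{Area}_{IS}}
\times \mathrm{Conc}_{IS} \times \mathrm{Dilution}.
\]
It assumes the analyte and its IS experience the same matrix and drift
effects (the basis of ratio quantification) and is homogeneous of degree
zero in the two areas. Division by a zero IS area is an error naming the
analyte and sample rather than an `Inf` that would silently poison
downstream RSDs.

Detection limits come in two flavours. For flow-injection panels, where
background in blanks is the practical floor, `blankLod()` sets
LOD = LOQ = 10 × mean blank concentration (zero blanks give zero). For
LC-MRM targets, `snLod()` uses the conventional
LOD = 3 × conc / (S/N) at the lowest standard with a measurable peak.
Concentrations below LOD are *flagged, never censored*: replicate RSDs and
means downstream need values, and censoring at LOD would bias them.

## Calibration curves

`fitCalibration()` supports the two response models used by targeted
panels:

* **linear, 1/x² weights** — the standard bioanalytical choice when noise
  is roughly proportional to concentration; weighting by \(1/x^2\) keeps
  relative (not absolute) residuals flat so low standards are not
  swamped by the top of the range;
* **quadratic in log₁₀–log₁₀ space** — for detector saturation or
  non-linear response over 5–6 decades, fitted unweighted in log space
  (the log transform already equalizes relative errors).

The reported `r` is the Pearson correlation of fitted versus observed
responses *on the regression scale*; a single correlation coefficient is
conventional on calibration reports and this definition covers both curve
shapes uniformly. At least 5 points are required for a line and 6 for a
quadratic.

**Inversion.** Linear models invert algebraically. Quadratics are inverted
by locating sign changes of the forward model on its monotone segments
(split at the stationary point) and bisecting — in log space for log–log
fits — rather than via the quadratic formula, which is numerically fragile
when the curvature term is small. Three explicit flags replace silent
behaviour: responses below the calibrated response range return
concentration 0 with `below_range = TRUE`; responses above it are inverted
on the adjacent segment and flagged `extrapolated`; a quadratic with two
roots inside the calibration range raises an ambiguity error. A relative
tolerance of 10⁻⁸ of the response range absorbs float round-off at the
range edges, so a noiseless fit→invert round trip is exact to ~10⁻¹²
rather than failing at the boundary standards.

## Isotopic deconvolution of flow-injection lipid data

Flow injection ionizes a whole lipid class at once. Within a class, adding
one double bond removes two hydrogens (−2 Da), so the M+2 isotopologue of
species *i* (two ¹³C) is isobaric with the monoisotopic ion of the species
with one fewer double bond. MRM transitions cannot separate them; the
correction is arithmetic.

**Isotope model.** `isotopeEnvelope()` uses a carbon-only binomial with
p(¹³C) = 0.0107:
\(a_k = \binom{n}{k} p^k (1-p)^{n-k}\), truncated to the first
`n_peaks` (default 3) isotopologues and renormalized. Hydrogen, nitrogen,
oxygen and phosphorus isotopes are ignored: for lipids the +2 Da
interference is dominated by ¹³C₂ (²H and ¹⁵N are an order of magnitude
rarer per atom, ¹⁸O contributes < 10% of the ¹³C₂ term at these carbon
counts). The invariant \(a_1/a_0 = np/(1-p)\) is tested exactly.

**Carbon counts.** The class/C:DB nomenclature (`PCaaC34:0`,
`lysoPCaC20:2`, `SM(d18:0/C18:1)`, `C2:0`) counts only fatty-acid (and
explicit sphingoid) carbons. The envelope needs the whole molecule, so
`totalCarbons()` adds per-class backbone carbons — PC and lysoPC 8
(glycerol + phosphocholine head), SM 5 beyond its chains, carnitine 7 —
and assumes an 18-carbon sphingoid base for shorthand SM names. The
lookup is an exported default, overridable per call, since exact elemental
composition is deliberately out of scope of the nomenclature.

**Mixing and inversion.** For a same-class, same-carbon series sorted by
descending double bonds (ascending mass), `overlapMatrix()` builds the
lower-bidiagonal matrix with \(M_{ii} = a_0(i)\) and
\(M_{ji} = a_2(i)\) where *j* sits exactly +2 Da above *i*. Observed areas
are \(M x\); `deconvolveAreas()` solves by forward substitution, which
propagates the correction down arbitrarily long chains (subsuming M+4 and
beyond through the chain itself). Negative solutions — possible when noise
makes a small species' observed area smaller than its neighbour's isotope
contribution — are clipped to zero with a per-species flag rather than
erroring, again because downstream RSDs need complete vectors.
`deconvolveLipids()` applies this matrix-wide, grouping columns by parsed
class and carbon number, passing through anything that does not parse as a
lipid and any sample with missing values inside a series.

## Signal-drift and batch correction

The model: electrospray response drifts approximately linearly with
injection order within a batch, multiplicatively on signal scale, and
batches differ by a multiplicative offset. Correction is therefore a
*ratio to a fitted trend*, never a subtraction — this preserves
non-negativity and makes every correction scale-equivariant (a property
the suite tests), so RSDs and threshold counts are unit-free.

`fitLinearSequence()` is per-feature OLS of QC_train intensity on
injection order; features with fewer than two finite QC values, or a
non-positive mean fitted level, are passed through uncorrected rather than
corrected by an untrustworthy model. `applyDrift()` divides by the fitted
trend and rescales to the anchor level; injections where the fitted trend
is non-positive become missing with a warning.

**Anchoring.** A genuinely open choice was whether the corrected series of
each batch should sit at that batch's own mean QC level or at the grand QC
mean of the run. We default to the grand mean
(`linearSequenceCorrect(anchor = "global")`): this is the standard
QC-reference formulation of sequence correction, it leaves single-batch
runs unchanged relative to the alternative, and it means "linear sequence
correction" of a multi-batch run produces one coherent scale. The pure
within-batch variant (`anchor = "batch"`) is kept for studies that
normalize batches downstream. `batchAnchorCorrect()` expresses the same
correction as two explicit stages — within-batch detrending, then
between-batch scaling of every feature's QC_train mean to the grand mean —
and fills the benchmark slot that external batch-correction tools occupy
in comparable study designs; reports label it as the package's own
QC-anchored method, not a re-implementation of those tools.

**Strategies and benchmark.** `runStrategy()` composes steps from
{`none`, `is_norm`, `linear_sequence`, `batch_anchor`} in order,
validating the step list before any computation. The default comparison
set (`defaultStrategies()`) is the four single methods plus three
combinations, IS-first where IS normalization is involved, since dividing
by the IS first removes the shared multiplicative component before the
order-dependent fit. `benchmarkStrategies()` scores every strategy by
per-feature RSD over QC_train and QC_test separately and counts features
below 15% and 30% RSD — the conventional acceptance thresholds for
non-target features. RSD uses the sample (n−1) standard deviation
throughout, appropriate for the 4–15-replicate groups these metrics are
computed from.

## Non-target annotation

`putativeIdFilter()` passes a feature iff its spectral-library match score
is *strictly* greater than 90 (the wording "higher than 90%" makes 90.0 a
fail; the boundary is covered by a test) and at least one of the six
exact-mass databases corroborates the identity. Unannotated features are
tallied separately from failing ones, so a sparse annotation export is
distinguishable from a poorly matching one. Passing this filter
corresponds to a level-2 putative identification — a strong prior for
deciding whether standard-based confirmation is worth the effort, not an
identification in itself.

`flagLipidParents()` reconstructs fragment→parent links that full-scan
processing software does not provide at scale: any feature within
`mz_tol` (default 0.01 Th) of a catalog head-group fragment (m/z 184.0733
for phosphocholine-containing classes, 85.0284 for acylcarnitines) marks a
lipid elution point, and every heavier feature within `rt_tol` (default
0.05 min) is emitted as a candidate parent. All pairs are reported in a
deterministic order (fragment, |Δrt|, descending mean intensity) — never a
silent best-only choice. The defaults suit sub-ppm-calibrated
high-resolution data; both windows are per-call parameters and in
`metaboDefaults()`. Whether the original acquisition's fragment RT should
be the MS² scan's or the apex's is unresolvable from a feature table; the
feature RT is used for both sides, which cancels any systematic offset.

`qqqCrossCheck()` formalizes the false-positive check for MRM detections:
`confirmed` if a high-resolution feature lies within ±0.005 Da of the
target's protonated mass (monoisotopic + 1.007276; positive mode assumed),
`wide_only` if a feature exists only within ±0.5 Da — the signature of a
nominal-mass interferent mimicking the MRM transition — and `absent`
otherwise.

## Precision, accuracy and platform comparison

`precisionReport()` distinguishes three scopes: *technical* (repeated
injections of one extract, i.e. rows sharing a replicate group),
*within-batch* (extraction replicates of one batch, averaged over
batches), and *between-batch* (all extraction replicates pooled). The
pooled definition of between-batch RSD was chosen over the RSD of batch
means: it is the quantity a user of the assay experiences when samples
span batches, and it degrades gracefully with unbalanced designs such as
4 + 8 replicates.

`accuracyVsReference()` reports measured/certified × 100 with an
inclusive 50–150% acceptance band by default. `comparePlatforms()`
declares a per-compound winner by strictly lower RSD (ties kept explicit)
over a user-supplied compound↔feature map — an explicit map, because
automated mass/RT matching silently overriding a curated pairing is the
kind of convenience that corrupts comparisons. `featureCountSummary()`
reports both "X% of" and "X% more" for the positive/negative and
HILIC/C18 ratios, because the two readings of a percentage comparison
differ by 100 points and are easily conflated.

## Synthetic data: what it emulates and what it does not

The generators produce data with the statistical structure each method
assumes, plus the stored truth needed for parameter-recovery tests:

* `makeTargetedRun()` — an 11-level geometric calibration series spanning
  346.3 pM–161.2 µM, blanks at 0.1% of the truth level, and 4 + 8
  replicates in two batches (the replicate design of reference-plasma
  validation). Noise is multiplicative lognormal (mean 1), independent on
  analyte and IS areas — ESI noise scales with signal and lognormal keeps
  areas positive. At `noise_cv = 0` the quantification pipeline returns
  the truth exactly, which pins the full algebraic path.
* `makeLipidRun()` — the forward isotope-overlap model `M · truth`,
  optionally noisy, for round-trip tests of the deconvolution.
* `makeDriftTable()` — per feature, a lognormal base level × a linear
  injection-order trend × a per-batch offset × lognormal noise, with
  pooled QC_train injections every 10th slot (each batch opening and
  closing with one) and QC_test replicates interleaved midway between
  grid points. Defaults — total drift drawn within ±30% of the feature
  mean over the sequence, 5% noise, two batches with offsets (1, 2) —
  are the package's reference study conditions for the drift benchmark:
  uncorrected, the batch offset alone puts the median QC RSD far above
  the 15% threshold; corrected, essentially all features fall below it.
* `makeAnnotations()` — match scores with a controlled probability mass
  strictly above 90 and six independent per-database hit flags, so the
  filter's pass count has the closed form
  \(n\,p_{high}\,(1-(1-p_{lib})^6)\) to test against.

Every generator is deterministic under its seed. What they do **not**
emulate: chromatographic peak shape and integration error, retention-time
drift, correlated (non-linear) sensitivity changes, missing-at-low-signal
censoring, isomer co-elution, or real annotation-score distributions.
Passing tests on these fixtures therefore demonstrates correctness of the
computations under their stated models — not that real data satisfy those
models.

## Problem sizes and numerical choices

The test suite and the acceptance script run the methods at the scales the
checks need and nothing more: 10,000 random tuples for the quantification
oracle, isotope series of lengths 1–10 in triplicate, a 200-feature ×
two-batch drift table with 60 biological samples, a 10,000-feature
annotated table, and 100 features for the exhaustive fragment-matching
oracle. Tolerances: 10⁻¹² relative for pure arithmetic against oracles,
10⁻⁹ for round trips through fitted or inverted models, 3σ bands for
stochastic closed-form checks. Report files format numerics to 9
significant digits, which round-trips doubles through text well below
every tolerance above.

## Known limitations

* Drift models are linear only; LOESS/spline trends and cluster-based
  batch alignment are out of scope, and the QC-anchored batch method is a
  stand-in interface slot for external tools, not a reimplementation of
  them.
* The isotope model is carbon-binomial; species with unusual heteroatom
  counts (e.g. polyphosphorylated lipids) would need a fuller envelope.
* Cross-class isotope interference (e.g. between overlapping class
  panels) is not corrected — only same-class, same-carbon series.
* The annotation filter consumes scores; it does not compute spectral
  similarity, and MS² spectra are never touched.
* Positive-mode protonation is assumed for the targeted cross-check;
  adduct handling beyond [M+H]⁺ is the caller's responsibility via the
  `proton_mass` offset.
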