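# MetaboBench

Post-acquisition computation for combined **targeted** and **non-targeted
metabolomics** workflows: internal-standard quantification with weighted
calibration, isotopic deconvolution of flow-injection lipid MRM data,
QC-anchored signal-drift/batch correction with RSD-threshold benchmarking,
putative-identification filtering and lipid fragment→parent matching for
high-resolution feature tables, and precision/accuracy comparison of the
two platforms.

## Who this is for

Analytical labs running a triple-quadrupole targeted panel (LC-MRM for
polar metabolites, flow-injection MRM for lipid classes) alongside an
Orbitrap-style non-targeted acquisition, who need the computation layer
between instrument export and statistics: peak-area matrices in,
concentrations, corrected feature tables and precision reports out.

## The core computations

**Internal-standard quantification.** Every targeted analyte is assigned an
internal standard (IS) and quantified by the area-ratio rule

```
Conc_analyte = (Area_analyte / Area_IS) × Conc_IS × Dilution_factor
```

with blank-based detection limits (LOD = LOQ = 10 × mean blank
concentration) for flow-injection data and S/N-based limits
(LOD = 3 × conc / (S/N) at the lowest measurable standard) for LC-MRM.
Calibration curves are linear with 1/x² weighting or quadratic in
log₁₀–log₁₀ space, inverted by monotone-segment bisection with explicit
flags for below-range, extrapolated and ambiguous responses.

**Isotope deconvolution.** Without chromatography, the two-¹³C (M+2)
isotopologue of a lipid lands exactly on the monoisotopic mass of the
same-class species with one fewer double bond. For each same-class,
same-carbon series sorted by ascending mass, observed areas are a
lower-triangular mixture `observed = M · truth` with `M[i,i] = a₀(i)` and
`M[j,i] = a₂(i)` for the +2 Da neighbour, where the isotopologue abundances
follow a carbon-count binomial with p(¹³C) = 0.0107. The system is solved
by forward substitution; negative solutions are clipped to zero and
flagged.

**Drift and batch correction.** Pooled technical QCs (QC_train) train
per-feature, per-batch linear models of intensity on injection order;
corrected values are the ratio to the fitted trend rescaled to the QC
reference level, with between-batch scaling equalizing each feature's
QC_train mean across batches. IS normalization and step combinations are
available, and `benchmarkStrategies()` scores every strategy by the number
of features below 15%/30% RSD in QC_train and in held-out extraction QCs
(QC_test).

**Non-target annotation.** A feature is putatively identified (level 2)
when its spectral-library match score is strictly above 90 *and* at least
one of six exact-mass databases (BioCyc, HMDB, KEGG, LipidMaps, PubChem,
SMPDB) suggests the same identity. Lipid parents are recovered by matching
head-group fragment features (e.g. m/z 184.0733 for phosphocholines) to
heavier co-eluting features, and targeted detections are cross-checked
against the exact-mass data with a narrow (±0.005 Da) versus wide
(±0.5 Da) window to expose probable MRM false positives.

**Precision and accuracy.** RSD (sample SD / |mean| × 100) at technical,
within-batch and between-batch scope; accuracy as measured/certified × 100
against reference-plasma certificates; per-compound targeted-vs-non-targeted
winners; and feature-count summaries across chromatography/ionization
combinations.

## Worked example

```r
library(MetaboBench)

panel <- TargetPanel(data.frame(
  name = c("ala", "leu"), analyte_class = "amino_acid",
  is_name = "IS_aa", conc_is = 0.19))

# simulate a full targeted run: 11 calibration levels, blanks and
# 4 + 8 replicates in two batches, 5% multiplicative noise
run <- makeTargetedRun(panel, c(ala = 2, leu = 0.4),
                       noise_cv = 0.05, seed = 1)
q <- quantifyMatrix(run$areas, panel, run$sheet)
reps <- run$sheet$sample_id[run$sheet$role == "sample"]
round(colMeans(q$conc[reps, ]), 3)
#>   ala   leu
#> 2.018 0.398
round(q$lod, 4)
#>    ala    leu
#> 0.0199 0.0041
```

The replicate means recover the simulated truth (2 and 0.4 µM) within the
noise, and the blank-based LODs sit at 10× the simulated blank
concentration (0.1% of the truth level, so ≈0.02 and 0.004 µM). Precision
of the same run:

```r
subset(precisionReport(q$conc, run$sheet), scope == "between_batch")
#>   analyte         scope  n mean_value rsd_pct
#>       ala between_batch 12      2.018    6.93
#>       leu between_batch 12      0.398    7.10
```

≈7% between-batch RSD is the error-propagation expectation for two
independent 5% noise sources (analyte and IS areas). Drift correction on a
simulated 200-feature, two-batch feature table:

```r
d <- makeDriftTable(n_features = 200, n_samples = 60, driftSpec(seed = 1))
benchmarkStrategies(d$table, d$sheet)
#> CorrectionBenchmark: 200 features, 4 strategies
#>                      strategy   qc_set n_lt_15 n_lt_30 n_total evaluable
#>                          none qc_train       0       0     200      TRUE
#>                          none  qc_test       0       0     200      TRUE
#>               linear_sequence qc_train     200     200     200      TRUE
#>               linear_sequence  qc_test     200     200     200      TRUE
#>                  batch_anchor qc_train     200     200     200      TRUE
#>                  batch_anchor  qc_test     200     200     200      TRUE
#>  linear_sequence+batch_anchor qc_train     200     200     200      TRUE
#>  linear_sequence+batch_anchor  qc_test     200     200     200      TRUE
#> winner (n_lt_30): qc_train=linear_sequence, qc_test=linear_sequence
```

Uncorrected, the ±30% injection-order drift plus the two-fold batch offset
pushes every feature above 30% QC RSD; QC-anchored correction brings all
200 under 15%.

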