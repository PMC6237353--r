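## Synthetic-data generators reproducing the statistical structure the rest
## of the package assumes: replicate concentration measurements with
## multiplicative (lognormal) noise, lipid-class panels with M+2 isotope
## overlap, feature tables with injection-order drift + batch offsets + a QC
## every 10th injection, and annotated tables with scores and library hits.
## Every generator is deterministic under a fixed seed and stores its truth
## for parameter-recovery tests.

.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

#' Simulate a targeted MRM acquisition
#'
#' Generates a peak-area matrix, sample sheet and truth table for a
#' targeted run: an 11-level calibration series (geometric, spanning
#' 346.3 pM–161.2 µM by default), blanks at a stated low level, and
#' replicate study samples split over two batches (4 + 8 by default, the
#' replicate design used for reference-plasma validation).  Analyte areas
#' are the internal-standard response scaled by the truth concentration
#' under Eq.-style ratio quantification, with independent multiplicative
#' lognormal noise on analyte and IS areas, so the quantification pipeline
#' recovers the truth exactly at `noise_cv = 0`.
#'
#' @param panel a [TargetPanel-class].
#' @param truth_concs named numeric vector of true sample concentrations
#'   (µM) per analyte (defaults to 1 µM for all panel analytes).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_cal_levels number of calibration standards.
#' @param cal_range lowest/highest calibration concentration, µM.
#' @param batch_sizes replicate count per batch.
#' @param n_blanks blank injections.
#' @param blank_frac blank signal as a fraction of the truth level.
#' @param dilution_factor dilution factor of study samples.
#' @param is_area_base mean IS peak area (arbitrary units).
#' @param seed RNG seed.
#' @return list with `areas` (samples × analyte+IS columns), `sheet`
#'   ([SampleSheet-class]), `truth` (list with `concs`, `cal_levels`,
#'   `blank_frac`, generating parameters).
#' @export
makeTargetedRun <- function(panel, truth_concs = NULL, noise_cv = 0.05,
                            n_cal_levels = 11L,
                            cal_range = c(346.3e-6, 161.2),
                            batch_sizes = c(4L, 8L), n_blanks = 2L,
                            blank_frac = 0.001, dilution_factor = 5,
                            is_area_base = 1e5, seed = 1L) {
  stopifnot(is(panel, "TargetPanel"))
  set.seed(seed)
  analytes <- panel$name
  if (is.null(truth_concs))
    truth_concs <- stats::setNames(rep(1, length(analytes)), analytes)
  stopifnot(all(analytes %in% names(truth_concs)))
  is_names <- unique(panel$is_name)
  cal_levels <- exp(seq(log(cal_range[1]), log(cal_range[2]),
                        length.out = n_cal_levels))
  n_rep <- sum(batch_sizes)
  ids <- c(sprintf("cal%02d", seq_len(n_cal_levels)),
           sprintf("blank%02d", seq_len(n_blanks)),
           sprintf("rep%02d", seq_len(n_rep)))
  roles <- c(rep("cal_standard", n_cal_levels), rep("blank", n_blanks),
             rep("sample", n_rep))
  batch <- c(rep("b1", n_cal_levels + n_blanks),
             rep(paste0("b", seq_along(batch_sizes)), batch_sizes))
  dil <- ifelse(roles == "sample", dilution_factor, 1)
  ord <- stats::ave(seq_along(ids), batch, FUN = seq_along)
  sheet <- SampleSheet(data.frame(
    sample_id = ids, role = roles, injection_order = ord, batch_id = batch,
    tissue = "plasma", replicate_group = ifelse(roles == "sample", "pool",
                                                ids),
    dilution_factor = dil))
  areas <- matrix(NA_real_, length(ids), length(analytes) + length(is_names),
                  dimnames = list(ids, c(analytes, is_names)))
  areas[, is_names] <- is_area_base *
    .lognoise(length(ids) * length(is_names), noise_cv)
  for (a in analytes) {
    conc_is <- panel[a, "conc_is"]
    is_a <- panel[a, "is_name"]
    true_conc <- ifelse(roles == "cal_standard",
                        cal_levels[pmin(ord, n_cal_levels)],
                 ifelse(roles == "blank",
                        blank_frac * truth_concs[[a]],
                        truth_concs[[a]]))
    areas[, a] <- true_conc / (conc_is * dil) * is_area_base *
      .lognoise(length(ids), noise_cv)
  }
  list(areas = areas, sheet = sheet,
       truth = list(concs = truth_concs, cal_levels = cal_levels,
                    blank_frac = blank_frac, noise_cv = noise_cv,
                    dilution_factor = dilution_factor, seed = seed))
}

#' Simulate a flow-injection lipid panel with isotope overlap
#'
#' Forward model of the M+2 interference: observed areas are
#' `M %*% truth` per sample when `with_overlap` is on (`M` from
#' [overlapMatrix()]), or the truth itself when off, with optional
#' multiplicative noise.
#'
#' @param class_series character names or list of [LipidSpecies-class], one
#'   same-class same-carbon series.
#' @param truth_areas numeric vector (one sample) or samples-by-species
#'   matrix of true areas, aligned with the canonical descending
#'   double-bond order.
#' @param with_overlap apply the isotope mixing matrix.
#' @param noise_cv multiplicative noise CV.
#' @param seed RNG seed.
#' @return samples-by-species matrix of observed areas with attributes
#'   `"truth"` and `"M"`.
#' @export
makeLipidRun <- function(class_series, truth_areas, with_overlap = TRUE,
                         noise_cv = 0, seed = 1L) {
  set.seed(seed)
  M <- overlapMatrix(class_series)
  truth <- if (is.matrix(truth_areas)) truth_areas
           else matrix(truth_areas, nrow = 1)
  stopifnot(ncol(truth) == nrow(M))
  colnames(truth) <- rownames(M)
  observed <- if (with_overlap) truth %*% t(M) else truth
  observed <- observed * matrix(.lognoise(length(observed), noise_cv),
                                nrow(observed))
  dimnames(observed) <- dimnames(truth)
  attr(observed, "truth") <- truth
  attr(observed, "M") <- M
  observed
}

#' Drift-table generating parameters
#'
#' @param kind `"linear"` drift or `"none"`.
#' @param slope_range maximum absolute fractional change of a feature over
#'   the whole injection sequence (slopes drawn uniformly in ± this value).
#' @param batch_offsets multiplicative level factor per batch (its length
#'   sets the number of batches); the default emulates a two-batch run with
#'   a two-fold between-batch shift.
#' @param noise_cv multiplicative noise CV.
#' @param qc_every a QC_train injection every this many injections (>= 2).
#' @param n_qc_test QC_test injections per batch.
#' @param seed RNG seed.
#' @return list of class `"DriftSpec"`.
#' @export
driftSpec <- function(kind = c("linear", "none"), slope_range = 0.3,
                      batch_offsets = c(1, 2), noise_cv = 0.05,
                      qc_every = 10L,
                      n_qc_test = 3L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(noise_cv >= 0, qc_every >= 2L, all(batch_offsets > 0),
            slope_range >= 0, n_qc_test >= 2L)
  structure(list(kind = kind, slope_range = slope_range,
                 batch_offsets = batch_offsets, noise_cv = noise_cv,
                 qc_every = as.integer(qc_every),
                 n_qc_test = as.integer(n_qc_test),
                 seed = as.integer(seed)),
            class = "DriftSpec")
}

#' Simulate a drifting non-target feature table
#'
#' Per feature: a lognormal base level times a linear injection-order trend
#' (total fractional change drawn within ± `slope_range`), times the
#' batch's multiplicative offset, times lognormal noise.  Pooled QC_train
#' injections (technical replicates of one pool at the feature base level)
#' are inserted every `qc_every`-th injection; QC_test extraction-replicate
#' injections are interleaved midway between them.  All generating
#' parameters are stored in the truth table for recovery tests.
#'
#' @param n_features number of features.
#' @param n_samples biological samples, split evenly over the batches.
#' @param spec a [driftSpec()].
#' @return list with `table` (features × samples matrix), `sheet`
#'   ([SampleSheet-class]), `truth` (list with `base`, `slope_per_order`,
#'   `batch_offsets`, `spec`).
#' @export
makeDriftTable <- function(n_features, n_samples, spec = driftSpec()) {
  stopifnot(inherits(spec, "DriftSpec"))
  set.seed(spec$seed)
  n_batches <- length(spec$batch_offsets)
  per_batch <- rep(n_samples %/% n_batches, n_batches)
  if (n_samples %% n_batches)
    per_batch[seq_len(n_samples %% n_batches)] <-
      per_batch[seq_len(n_samples %% n_batches)] + 1L
  base <- stats::rlnorm(n_features, meanlog = log(1e5), sdlog = 0.5)
  # build the injection sequence per batch: QC_train on the qc_every grid,
  # QC_test midway between grid points, samples in the remaining slots
  all_rows <- list()
  for (b in seq_len(n_batches)) {
    n_b <- per_batch[b]
    seq_ids <- character(); seq_roles <- character()
    s_i <- 0L; qtest_i <- 0L; pos <- 0L
    half <- max(1L, spec$qc_every %/% 2L)
    while (s_i < n_b || qtest_i < spec$n_qc_test) {
      pos <- pos + 1L
      mod <- pos %% spec$qc_every
      if (mod == 1L || spec$qc_every == 2L && mod == 0L && s_i >= n_b &&
          qtest_i >= spec$n_qc_test) {
        seq_ids <- c(seq_ids, sprintf("b%d_qctrain%02d", b,
                                      sum(seq_roles == "qc_train") + 1L))
        seq_roles <- c(seq_roles, "qc_train")
      } else if (qtest_i < spec$n_qc_test &&
                 (mod == half + 1L || s_i >= n_b)) {
        qtest_i <- qtest_i + 1L
        seq_ids <- c(seq_ids, sprintf("b%d_qctest%02d", b, qtest_i))
        seq_roles <- c(seq_roles, "qc_test")
      } else if (s_i < n_b) {
        s_i <- s_i + 1L
        seq_ids <- c(seq_ids, sprintf("b%d_s%02d", b, s_i))
        seq_roles <- c(seq_roles, "sample")
      }
    }
    # close the batch with a QC_train (and guarantee >= 2 for model fitting)
    while (sum(seq_roles == "qc_train") < 2L ||
           seq_roles[length(seq_roles)] != "qc_train") {
      seq_ids <- c(seq_ids, sprintf("b%d_qctrain%02d", b,
                                    sum(seq_roles == "qc_train") + 1L))
      seq_roles <- c(seq_roles, "qc_train")
    }
    all_rows[[b]] <- data.frame(
      sample_id = seq_ids, role = seq_roles,
      injection_order = seq_along(seq_ids), batch_id = paste0("b", b),
      tissue = "pool",
      replicate_group = ifelse(seq_roles == "qc_train", "qc_pool",
                        ifelse(seq_roles == "qc_test", "qc_extract",
                               seq_ids)),
      dilution_factor = 1)
  }
  sheet_df <- do.call(rbind, all_rows)
  sheet <- SampleSheet(sheet_df)
  n_total <- max(sheet_df$injection_order)
  total_frac <- stats::runif(n_features, -spec$slope_range, spec$slope_range)
  if (spec$kind == "none") total_frac[] <- 0
  slope_per_order <- total_frac / n_total
  mat <- matrix(NA_real_, n_features, nrow(sheet_df),
                dimnames = list(sprintf("F%04d", seq_len(n_features)),
                                sheet_df$sample_id))
  for (b in seq_len(n_batches)) {
    in_b <- sheet_df$batch_id == paste0("b", b)
    ordv <- sheet_df$injection_order[in_b]
    trend <- outer(slope_per_order, ordv - 1) + 1  # 1 + r*(order-1)
    noise <- matrix(.lognoise(n_features * sum(in_b), spec$noise_cv),
                    n_features)
    mat[, in_b] <- base * trend * spec$batch_offsets[b] * noise
  }
  list(table = mat, sheet = sheet,
       truth = list(base = base, slope_per_order = slope_per_order,
                    total_frac = total_frac,
                    batch_offsets = spec$batch_offsets, spec = spec))
}

#' Simulate an annotated feature table
#'
#' Spectral-library match scores are drawn uniformly, with probability
#' `p_high_score` of landing strictly above 90; each of the six exact-mass
#' databases flags the feature independently with probability
#' `p_library_hit`.  The expected pass count of the putative-identification
#' filter is therefore
#' `n_features * p_high_score * (1 - (1 - p_library_hit)^6)`.
#'
#' @param n_features number of features.
#' @param p_high_score probability of a score strictly above 90.
#' @param p_library_hit per-database hit probability.
#' @param seed RNG seed.
#' @return data.frame with `feature_id`, `mz`, `rt`, `mzcloud_score`,
#'   `library_hits`.
#' @export
makeAnnotations <- function(n_features, p_high_score, p_library_hit,
                            seed = 1L) {
  stopifnot(p_high_score >= 0, p_high_score <= 1,
            p_library_hit >= 0, p_library_hit <= 1)
  set.seed(seed)
  high <- stats::runif(n_features) < p_high_score
  score <- ifelse(high, stats::runif(n_features, 90, 100),
                  stats::runif(n_features, 0, 90))
  score[high & score <= 90] <- 90 + 1e-9  # strictly above the threshold
  hits <- vapply(seq_len(n_features), function(i) {
    hit <- stats::runif(6) < p_library_hit
    paste(.LIBRARY_VOCAB[hit], collapse = ";")
  }, character(1))
  mz <- stats::runif(n_features, 70, 1000)
  rt <- stats::runif(n_features, 0.5, 14)
  data.frame(feature_id = featureId(mz, rt), mz = mz, rt = rt,
             mzcloud_score = score, library_hits = hits)
}
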