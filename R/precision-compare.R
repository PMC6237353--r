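## RSD / accuracy metrics and the targeted-versus-non-targeted and
## chromatography/ionization comparisons.

#' Relative standard deviation in percent
#'
#' Sample standard deviation (n−1 denominator, appropriate for the small
#' replicate groups of method validation) divided by the absolute mean,
#' times 100.
#'
#' @param values numeric vector.
#' @return RSD in %; `NA` with fewer than 2 finite values; `NaN` when the
#'   mean is zero.
#' @examples
#' rsd(c(1, 2, 3))  # 50
#' @export
rsd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NaN)
  stats::sd(values) / abs(m) * 100
}

#' Technical, within-batch and between-batch precision
#'
#' Builds a precision report over replicate measurements:
#' `technical` — RSD over repeated injections of one extract (rows sharing
#' a `replicate_group`), averaged over groups when several exist;
#' `within_batch` — RSD over the extraction replicates of one batch,
#' averaged over batches; `between_batch` — RSD over all extraction
#' replicates pooled across batches.  Groups with fewer than two values are
#' omitted (with a message).
#'
#' @param conc samples-by-analytes matrix of concentrations (µM) or
#'   intensities.
#' @param sheet a [SampleSheet-class] covering the rows; `replicate_group`
#'   and `batch_id` drive the grouping.
#' @param roles sample roles included in the report (default `"sample"`).
#' @return data.frame with `analyte`, `scope`, `n`, `mean_value`,
#'   `rsd_pct`.
#' @export
precisionReport <- function(conc, sheet, roles = "sample") {
  stopifnot(is(sheet, "SampleSheet"))
  meta <- sheet[match(rownames(conc), sheet$sample_id), ]
  keep <- meta$role %in% roles
  conc <- conc[keep, , drop = FALSE]
  meta <- meta[keep, ]
  rows <- list()
  for (a in colnames(conc)) {
    v <- conc[, a]
    tech <- vapply(split(v, meta$replicate_group), rsd, numeric(1))
    tech_n <- vapply(split(v, meta$replicate_group), function(x)
      sum(is.finite(x)), integer(1))
    tech_ok <- is.finite(tech)
    if (any(tech_n >= 2L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a, scope = "technical", n = sum(tech_n[tech_ok]),
        mean_value = mean(v[meta$replicate_group %in%
                              names(tech)[tech_ok]], na.rm = TRUE),
        rsd_pct = mean(tech[tech_ok]))
    }
    wb <- vapply(split(v, meta$batch_id), rsd, numeric(1))
    wb_ok <- is.finite(wb)
    if (any(wb_ok))
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a, scope = "within_batch",
        n = sum(is.finite(v[meta$batch_id %in% names(wb)[wb_ok]])),
        mean_value = mean(v[meta$batch_id %in% names(wb)[wb_ok]],
                          na.rm = TRUE),
        rsd_pct = mean(wb[wb_ok]))
    bb <- rsd(v)
    if (is.finite(bb))
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a, scope = "between_batch", n = sum(is.finite(v)),
        mean_value = mean(v, na.rm = TRUE), rsd_pct = bb)
    else
      message("precisionReport: '", a, "' has fewer than 2 values; omitted")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accuracy against certified reference concentrations
#'
#' Compares measured means with certificate values (e.g. the SRM 1950
#' plasma certificate with its expanded uncertainties):
#' `accuracy_pct = measured / reference × 100`.  Analytes inside the stated
#' acceptance band (endpoints inclusive, default 50–150%) are flagged.
#'
#' @param measured named numeric vector of measured mean concentrations,
#'   µM.
#' @param reference data.frame with `analyte`, `reference_value` (µM) and
#'   optionally `reference_uncertainty` (µM, expanded uncertainty).
#' @param band inclusive lower/upper accuracy bounds in %.
#' @return data.frame with `analyte`, `measured_mean`, `reference_value`,
#'   `reference_uncertainty`, `accuracy_pct`, `in_band`.
#' @export
accuracyVsReference <- function(measured, reference, band = c(50, 150)) {
  stopifnot(!is.null(names(measured)),
            all(c("analyte", "reference_value") %in% colnames(reference)))
  if (any(reference$reference_value <= 0))
    stop("reference values must be > 0", call. = FALSE)
  if (!"reference_uncertainty" %in% colnames(reference))
    reference$reference_uncertainty <- NA_real_
  common <- intersect(names(measured), reference$analyte)
  skipped <- setdiff(names(measured), common)
  if (length(skipped))
    message("accuracyVsReference: no reference for ",
            paste(skipped, collapse = ", "), "; skipped")
  ref <- reference[match(common, reference$analyte), ]
  acc <- measured[common] / ref$reference_value * 100
  data.frame(analyte = common, measured_mean = unname(measured[common]),
             reference_value = ref$reference_value,
             reference_uncertainty = ref$reference_uncertainty,
             accuracy_pct = unname(acc),
             in_band = unname(acc >= band[1] & acc <= band[2]))
}

#' Compare targeted and non-targeted precision per matched compound
#'
#' Given per-compound RSDs from a targeted platform and per-feature RSDs
#' from a non-targeted platform, plus an explicit compound-to-feature map,
#' declares a winner per pair (strictly lower RSD; tie when equal) and
#' summarizes counts and mean RSDs over the matched set.  Pairs missing an
#' RSD on either side are excluded and counted separately.
#'
#' @param targeted_rsd named numeric vector, % RSD per compound.
#' @param nontarget_rsd named numeric vector, % RSD per feature.
#' @param mapping data.frame with `compound` and `feature_id`.
#' @return list: `pairs` (data.frame with `compound`, `feature_id`,
#'   `targeted_rsd`, `nontarget_rsd`, `winner`), `summary` (data.frame with
#'   `n_matched`, `n_targeted_better`, `n_nontarget_better`, `n_ties`,
#'   `n_excluded`, `mean_targeted_rsd`, `mean_nontarget_rsd`).
#' @export
comparePlatforms <- function(targeted_rsd, nontarget_rsd, mapping) {
  stopifnot(all(c("compound", "feature_id") %in% colnames(mapping)),
            nrow(mapping) > 0L)
  t_rsd <- targeted_rsd[mapping$compound]
  n_rsd <- nontarget_rsd[mapping$feature_id]
  ok <- is.finite(t_rsd) & is.finite(n_rsd)
  winner <- ifelse(t_rsd < n_rsd, "targeted",
                   ifelse(n_rsd < t_rsd, "nontarget", "tie"))
  pairs <- data.frame(compound = mapping$compound,
                      feature_id = mapping$feature_id,
                      targeted_rsd = unname(t_rsd),
                      nontarget_rsd = unname(n_rsd),
                      winner = ifelse(ok, winner, NA_character_))
  inc <- pairs[ok, , drop = FALSE]
  summary <- data.frame(
    n_matched = nrow(inc),
    n_targeted_better = sum(inc$winner == "targeted"),
    n_nontarget_better = sum(inc$winner == "nontarget"),
    n_ties = sum(inc$winner == "tie"),
    n_excluded = sum(!ok),
    mean_targeted_rsd = mean(inc$targeted_rsd),
    mean_nontarget_rsd = mean(inc$nontarget_rsd))
  list(pairs = pairs, summary = summary)
}

#' Feature-count comparison across chromatography and ionization
#'
#' Summarizes how many features each chromatography/polarity combination
#' produced for one tissue, as counts and as percentages of the tissue
#' total, and derives the two headline ratios: positive-versus-negative
#' ionization (sum over both columns) and HILIC-versus-C18 (sum over both
#' polarities).  Each ratio is reported both as "X% of" (ratio × 100) and
#' "X% more" (increment over 100%) to keep the two readings apart.
#'
#' @param counts data.frame with `chromatography` (`"C18"`/`"HILIC"`),
#'   `polarity` (`"pos"`/`"neg"` or `"+"`/`"-"`), `n_features`; or a named
#'   list of feature tables/matrices (names like `"HILIC_pos"`), counted by
#'   rows.
#' @param tissue label carried into the output.
#' @return list: `table` (counts with `pct_of_tissue_total`), `ratios`
#'   (data.frame with `metric`, `pct_of`, `pct_more`; `NA` when a
#'   denominator is zero).
#' @export
featureCountSummary <- function(counts, tissue = "") {
  if (is.list(counts) && !is.data.frame(counts)) {
    stopifnot(!is.null(names(counts)))
    parts <- strsplit(names(counts), "_", fixed = TRUE)
    counts <- data.frame(
      chromatography = vapply(parts, `[`, character(1), 1),
      polarity = vapply(parts, `[`, character(1), 2),
      n_features = vapply(counts, function(x)
        nrow(.as_feature_matrix(x)), integer(1)))
  }
  stopifnot(all(c("chromatography", "polarity", "n_features") %in%
                  colnames(counts)), nrow(counts) >= 2L)
  sign_map <- c("+" = "pos", "-" = "neg")
  signed <- counts$polarity %in% names(sign_map)
  counts$polarity[signed] <- sign_map[counts$polarity[signed]]
  if (!all(counts$polarity %in% c("pos", "neg")))
    stop("polarity must be pos/neg or +/-", call. = FALSE)
  total <- sum(counts$n_features)
  tab <- counts[order(counts$chromatography, counts$polarity), ]
  tab$tissue <- tissue
  tab$pct_of_tissue_total <- tab$n_features / total * 100
  rownames(tab) <- NULL
  ratio <- function(num, den)
    if (den == 0) c(NA_real_, NA_real_) else c(num / den * 100,
                                               (num / den - 1) * 100)
  pos <- sum(tab$n_features[tab$polarity == "pos"])
  neg <- sum(tab$n_features[tab$polarity == "neg"])
  hil <- sum(tab$n_features[tab$chromatography == "HILIC"])
  c18 <- sum(tab$n_features[tab$chromatography == "C18"])
  r1 <- ratio(pos, neg); r2 <- ratio(hil, c18)
  ratios <- data.frame(metric = c("pos_vs_neg", "hilic_vs_c18"),
                       pct_of = c(r1[1], r2[1]),
                       pct_more = c(r1[2], r2[2]))
  list(table = tab, ratios = ratios)
}
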