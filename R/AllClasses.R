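#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Controlled vocabularies ---------------------------------------------------

.SAMPLE_ROLES <- c("sample", "blank", "cal_standard", "qc_train", "qc_test")

.ANALYTE_CLASSES <- c("amino_acid", "biogenic_amine", "neurotransmitter",
                      "nucleobase", "carnitine", "PC", "lysoPC", "SM", "other")

.LIPID_CLASSES <- c("PC", "lysoPC", "SM", "carnitine")

.LIBRARY_VOCAB <- c("BioCyc", "HMDB", "KEGG", "LipidMaps", "PubChem", "SMPDB")

.SHEET_REQUIRED <- c("sample_id", "role", "injection_order", "batch_id",
                     "tissue", "dilution_factor")

## SampleSheet ---------------------------------------------------------------

#' Per-injection sample metadata
#'
#' A `SampleSheet` holds one row per injection: the sample identifier, its
#' role in the analytical sequence (`sample`, `blank`, `cal_standard`,
#' `qc_train` or `qc_test`), the injection order, the extraction/analysis
#' batch, the tissue, an optional replicate grouping and the dilution factor
#' applied before injection.  Pooled technical-replicate QCs used to fit
#' drift models carry role `qc_train`; extraction-replicate QCs used to judge
#' a correction carry role `qc_test`.
#'
#' Validity enforces: roles drawn from the fixed vocabulary; injection order
#' strictly positive and unique within each batch; every QC row assigned to a
#' batch; dilution factors strictly positive.
#'
#' @seealso [SampleSheet()], [readSampleSheet()]
#' @export
setClass("SampleSheet", contains = "DFrame")

setValidity("SampleSheet", function(object) {
  msg <- character()
  miss <- setdiff(.SHEET_REQUIRED, colnames(object))
  if (length(miss))
    return(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  if (nrow(object) == 0L)
    return(TRUE)
  bad_role <- setdiff(unique(object$role), .SAMPLE_ROLES)
  if (length(bad_role))
    msg <- c(msg, paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  ord <- object$injection_order
  if (!is.numeric(ord) || anyNA(ord) || any(ord <= 0) || any(ord != round(ord)))
    msg <- c(msg, "injection_order must be a strictly positive integer")
  else {
    key <- paste(object$batch_id, ord, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])
      msg <- c(msg, paste0("duplicate (batch_id, injection_order): ",
                           paste(gsub("\r", "/", dup), collapse = ", ")))
    }
  }
  qc <- object$role %in% c("qc_train", "qc_test")
  if (any(qc & (is.na(object$batch_id) | object$batch_id == "")))
    msg <- c(msg, "every qc_train/qc_test sample must have a batch_id")
  df <- object$dilution_factor
  if (!is.numeric(df) || anyNA(df) || any(df <= 0))
    msg <- c(msg, "dilution_factor must be > 0")
  if (anyDuplicated(object$sample_id))
    msg <- c(msg, "sample_id must be unique")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a SampleSheet
#'
#' @param df data.frame (or DataFrame) with at least the columns
#'   `sample_id`, `role`, `injection_order`, `batch_id`, `tissue`,
#'   `dilution_factor`.  A `replicate_group` column is added (defaulting to
#'   `sample_id`) when absent; extra columns are preserved untouched.
#' @return A validated [SampleSheet-class] object.
#' @examples
#' sheet <- SampleSheet(data.frame(
#'   sample_id = c("QC1", "S1"), role = c("qc_train", "sample"),
#'   injection_order = 1:2, batch_id = "b1", tissue = "plasma",
#'   dilution_factor = 5))
#' @export
SampleSheet <- function(df = data.frame(sample_id = character(),
                                        role = character(),
                                        injection_order = integer(),
                                        batch_id = character(),
                                        tissue = character(),
                                        dilution_factor = numeric())) {
  df <- as.data.frame(df)
  miss <- setdiff(.SHEET_REQUIRED, colnames(df))
  if (length(miss))
    stop("sample sheet is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"replicate_group" %in% colnames(df))
    df$replicate_group <- as.character(df$sample_id)
  df$sample_id   <- as.character(df$sample_id)
  df$role        <- as.character(df$role)
  df$batch_id    <- as.character(df$batch_id)
  df$tissue      <- as.character(df$tissue)
  if (nrow(df)) df$injection_order <- as.integer(df$injection_order)
  new("SampleSheet", DataFrame(df, row.names = df$sample_id))
}

## TargetPanel ---------------------------------------------------------------

#' Targeted panel definition
#'
#' A `TargetPanel` describes the analytes of a targeted assay: analyte name,
#' compound class, the internal standard (IS) assigned for ratio-based
#' quantification, the IS concentration in µM, the monoisotopic mass and, for
#' lipid species, the fatty-acid carbon and double-bond counts parsed from
#' the class/C:DB nomenclature (e.g. `PCaaC34:0`, `lysoPCaC20:2`,
#' `SM(d18:0/C18:1)`, `C2:0`).
#'
#' Validity enforces: unique analyte names; exactly one IS per analyte
#' (non-empty `is_name`); lipid-class analytes carry carbon and double-bond
#' counts; `conc_is` strictly positive where given.
#'
#' @seealso [TargetPanel()], [readTargetPanel()], [parseLipidSpecies()]
#' @export
setClass("TargetPanel", contains = "DFrame")

setValidity("TargetPanel", function(object) {
  msg <- character()
  req <- c("name", "analyte_class", "is_name", "conc_is")
  miss <- setdiff(req, colnames(object))
  if (length(miss))
    return(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  if (nrow(object) == 0L)
    return(TRUE)
  if (anyDuplicated(object$name))
    msg <- c(msg, "analyte names must be unique")
  bad <- setdiff(unique(object$analyte_class), .ANALYTE_CLASSES)
  if (length(bad))
    msg <- c(msg, paste0("unknown analyte_class: ", paste(bad, collapse = ", ")))
  if (any(is.na(object$is_name) | object$is_name == ""))
    msg <- c(msg, "every analyte must map to exactly one internal standard")
  ci <- object$conc_is
  if (!is.numeric(ci) || any(!is.na(ci) & ci <= 0))
    msg <- c(msg, "conc_is must be > 0 where given")
  lip <- object$analyte_class %in% .LIPID_CLASSES
  if (any(lip)) {
    if (!all(c("n_carbons", "n_double_bonds") %in% colnames(object)) ||
        anyNA(object$n_carbons[lip]) || anyNA(object$n_double_bonds[lip]))
      msg <- c(msg, "lipid analytes must carry n_carbons and n_double_bonds")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a TargetPanel
#'
#' @param df data.frame with columns `name`, `analyte_class`, `is_name`,
#'   `conc_is` (µM) and optionally `hmdb_id`, `monoisotopic_mass` (Da),
#'   `n_carbons`, `n_double_bonds`, `bond_code`.
#' @return A validated [TargetPanel-class] object.
#' @export
TargetPanel <- function(df) {
  df <- as.data.frame(df)
  for (col in c("hmdb_id", "bond_code"))
    if (!col %in% colnames(df)) df[[col]] <- NA_character_
  for (col in c("monoisotopic_mass"))
    if (!col %in% colnames(df)) df[[col]] <- NA_real_
  for (col in c("n_carbons", "n_double_bonds"))
    if (!col %in% colnames(df)) df[[col]] <- NA_integer_
  df$name <- as.character(df$name)
  new("TargetPanel", DataFrame(df, row.names = df$name))
}

## MetaboExperiment ----------------------------------------------------------

#' Intensity matrix with sample metadata
#'
#' `MetaboExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' for metabolomics signal tables: the `"intensity"` assay holds one row per
#' analyte or feature and one column per injection (peak areas for MRM
#' acquisitions, feature intensities for high-resolution data), `colData`
#' carries the [SampleSheet-class] fields and `rowData` carries per-feature
#' `mz` (Th) and `rt` (minutes) plus annotation columns
#' (`best_match_name`, `mzcloud_score`, `library_hits`) when available.
#'
#' Validity enforces non-negative intensities (missing values allowed and
#' kept distinct from zero), positive `mz` and non-negative `rt`.
#'
#' @seealso [MetaboExperiment()], [readFeatureTable()], [readAreaMatrix()]
#' @export
setClass("MetaboExperiment", contains = "SummarizedExperiment")

setValidity("MetaboExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    return("assay 'intensity' is required")
  x <- assay(object, "intensity")
  if (any(x < 0, na.rm = TRUE))
    msg <- c(msg, "negative intensities are not allowed")
  rd <- rowData(object)
  if ("mz" %in% colnames(rd) && any(rd$mz <= 0, na.rm = TRUE))
    msg <- c(msg, "mz must be > 0")
  if ("rt" %in% colnames(rd) && any(rd$rt < 0, na.rm = TRUE))
    msg <- c(msg, "rt must be >= 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a MetaboExperiment
#'
#' @param intensity numeric matrix, analytes/features in rows, samples in
#'   columns; non-negative, `NA` for missing.
#' @param sheet a [SampleSheet-class] covering the matrix columns (matched
#'   by `sample_id`).
#' @param rowData optional per-feature DataFrame (`mz`, `rt`, annotation).
#' @return A [MetaboExperiment-class].
#' @export
MetaboExperiment <- function(intensity, sheet, rowData = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(colnames(intensity)))
    stop("intensity matrix must have sample_id column names", call. = FALSE)
  if (!all(colnames(intensity) %in% sheet$sample_id))
    stop("intensity columns absent from sample sheet: ",
         paste(setdiff(colnames(intensity), sheet$sample_id), collapse = ", "),
         call. = FALSE)
  cd <- sheet[match(colnames(intensity), sheet$sample_id), , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = as(cd, "DFrame"))
  if (!is.null(rowData))
    SummarizedExperiment::rowData(se) <- rowData
  new("MetaboExperiment", se)
}

#' @describeIn MetaboExperiment the intensity assay matrix.
#' @param object,x a `MetaboExperiment`.
#' @export
intensities <- function(x) assay(x, "intensity")

#' @describeIn MetaboExperiment the sample sheet stored in `colData`.
#' @export
sampleSheet <- function(x) new("SampleSheet", as(colData(x), "DFrame"))

## CalibrationModel ----------------------------------------------------------

#' Fitted calibration curve
#'
#' Per-analyte calibration response model: linear or quadratic, fitted by
#' weighted least squares with weighting `inv_x_squared` (weight 1/conc²),
#' `log_log` (polynomial fitted in log10(conc)–log10(response) space,
#' unweighted) or `none`.  `coefficients` are on the regression scale,
#' intercept first.  `r` is the Pearson correlation of fitted versus observed
#' responses on the regression scale.  `concRange`/`responseRange` bound the
#' calibrated region used for inversion and extrapolation flagging.
#'
#' @seealso [fitCalibration()], [invertCalibration()]
#' @export
setClass("CalibrationModel",
  representation(analyte = "character", kind = "character",
                 weighting = "character", coefficients = "numeric",
                 r = "numeric", concRange = "numeric",
                 responseRange = "numeric"))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("linear", "quadratic"))
    msg <- c(msg, "kind must be 'linear' or 'quadratic'")
  if (!object@weighting %in% c("inv_x_squared", "log_log", "none"))
    msg <- c(msg, "unknown weighting")
  n_expect <- if (identical(object@kind, "linear")) 2L else 3L
  if (length(object@coefficients) != n_expect)
    msg <- c(msg, sprintf("%s model must have %d coefficients",
                          object@kind, n_expect))
  if (length(object@concRange) != 2L ||
      !(object@concRange[1] < object@concRange[2]))
    msg <- c(msg, "concRange must satisfy min < max")
  if (!is.finite(object@r) || abs(object@r) > 1 + 1e-8)
    msg <- c(msg, "r must be finite and within [-1, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel '%s': %s fit, weighting=%s\n",
              object@analyte, object@kind, object@weighting))
  cat("  coefficients:", signif(object@coefficients, 6), "\n")
  cat(sprintf("  r = %.4f, range = [%g, %g] uM\n", object@r,
              object@concRange[1], object@concRange[2]))
})

## DriftModelSet -------------------------------------------------------------

#' Per-feature linear drift models
#'
#' One row per feature: the OLS `slope` (intensity per injection) and
#' `intercept` of QC_train intensity on injection order, the `anchor` level
#' the corrected series is rescaled to (mean fitted QC level), the number of
#' QC injections used and whether the fit succeeded (`fit_ok`; features with
#' fewer than two finite QC values are passed through uncorrected).
#'
#' @seealso [fitLinearSequence()], [applyDrift()]
#' @export
setClass("DriftModelSet", contains = "DFrame")

setValidity("DriftModelSet", function(object) {
  req <- c("feature_id", "slope", "intercept", "anchor", "n_qc_used", "fit_ok")
  miss <- setdiff(req, colnames(object))
  if (length(miss))
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  ok <- object$fit_ok
  if (any(ok & object$n_qc_used < 2L))
    return("fit_ok requires n_qc_used >= 2")
  if (any(ok & !(object$anchor > 0)))
    return("anchor must be > 0 when fit_ok")
  TRUE
})

## LipidSpecies --------------------------------------------------------------

#' A lipid species named by class, carbons and double bonds
#'
#' Parsed form of the class/C:DB nomenclature used for flow-injection lipid
#' panels: `PCaaC34:0` (diacyl phosphatidylcholine, 34 fatty-acid carbons,
#' no double bond), `PCaeC36:4` (acyl-alkyl), `lysoPCaC20:2`,
#' `SM(d18:0/C18:1)` (sphingomyelin with explicit sphingoid base and fatty
#' acid), shorthand `SMC16:0`, and acylcarnitines `C2:0` or `C0`.  The
#' nomenclature does not locate double bonds nor split carbons over side
#' chains.  `carbons`/`doubleBonds` are the fatty-acid counts of the name;
#' sphingoid base counts are kept separately for SMs.
#'
#' @seealso [parseLipidSpecies()], [formatLipidSpecies()], [totalCarbons()]
#' @export
setClass("LipidSpecies",
  representation(name = "character", lipidClass = "character",
                 carbons = "integer", doubleBonds = "integer",
                 sphingoidCarbons = "integer", sphingoidDoubleBonds = "integer",
                 bondCode = "character"))

setValidity("LipidSpecies", function(object) {
  msg <- character()
  if (!object@lipidClass %in% .LIPID_CLASSES)
    msg <- c(msg, "lipidClass must be one of PC, lysoPC, SM, carnitine")
  if (is.na(object@carbons) || object@carbons < 0L)
    msg <- c(msg, "carbons must be a non-negative integer")
  if (is.na(object@doubleBonds) || object@doubleBonds < 0L)
    msg <- c(msg, "doubleBonds must be a non-negative integer")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "LipidSpecies", function(object) {
  cat(sprintf("LipidSpecies %s [%s, C%d:%d]\n", object@name,
              object@lipidClass, object@carbons, object@doubleBonds))
})
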