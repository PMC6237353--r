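## Delimited-text I/O for all tabular artifacts.
## Dialect: comma default, tab accepted; decimal point only; missing values
## are empty cells or "NA" and are kept distinct from literal zeros (blank
## subtraction needs true zeros).

.read_delim <- function(path, sep = ",") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("", "NA"), check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

.write_delim <- function(df, path, sep = ",") {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.9g", x)
    out[is.na(x)] <- NA_character_
    out
  })
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE, na = "",
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(NULL)
}

#' Read a sample sheet
#'
#' Reads per-injection metadata from delimited text.  Required columns:
#' `sample_id`, `role`, `injection_order`, `batch_id`, `tissue`,
#' `dilution_factor`; a `replicate_group` column is honoured when present
#' and any further columns are preserved as opaque extras.
#'
#' @param path path to a CSV (or TSV) file.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return A [SampleSheet-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,role,injection_order,batch_id,tissue,dilution_factor",
#'              "QC1,qc_train,1,b1,plasma,5"), f)
#' readSampleSheet(f)
#' @export
readSampleSheet <- function(path, sep = ",") {
  df <- .read_delim(path, sep)
  miss <- setdiff(.SHEET_REQUIRED, colnames(df))
  if (length(miss))
    stop("sample sheet is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  SampleSheet(df)
}

#' Read a target-panel definition
#'
#' @inheritParams readSampleSheet
#' @return A [TargetPanel-class].
#' @export
readTargetPanel <- function(path, sep = ",") {
  df <- .read_delim(path, sep)
  TargetPanel(df)
}

#' Read a peak-area matrix
#'
#' The file layout is one row per sample (first column `sample_id`) and one
#' column per analyte, holding non-negative peak areas in arbitrary units.
#' Empty cells are read as missing, never as zero.
#'
#' @inheritParams readSampleSheet
#' @param sheet optional [SampleSheet-class]; when given, every row id must
#'   occur in the sheet.
#' @return numeric matrix, samples in rows (named by `sample_id`), analytes
#'   in columns.
#' @export
readAreaMatrix <- function(path, sep = ",", sheet = NULL) {
  df <- .read_delim(path, sep)
  if (colnames(df)[1] != "sample_id")
    stop("first column of an area matrix must be 'sample_id'", call. = FALSE)
  ids <- as.character(df$sample_id)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (any(mat < 0, na.rm = TRUE))
    stop("negative peak areas are not allowed", call. = FALSE)
  if (!is.null(sheet)) {
    unknown <- setdiff(ids, sheet$sample_id)
    if (length(unknown))
      stop("sample id(s) absent from sample sheet: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  mat
}

#' Write a peak-area matrix
#'
#' @param mat samples-by-analytes numeric matrix with row and column names.
#' @param path output file.
#' @param sep field delimiter.
#' @export
writeAreaMatrix <- function(mat, path, sep = ",") {
  df <- data.frame(sample_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  .write_delim(df, path, sep)
}

#' Synthesize a feature identifier from m/z and retention time
#'
#' Fixed format: m/z to 4 decimals, `"@"`, RT to 2 decimals — the precision
#' relevant for high-resolution LC-MS features.
#'
#' @param mz,rt numeric vectors (Th, minutes).
#' @return character vector like `"760.5851@7.43"`.
#' @export
featureId <- function(mz, rt) sprintf("%.4f@%.2f", mz, rt)

#' Read a non-target feature table
#'
#' Consumes feature exports with columns `mz`, `rt`, one intensity column
#' per sample and optional annotation columns `best_match_name`,
#' `mzcloud_score` (0–100) and `library_hits` (`;`-separated subset of
#' BioCyc, HMDB, KEGG, LipidMaps, PubChem, SMPDB).  A `feature_id` column is
#' synthesized as [featureId()] when absent.  Empty intensity cells are kept
#' missing, never zero.
#'
#' @inheritParams readSampleSheet
#' @param sample_ids character vector naming the intensity columns expected.
#' @param sheet optional [SampleSheet-class] used as column metadata; when
#'   `NULL` a minimal sheet (role `sample`, one batch, unit dilution) is
#'   fabricated from `sample_ids`.
#' @return A [MetaboExperiment-class] with `mz`, `rt` and any annotation in
#'   `rowData`.
#' @export
readFeatureTable <- function(path, sample_ids, sep = ",", sheet = NULL) {
  df <- .read_delim(path, sep)
  for (col in c("mz", "rt"))
    if (!col %in% colnames(df))
      stop("feature table must contain an '", col, "' column", call. = FALSE)
  missing_ids <- setdiff(sample_ids, colnames(df))
  if (length(missing_ids))
    stop("sample id(s) absent from feature-table header: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  for (col in c("mz", "rt")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("non-numeric ", col, " at row ", bad[1], call. = FALSE)
      df[[col]] <- vn
    }
  }
  fid <- if ("feature_id" %in% colnames(df)) as.character(df$feature_id)
         else featureId(df$mz, df$rt)
  mat <- as.matrix(df[, sample_ids, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- fid
  rd <- DataFrame(feature_id = fid, mz = df$mz, rt = df$rt)
  annot_cols <- intersect(c("best_match_name", "mzcloud_score", "library_hits"),
                          colnames(df))
  has_annot <- length(annot_cols) > 0L
  if (has_annot) {
    rd$best_match_name <- if ("best_match_name" %in% annot_cols)
      as.character(df$best_match_name) else NA_character_
    rd$mzcloud_score <- if ("mzcloud_score" %in% annot_cols)
      as.numeric(df$mzcloud_score) else NA_real_
    rd$library_hits <- if ("library_hits" %in% annot_cols)
      as.character(df$library_hits) else NA_character_
  }
  if (is.null(sheet))
    sheet <- SampleSheet(data.frame(
      sample_id = sample_ids, role = "sample",
      injection_order = seq_along(sample_ids), batch_id = "b1",
      tissue = "", dilution_factor = 1))
  MetaboExperiment(mat, sheet, rowData = rd)
}

#' Write a report table deterministically
#'
#' Rows are ordered by analyte name then metric (falling back to all
#' character columns left to right), numeric cells formatted to 9
#' significant digits, so the same report always produces a byte-identical
#' file and values survive a write/read round trip.
#'
#' @param report non-empty data.frame (any report type).
#' @param path output file.
#' @param sep field delimiter.
#' @export
writeReport <- function(report, path, sep = ",") {
  report <- as.data.frame(report)
  if (nrow(report) == 0L)
    stop("refusing to write an empty report", call. = FALSE)
  keys <- intersect(c("analyte", "name", "feature_id", "metric", "scope",
                      "strategy", "qc_set"), colnames(report))
  if (!length(keys))
    keys <- colnames(report)[vapply(report, is.character, logical(1))]
  if (length(keys)) {
    ord <- do.call(order, unname(report[keys]))
    report <- report[ord, , drop = FALSE]
  }
  .write_delim(report, path, sep)
}

#' Read back a report written by [writeReport()]
#'
#' @inheritParams readSampleSheet
#' @return data.frame.
#' @export
readReport <- function(path, sep = ",") .read_delim(path, sep)

#' Convert an xlsx sheet to the canonical delimited form
#'
#' Read-only bridge for spreadsheet supplements: extracts one worksheet and
#' writes it as CSV so the rest of the package stays format-agnostic.
#' Requires the `readxl` package.
#'
#' @param path xlsx file.
#' @param out output CSV path.
#' @param sheet worksheet index or name.
#' @return `out`, invisibly.
#' @export
convertXlsx <- function(path, out, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("convertXlsx() requires the 'readxl' package", call. = FALSE)
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  .write_delim(df, out, sep = ",")
  invisible(out)
}

#' Package-wide tolerance and dialect defaults
#'
#' Central defaults used across the workflow: field delimiter, the
#' retention-time and m/z windows for fragment/parent matching, the
#' narrow and wide mass tolerances of the targeted/non-targeted
#' cross-check, and the putative-identification filter settings.
#' A YAML config file with any subset of these keys overrides them.
#'
#' @param path optional YAML file of overrides (requires the `yaml` package).
#' @return named list of defaults.
#' @export
metaboDefaults <- function(path = NULL) {
  defaults <- list(sep = ",", rt_tol = 0.05, mz_tol = 0.01,
                   mass_tol = 0.005, wide_tol = 0.5,
                   score_threshold = 90, min_libraries = 1L,
                   qc_every = 10L, proton_mass = 1.007276)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("config files require the 'yaml' package", call. = FALSE)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[names(user)] <- user
  }
  defaults
}
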