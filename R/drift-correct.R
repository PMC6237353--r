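## QC-anchored signal-drift and batch correction of feature tables, and the
## RSD-threshold benchmark comparing correction strategies.
##
## All corrections are multiplicative (ratio to a fitted trend or reference
## level): electrospray drift acts predominantly on the scale of the signal
## and a ratio correction preserves non-negativity.  Pooled technical QCs
## (role qc_train) train the models; extraction-replicate QCs (qc_test)
## judge them.

.as_feature_matrix <- function(table) {
  if (is(table, "MetaboExperiment")) intensities(table) else as.matrix(table)
}

.sheet_for <- function(mat, sheet) {
  unknown <- setdiff(colnames(mat), sheet$sample_id)
  if (length(unknown))
    stop("sample(s) absent from sheet: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sheet[match(colnames(mat), sheet$sample_id), ]
}

#' Internal-standard normalization
#'
#' Divides every feature's intensity by the intensity of its internal
#' standard in the same sample, then rescales by the IS grand mean so
#' corrected values stay on the original intensity scale.  Samples where the
#' IS is missing or zero are flagged missing with a warning.
#'
#' @param table features-by-samples matrix or [MetaboExperiment-class].
#' @param is_map either a single feature id used as IS for all features, or
#'   a named character vector mapping feature id -> IS feature id.
#' @return corrected matrix (IS rows are normalized against themselves and
#'   end up constant).
#' @export
isNormalize <- function(table, is_map) {
  mat <- .as_feature_matrix(table)
  if (is.null(names(is_map))) {
    if (length(is_map) != 1L)
      stop("unnamed is_map must be a single IS feature id", call. = FALSE)
    is_map <- stats::setNames(rep(is_map, nrow(mat)), rownames(mat))
  }
  out <- mat
  n_bad <- 0L
  for (f in rownames(mat)) {
    is_f <- is_map[[f]]
    if (is.null(is_f) || is.na(is_f)) next
    if (!is_f %in% rownames(mat))
      stop("IS feature '", is_f, "' not present in table", call. = FALSE)
    is_vals <- mat[is_f, ]
    bad <- is.na(is_vals) | is_vals == 0
    grand <- mean(is_vals[!bad])
    out[f, !bad] <- mat[f, !bad] / is_vals[!bad] * grand
    if (any(bad)) {
      out[f, bad] <- NA_real_
      n_bad <- n_bad + sum(bad)
    }
  }
  if (n_bad > 0L)
    warning("IS missing or zero in ", n_bad,
            " cell(s); corrected values set missing", call. = FALSE)
  out
}

#' Fit per-feature linear drift models on QC injections
#'
#' Ordinary least squares of QC_train intensity on injection order, one
#' model per feature.  Features with fewer than two finite QC values (or a
#' non-positive mean fitted level) get `fit_ok = FALSE` and are passed
#' through uncorrected by [applyDrift()].
#'
#' @param qc_values features-by-QC matrix of QC_train intensities.
#' @param orders injection orders of the QC_train columns.
#' @return A [DriftModelSet-class].
#' @export
fitLinearSequence <- function(qc_values, orders) {
  qc_values <- as.matrix(qc_values)
  stopifnot(ncol(qc_values) == length(orders))
  n_feat <- nrow(qc_values)
  slope <- intercept <- anchor <- rep(NA_real_, n_feat)
  n_used <- integer(n_feat); ok <- logical(n_feat)
  for (f in seq_len(n_feat)) {
    y <- qc_values[f, ]
    use <- is.finite(y)
    n_used[f] <- sum(use)
    if (n_used[f] < 2L) next
    x <- orders[use]; yy <- y[use]
    vx <- sum((x - mean(x))^2)
    b1 <- if (vx == 0) 0 else sum((x - mean(x)) * (yy - mean(yy))) / vx
    b0 <- mean(yy) - b1 * mean(x)
    a <- mean(b0 + b1 * x)
    slope[f] <- b1; intercept[f] <- b0; anchor[f] <- a
    ok[f] <- a > 0
  }
  new("DriftModelSet", DataFrame(
    feature_id = rownames(qc_values) %||% as.character(seq_len(n_feat)),
    slope = slope, intercept = intercept, anchor = anchor,
    n_qc_used = n_used, fit_ok = ok))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply fitted drift models to a table
#'
#' Multiplicative correction to the QC anchor level:
#' `corrected = raw * anchor / (intercept + slope * order)`.  Samples where
#' the fitted trend is non-positive become missing with a warning; features
#' whose fit failed pass through unchanged.
#'
#' @param table features-by-samples matrix (rows aligned with `models`).
#' @param models a [DriftModelSet-class] from [fitLinearSequence()].
#' @param orders injection orders of the table columns.
#' @return corrected matrix.
#' @export
applyDrift <- function(table, models, orders) {
  mat <- .as_feature_matrix(table)
  stopifnot(nrow(mat) == nrow(models), ncol(mat) == length(orders))
  out <- mat
  n_dropped <- 0L
  for (f in seq_len(nrow(mat))) {
    if (!models$fit_ok[f]) next
    trend <- models$intercept[f] + models$slope[f] * orders
    bad <- trend <= 0
    out[f, !bad] <- mat[f, !bad] * models$anchor[f] / trend[!bad]
    if (any(bad)) { out[f, bad] <- NA_real_; n_dropped <- n_dropped + sum(bad) }
  }
  if (n_dropped > 0L)
    warning("non-positive fitted trend in ", n_dropped,
            " cell(s); set missing", call. = FALSE)
  out
}

## Stage (i): per-batch ratio-to-trend correction to the batch's QC anchor.
.lin_seq_within <- function(mat, meta) {
  out <- mat
  for (b in unique(meta$batch_id)) {
    in_b <- meta$batch_id == b
    qc <- in_b & meta$role == "qc_train"
    if (sum(qc) < 2L) next  # nothing to train on: passthrough
    models <- fitLinearSequence(mat[, qc, drop = FALSE],
                                meta$injection_order[qc])
    out[, in_b] <- applyDrift(mat[, in_b, drop = FALSE], models,
                              meta$injection_order[in_b])
  }
  out
}

## Stage (ii): scale every feature so its per-batch QC_train mean equals the
## grand QC_train mean; batches without QC coverage are flagged.
.batch_rescale <- function(mat, meta) {
  batches <- unique(meta$batch_id)
  flags <- matrix(FALSE, nrow(mat), length(batches),
                  dimnames = list(rownames(mat), batches))
  if (length(batches) > 1L) {
    qc_all <- meta$role == "qc_train"
    grand <- rowMeans(mat[, qc_all, drop = FALSE], na.rm = TRUE)
    for (b in batches) {
      in_b <- meta$batch_id == b
      qc_b <- in_b & qc_all
      bmean <- rowMeans(mat[, qc_b, drop = FALSE], na.rm = TRUE)
      n_qc <- rowSums(!is.na(mat[, qc_b, drop = FALSE]))
      scale_ok <- n_qc >= 1L & is.finite(bmean) & bmean > 0
      flags[!scale_ok, b] <- TRUE
      mat[scale_ok, in_b] <- mat[scale_ok, in_b, drop = FALSE] *
        (grand[scale_ok] / bmean[scale_ok])
    }
  }
  attr(mat, "uncorrectable") <- flags
  mat
}

#' Linear sequence correction over an analytical run
#'
#' Fits [fitLinearSequence()] on the QC_train injections of each batch and
#' divides every injection by its fitted trend.  With
#' `anchor = "global"` (default, the standard QC-reference formulation)
#' each batch is then rescaled to the grand QC_train mean, so a multi-batch
#' run ends up on one common scale; `anchor = "batch"` leaves each batch at
#' its own mean fitted QC level.  On a single batch the two are identical.
#'
#' @param table features-by-samples matrix or [MetaboExperiment-class].
#' @param sheet a [SampleSheet-class] covering the columns.
#' @param anchor `"global"` (rescale batches to the grand QC mean) or
#'   `"batch"` (within-batch only).
#' @return corrected matrix.
#' @export
linearSequenceCorrect <- function(table, sheet,
                                  anchor = c("global", "batch")) {
  anchor <- match.arg(anchor)
  mat <- .as_feature_matrix(table)
  meta <- .sheet_for(mat, sheet)
  out <- .lin_seq_within(mat, meta)
  if (anchor == "global") {
    out <- .batch_rescale(out, meta)
    attr(out, "uncorrectable") <- NULL
  }
  out
}

#' QC-anchored batch correction
#'
#' Two explicit stages: (i) within-batch linear sequence correction and
#' (ii) between-batch scaling so every feature's QC_train mean is equal
#' across batches (scaled to the grand QC mean).  This fills the benchmark
#' slot of external batch-correction tools with a transparent QC-anchored
#' method of the same interface.  On a single batch it reduces exactly to
#' linear sequence correction.
#'
#' @inheritParams linearSequenceCorrect
#' @return corrected matrix; attribute `"uncorrectable"` is a logical
#'   features-by-batches matrix marking batches lacking QC coverage for a
#'   feature (passed through unscaled).
#' @export
batchAnchorCorrect <- function(table, sheet) {
  mat <- .as_feature_matrix(table)
  meta <- .sheet_for(mat, sheet)
  .batch_rescale(.lin_seq_within(mat, meta), meta)
}

.STRATEGY_STEPS <- c("none", "is_norm", "linear_sequence", "batch_anchor")

#' Run an ordered correction strategy
#'
#' Applies steps from `none`, `is_norm`, `linear_sequence`, `batch_anchor`
#' in the listed order.  The step list is validated up front (non-empty, no
#' repeats, IS map present when `is_norm` is included) so a misconfigured
#' strategy fails before any computation.  Applied steps are recorded in the
#' `"steps"` attribute of the result.
#'
#' @inheritParams linearSequenceCorrect
#' @param steps character vector of correction steps, applied in order.
#' @param is_map IS assignment for `is_norm` (see [isNormalize()]).
#' @return corrected matrix with attribute `"steps"`.
#' @export
runStrategy <- function(table, sheet, steps, is_map = NULL) {
  bad <- setdiff(steps, .STRATEGY_STEPS)
  if (!length(steps) || length(bad) || anyDuplicated(steps))
    stop("invalid strategy: steps must be a non-empty, non-repeating subset",
         " of {", paste(.STRATEGY_STEPS, collapse = ", "), "}", call. = FALSE)
  if ("is_norm" %in% steps && is.null(is_map))
    stop("strategy includes is_norm but no IS map was supplied",
         call. = FALSE)
  mat <- .as_feature_matrix(table)
  for (step in steps)
    mat <- switch(step,
      none = mat,
      is_norm = isNormalize(mat, is_map),
      linear_sequence = linearSequenceCorrect(mat, sheet),
      batch_anchor = batchAnchorCorrect(mat, sheet))
  attr(mat, "steps") <- steps
  attr(mat, "uncorrectable") <- NULL
  mat
}

#' The default seven-strategy comparison set
#'
#' Four single methods (`none`, IS normalization, linear sequence
#' correction, QC-anchored batch correction) and three combinations
#' (IS-first orderings plus linear sequence with between-batch rescale).
#'
#' @return named list of step vectors for [benchmarkStrategies()].
#' @export
defaultStrategies <- function() {
  list(
    none              = "none",
    is_norm           = "is_norm",
    linear_sequence   = "linear_sequence",
    batch_anchor      = "batch_anchor",
    "is_norm+linear_sequence" = c("is_norm", "linear_sequence"),
    "is_norm+batch_anchor"    = c("is_norm", "batch_anchor"),
    "linear_sequence+batch_anchor" = c("linear_sequence", "batch_anchor"))
}

#' Benchmark correction strategies by QC RSD thresholds
#'
#' Runs every strategy, computes per-feature RSDs over the QC_train and
#' QC_test samples separately, and counts features below 15% and below 30%
#' RSD — the figure of merit for drift correction of non-target data.
#'
#' @inheritParams runStrategy
#' @param strategies named list of step vectors (default
#'   [defaultStrategies()], dropping `is_norm` entries when `is_map` is
#'   `NULL`).
#' @param metabolites optional feature ids whose per-strategy RSDs are
#'   reported individually.
#' @return list of class `"CorrectionBenchmark"`: `summary` (data.frame
#'   with `strategy`, `qc_set`, `n_lt_15`, `n_lt_30`, `n_total`,
#'   `evaluable`), `rsd` (feature × strategy/qc-set matrix, %),
#'   `metabolites` (data.frame or NULL), `winner` (strategy with the
#'   highest `n_lt_30` per qc_set).
#' @export
benchmarkStrategies <- function(table, sheet, strategies = NULL,
                                is_map = NULL, metabolites = NULL) {
  mat <- .as_feature_matrix(table)
  meta <- .sheet_for(mat, sheet)
  if (is.null(strategies)) {
    strategies <- defaultStrategies()
    if (is.null(is_map))
      strategies <- strategies[!vapply(strategies, function(s)
        "is_norm" %in% s, logical(1))]
  }
  sets <- list(qc_train = meta$role == "qc_train",
               qc_test = meta$role == "qc_test")
  if (!any(sets$qc_train) || !any(sets$qc_test))
    stop("benchmark needs both qc_train and qc_test samples", call. = FALSE)
  rows <- list(); rsd_cols <- list()
  for (lab in names(strategies)) {
    corrected <- runStrategy(mat, sheet, strategies[[lab]], is_map = is_map)
    for (set_name in names(sets)) {
      cols <- sets[[set_name]]
      evaluable <- sum(cols) >= 2L
      feat_rsd <- if (evaluable)
        apply(corrected[, cols, drop = FALSE], 1, rsd)
      else rep(NA_real_, nrow(mat))
      rsd_cols[[paste(lab, set_name, sep = "|")]] <- feat_rsd
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = lab, qc_set = set_name,
        n_lt_15 = sum(feat_rsd < 15, na.rm = TRUE),
        n_lt_30 = sum(feat_rsd < 30, na.rm = TRUE),
        n_total = nrow(mat), evaluable = evaluable)
    }
  }
  summary <- do.call(rbind, rows)
  rsd_mat <- do.call(cbind, rsd_cols)
  rownames(rsd_mat) <- rownames(mat)
  met <- NULL
  if (!is.null(metabolites)) {
    keep <- intersect(metabolites, rownames(rsd_mat))
    met <- data.frame(metabolite = rep(keep, ncol(rsd_mat)),
                      column = rep(colnames(rsd_mat), each = length(keep)),
                      rsd_pct = as.vector(rsd_mat[keep, , drop = FALSE]))
  }
  winner <- vapply(names(sets), function(set_name) {
    sub <- summary[summary$qc_set == set_name & summary$evaluable, ]
    if (!nrow(sub)) NA_character_ else sub$strategy[which.max(sub$n_lt_30)]
  }, character(1))
  structure(list(summary = summary, rsd = rsd_mat, metabolites = met,
                 winner = winner),
            class = "CorrectionBenchmark")
}

#' @export
print.CorrectionBenchmark <- function(x, ...) {
  cat("CorrectionBenchmark:", nrow(x$rsd), "features,",
      length(unique(x$summary$strategy)), "strategies\n")
  print(x$summary, row.names = FALSE)
  cat("winner (n_lt_30):",
      paste(names(x$winner), x$winner, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
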