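## Internal-standard quantification, weighted calibration and detection
## limits for the targeted (MRM) workflows.

#' Internal-standard quantification of a peak area
#'
#' The ratio-based rule used throughout flow-injection and LC-MRM targeted
#' panels:
#' \deqn{Conc_{analyte} = \frac{Area_{analyte}}{Area_{IS}} \times Conc_{IS}
#'   \times Dilution}
#'
#' @param area_analyte non-negative analyte peak area (arbitrary units).
#' @param area_is strictly positive internal-standard peak area, same units.
#' @param conc_is internal-standard concentration, µM.
#' @param dilution_factor dilution applied before injection (> 0).
#' @param analyte,sample optional labels used in error messages.
#' @return concentration in µM; vectorized with recycling.
#' @examples
#' quantifyIS(2, 1, 0.5, 10)  # 10 uM
#' @export
quantifyIS <- function(area_analyte, area_is, conc_is, dilution_factor = 1,
                       analyte = NULL, sample = NULL) {
  lab <- function() {
    who <- c(analyte, sample)
    if (length(who)) paste0(" (", paste(who, collapse = "/"), ")") else ""
  }
  if (any(area_analyte < 0, na.rm = TRUE) || any(conc_is < 0, na.rm = TRUE) ||
      any(dilution_factor <= 0, na.rm = TRUE) || any(area_is < 0, na.rm = TRUE))
    stop("negative input to internal-standard quantification", lab(),
         call. = FALSE)
  if (any(area_is == 0, na.rm = TRUE))
    stop("internal-standard area is zero", lab(), call. = FALSE)
  area_analyte / area_is * conc_is * dilution_factor
}

## ----------------------------------------------------------------------
## Calibration curves

.cal_design <- function(conc, kind, weighting) {
  x <- if (identical(weighting, "log_log")) log10(conc) else conc
  if (identical(kind, "linear")) cbind(1, x) else cbind(1, x, x^2)
}

.cal_forward <- function(model, conc) {
  b <- model@coefficients
  loglog <- identical(model@weighting, "log_log")
  x <- if (loglog) log10(conc) else conc
  y <- b[1] + b[2] * x + if (length(b) == 3L) b[3] * x^2 else 0
  if (loglog) 10^y else y
}

#' Fit a calibration curve
#'
#' Weighted least squares of instrument response on standard concentration.
#' `weighting = "inv_x_squared"` uses weights \eqn{1/conc^2} (the standard
#' bioanalytical down-weighting of high standards so low-end relative bias
#' stays small under noise proportional to concentration);
#' `"log_log"` fits the polynomial in log10(conc)–log10(response) space,
#' unweighted; `"none"` is ordinary least squares.  The reported `r` is the
#' Pearson correlation of fitted versus observed responses on the regression
#' scale.
#'
#' @param conc standard concentrations, µM; at least 5 points for a linear
#'   fit, 6 for quadratic; strictly positive unless `weighting = "none"`.
#' @param response instrument responses (area or area ratio).
#' @param kind `"linear"` or `"quadratic"`.
#' @param weighting `"inv_x_squared"`, `"log_log"` or `"none"`.
#' @param analyte label stored in the model.
#' @return A [CalibrationModel-class].
#' @examples
#' m <- fitCalibration(1:6, 3 * (1:6), kind = "linear", weighting = "none")
#' m@coefficients  # ~ (0, 3)
#' @export
fitCalibration <- function(conc, response,
                           kind = c("linear", "quadratic"),
                           weighting = c("inv_x_squared", "log_log", "none"),
                           analyte = "") {
  kind <- match.arg(kind)
  weighting <- match.arg(weighting)
  ok <- is.finite(conc) & is.finite(response)
  conc <- conc[ok]; response <- response[ok]
  n_req <- if (kind == "linear") 5L else 6L
  if (length(conc) < n_req)
    stop(sprintf("calibration for '%s' needs at least %d points, got %d",
                 analyte, n_req, length(conc)), call. = FALSE)
  if (weighting != "none" && any(conc <= 0))
    stop("concentrations must be strictly positive with weighting '",
         weighting, "'", call. = FALSE)
  if (weighting == "log_log" && any(response <= 0))
    stop("responses must be strictly positive with log-log weighting",
         call. = FALSE)
  X <- .cal_design(conc, kind, weighting)
  y <- if (weighting == "log_log") log10(response) else response
  w <- if (weighting == "inv_x_squared") 1 / conc^2 else rep(1, length(conc))
  fit <- stats::lm.wfit(X, y, w)
  coefs <- unname(fit$coefficients)
  r <- stats::cor(fit$fitted.values, y)
  if (!is.finite(r)) r <- 1  # degenerate constant response
  model <- new("CalibrationModel", analyte = analyte, kind = kind,
               weighting = weighting, coefficients = coefs, r = r,
               concRange = range(conc), responseRange = c(0, 0))
  model@responseRange <- range(.cal_forward(model, range(conc)))
  validObject(model)
  model
}

## Roots of forward(conc) = response inside the calibration range.
## The forward model is a (possibly log-space) quadratic: split the range at
## the stationary point and bisect each monotone segment.
.cal_roots <- function(model, response) {
  loglog <- identical(model@weighting, "log_log")
  lim <- if (loglog) log10(model@concRange) else model@concRange
  b <- model@coefficients
  target <- if (loglog) log10(response) else response
  g <- function(x) b[1] + b[2] * x + (if (length(b) == 3L) b[3] * x^2 else 0) -
    target
  if (length(b) == 2L) {
    if (b[2] == 0) return(numeric())
    root <- (target - b[1]) / b[2]
    return(if (loglog) 10^root else root)
  }
  # search slightly beyond the calibrated range so flagged extrapolations
  # can still be inverted on the adjacent monotone segment
  ext <- lim + c(-1, 1) * diff(lim)
  cuts <- sort(unique(c(ext, lim, if (b[3] != 0) {
    s <- -b[2] / (2 * b[3])
    if (s > ext[1] && s < ext[2]) s
  })))
  roots <- numeric()
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i]; hi <- cuts[i + 1L]
    flo <- g(lo); fhi <- g(hi)
    if (flo == 0) roots <- c(roots, lo)
    if (fhi == 0) roots <- c(roots, hi)
    if (flo * fhi < 0)
      roots <- c(roots, stats::uniroot(g, c(lo, hi), tol = 1e-12)$root)
  }
  roots <- sort(unique(signif(roots, 12)))
  if (loglog) 10^roots else roots
}

#' Invert a calibration curve to a concentration
#'
#' Linear models are inverted algebraically; quadratic models by bisection
#' of the forward model on its monotone segments within the calibrated
#' concentration range (robust for log-log fits).  Responses below the
#' calibrated response range are reported as concentration 0 with
#' `below_range = TRUE`; responses above it are inverted and flagged
#' `extrapolated`.  A quadratic with two in-range roots raises an ambiguity
#' error rather than choosing silently.
#'
#' @param response instrument response(s).
#' @param model a [CalibrationModel-class].
#' @param dilution_factor multiplies the back-calculated concentration.
#' @return data.frame with columns `response`, `conc` (µM), `below_range`,
#'   `extrapolated`.
#' @export
invertCalibration <- function(response, model, dilution_factor = 1) {
  stopifnot(is(model, "CalibrationModel"))
  n <- length(response)
  conc <- numeric(n); below <- logical(n); extra <- logical(n)
  rlim <- model@responseRange
  # absorb float round-off of the fitted forward model at the range edges
  rtol <- 1e-8 * diff(rlim)
  for (i in seq_len(n)) {
    y <- response[i]
    if (!is.finite(y)) { conc[i] <- NA_real_; next }
    if (y < rlim[1] - rtol) { conc[i] <- 0; below[i] <- TRUE; next }
    if (y > rlim[2] + rtol) extra[i] <- TRUE
    y <- min(max(y, rlim[1]), if (extra[i]) y else rlim[2])
    roots <- .cal_roots(model, y)
    in_range <- roots[roots >= model@concRange[1] - 1e-9 &
                      roots <= model@concRange[2] + 1e-9]
    use <- if (length(in_range)) in_range else if (extra[i]) roots else numeric()
    if (length(use) == 0L)
      stop(sprintf("no real root in calibration range for '%s' (response %g)",
                   model@analyte, y), call. = FALSE)
    if (length(use) > 1L)
      stop(sprintf(
        "ambiguous inversion for '%s' (response %g): two roots in range",
        model@analyte, y), call. = FALSE)
    conc[i] <- use
  }
  data.frame(response = response, conc = conc * dilution_factor,
             below_range = below, extrapolated = extra)
}

#' Blank-based detection and quantification limits
#'
#' The flow-injection rule: LOD and LOQ are both taken as 10 times the mean
#' concentration measured in the blanks run with the batch; all-zero blanks
#' give 0.
#'
#' @param blank_concs non-negative blank concentrations, µM (at least one).
#' @return named numeric `c(lod = , loq = )`, µM.
#' @examples
#' blankLod(c(0.1, 0.3))  # lod = loq = 2
#' @export
blankLod <- function(blank_concs) {
  if (length(blank_concs) == 0L)
    stop("at least one blank concentration is required", call. = FALSE)
  if (any(blank_concs < 0, na.rm = TRUE))
    stop("blank concentrations must be non-negative", call. = FALSE)
  lod <- 10 * mean(blank_concs, na.rm = TRUE)
  c(lod = lod, loq = lod)
}

#' Signal-to-noise based detection limit
#'
#' For LC-MRM targets: three times the concentration-equivalent of the noise
#' at the lowest standard in which a peak was still measurable,
#' LOD = 3 × conc / (S/N).
#'
#' @param lowest_conc concentration of the lowest measurable standard, µM.
#' @param sn its signal-to-noise ratio (> 0).
#' @return LOD in µM.
#' @export
snLod <- function(lowest_conc, sn) {
  if (any(sn <= 0)) stop("signal-to-noise must be > 0", call. = FALSE)
  3 * lowest_conc / sn
}

#' Quantify a peak-area matrix against a target panel
#'
#' Applies internal-standard quantification ([quantifyIS()]) analyte by
#' analyte: each analyte's area is divided by the area of its assigned IS in
#' the same sample, scaled by the IS concentration and the sample's dilution
#' factor.  When blank injections are present, a per-analyte LOD is derived
#' from them by the 10× blank rule and concentrations are flagged (never
#' censored: downstream RSDs need values).
#'
#' @param areas samples-by-analytes matrix of peak areas, containing both
#'   analyte and IS columns.
#' @param panel a [TargetPanel-class] whose `is_name` values name IS columns
#'   of `areas`.
#' @param sheet a [SampleSheet-class] supplying `dilution_factor` and blank
#'   roles for the rows of `areas`.
#' @return list with `conc` (samples × analytes, µM), `lod` (named vector,
#'   µM; `NA` when no blanks) and `below_lod` (logical matrix).
#' @export
quantifyMatrix <- function(areas, panel, sheet) {
  stopifnot(is(panel, "TargetPanel"), is(sheet, "SampleSheet"))
  samples <- rownames(areas)
  unknown <- setdiff(samples, sheet$sample_id)
  if (length(unknown))
    stop("sample(s) absent from sheet: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  meta <- sheet[match(samples, sheet$sample_id), ]
  analytes <- intersect(panel$name, colnames(areas))
  if (!length(analytes))
    stop("no panel analytes found in area matrix", call. = FALSE)
  conc <- matrix(NA_real_, length(samples), length(analytes),
                 dimnames = list(samples, analytes))
  for (a in analytes) {
    is_col <- panel[a, "is_name"]
    if (!is_col %in% colnames(areas))
      stop("internal standard '", is_col, "' (for ", a,
           ") not in area matrix", call. = FALSE)
    conc[, a] <- quantifyIS(areas[, a], areas[, is_col],
                            panel[a, "conc_is"], meta$dilution_factor,
                            analyte = a)
  }
  is_blank <- meta$role == "blank"
  lod <- rep(NA_real_, length(analytes)); names(lod) <- analytes
  if (any(is_blank))
    for (a in analytes)
      lod[a] <- blankLod(conc[is_blank, a])[["lod"]]
  below <- sweep(conc, 2, ifelse(is.na(lod), -Inf, lod), `<`)
  list(conc = conc, lod = lod, below_lod = below)
}
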