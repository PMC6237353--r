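## Putative-identification filtering of annotated feature tables, lipid
## fragment-to-parent matching, and the targeted/non-targeted cross-check.

.PROTON_MASS <- 1.007276

.annot_frame <- function(features) {
  if (is(features, "MetaboExperiment")) {
    rd <- as.data.frame(rowData(features))
    rd$mean_intensity <- rowMeans(intensities(features), na.rm = TRUE)
    rd
  } else as.data.frame(features)
}

.split_hits <- function(hits) {
  if (is.na(hits) || !nzchar(hits)) return(character())
  intersect(trimws(strsplit(hits, ";", fixed = TRUE)[[1]]), .LIBRARY_VOCAB)
}

#' Putative-identification filter
#'
#' A feature counts as putatively identified (level 2) when its spectral
#' library match score is strictly greater than `score_threshold` (default
#' 90, i.e. "higher than 90%") AND the same identification is suggested by
#' at least `min_libraries` of the six exact-mass databases (BioCyc, HMDB,
#' KEGG, LipidMaps, PubChem, SMPDB).  Features without annotation fail and
#' are tallied separately as unannotated.
#'
#' @param features a [MetaboExperiment-class] with annotation columns in
#'   `rowData`, or a data.frame with `feature_id`, `mzcloud_score` (0–100)
#'   and `library_hits` (`;`-separated database names).
#' @param score_threshold strict lower bound on the match score.
#' @param min_libraries minimum number of corroborating databases.
#' @return list: `passing` (data.frame subset), `n_pass`, `n_fail`,
#'   `n_unannotated`.
#' @examples
#' df <- data.frame(feature_id = c("a", "b", "c"),
#'                  mzcloud_score = c(95, 90, 95),
#'                  library_hits = c("HMDB", "HMDB", ""))
#' putativeIdFilter(df)$n_pass  # only 'a': 90 is not > 90, 'c' has no hit
#' @export
putativeIdFilter <- function(features, score_threshold = 90,
                             min_libraries = 1L) {
  df <- .annot_frame(features)
  if (!all(c("mzcloud_score", "library_hits") %in% colnames(df)))
    stop("features must carry 'mzcloud_score' and 'library_hits' annotation",
         call. = FALSE)
  score <- as.numeric(df$mzcloud_score)
  hits <- as.character(df$library_hits)
  hits[is.na(hits)] <- ""
  unannot <- is.na(score) & !nzchar(hits)
  n_hits <- vapply(hits, function(h) length(.split_hits(h)), integer(1),
                   USE.NAMES = FALSE)
  pass <- !unannot & !is.na(score) & score > score_threshold &
    n_hits >= min_libraries
  list(passing = df[pass, , drop = FALSE],
       n_pass = sum(pass),
       n_fail = sum(!pass & !unannot),
       n_unannotated = sum(unannot))
}

#' Default lipid-class fragment catalog
#'
#' Diagnostic head-group fragments observed in positive mode: m/z 184.0733
#' (phosphocholine) for PC, lysoPC and SM, and m/z 85.0284 for
#' acylcarnitines.
#'
#' @return data.frame with `class`, `fragment_mz` (Th), `polarity`.
#' @export
defaultFragmentCatalog <- function() {
  data.frame(class = c("PC", "lysoPC", "SM", "carnitine"),
             fragment_mz = c(184.0733, 184.0733, 184.0733, 85.0284),
             polarity = "+")
}

#' Flag lipid parent ions by fragment retention time
#'
#' High-resolution full-scan processing does not link MS2 fragments to their
#' precursors at scale; this does it by retention time: every feature whose
#' m/z lies within `mz_tol` of a catalog fragment marks a lipid elution
#' point, and all heavier features (`mz` greater than the fragment
#' feature's) within `rt_tol` minutes of it are emitted as candidate parent
#' ions.  All (fragment, parent) pairs are reported — never a silent
#' best-only choice — ordered by fragment, then |rt delta|, then descending
#' mean intensity.
#'
#' @param features a [MetaboExperiment-class] or data.frame with
#'   `feature_id`, `mz`, `rt` and optionally `mean_intensity`.
#' @param catalog fragment catalog (see [defaultFragmentCatalog()]).
#' @param rt_tol retention-time window, minutes.
#' @param mz_tol m/z window for recognizing the fragment, Th.
#' @return data.frame with `fragment_id`, `parent_id`, `rt_delta` (minutes,
#'   parent minus fragment), `class`, `parent_mz`, `parent_mean_intensity`.
#' @export
flagLipidParents <- function(features, catalog = defaultFragmentCatalog(),
                             rt_tol = 0.05, mz_tol = 0.01) {
  df <- .annot_frame(features)
  stopifnot(all(c("feature_id", "mz", "rt") %in% colnames(df)))
  if (!"mean_intensity" %in% colnames(df)) df$mean_intensity <- NA_real_
  out <- list()
  if (nrow(catalog) == 0L || nrow(df) == 0L)
    return(data.frame(fragment_id = character(), parent_id = character(),
                      rt_delta = numeric(), class = character(),
                      parent_mz = numeric(),
                      parent_mean_intensity = numeric()))
  for (ci in seq_len(nrow(catalog))) {
    frag_rows <- which(abs(df$mz - catalog$fragment_mz[ci]) <= mz_tol)
    for (fi in frag_rows) {
      parents <- which(abs(df$rt - df$rt[fi]) <= rt_tol & df$mz > df$mz[fi])
      if (!length(parents)) next
      out[[length(out) + 1L]] <- data.frame(
        fragment_id = df$feature_id[fi],
        parent_id = df$feature_id[parents],
        rt_delta = df$rt[parents] - df$rt[fi],
        class = catalog$class[ci],
        parent_mz = df$mz[parents],
        parent_mean_intensity = df$mean_intensity[parents])
    }
  }
  if (!length(out))
    return(data.frame(fragment_id = character(), parent_id = character(),
                      rt_delta = numeric(), class = character(),
                      parent_mz = numeric(),
                      parent_mean_intensity = numeric()))
  res <- do.call(rbind, out)
  ord <- order(res$class, res$fragment_id, abs(res$rt_delta),
               -ifelse(is.na(res$parent_mean_intensity), -Inf,
                       res$parent_mean_intensity),
               res$parent_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cross-check targeted detections against the high-resolution dataset
#'
#' A triple-quadrupole detection is `confirmed` when a high-resolution
#' feature lies within `mass_tol` of the target's protonated monoisotopic
#' mass; `wide_only` when a feature exists only within the wide `wide_tol`
#' window (±0.5 Da by default) — the signature of a probable targeted false
#' positive, where a nominal-mass neighbour mimics the MRM transition; and
#' `absent` otherwise.
#'
#' @param targets a [TargetPanel-class] with `monoisotopic_mass`.
#' @param features a [MetaboExperiment-class] or data.frame with `mz`.
#' @param mass_tol narrow window, Da.
#' @param wide_tol wide window, Da.
#' @param proton_mass proton mass added for the assumed [M+H]+ ion.
#' @return data.frame with `name`, `protonated_mz`, `status`,
#'   `nearest_delta` (Da; NA when no features).
#' @export
qqqCrossCheck <- function(targets, features, mass_tol = 0.005,
                          wide_tol = 0.5, proton_mass = .PROTON_MASS) {
  df <- .annot_frame(features)
  mz <- if (nrow(df)) df$mz else numeric()
  use <- !is.na(targets$monoisotopic_mass)
  nm <- targets$name[use]
  pmz <- targets$monoisotopic_mass[use] + proton_mass
  status <- character(length(nm)); nearest <- rep(NA_real_, length(nm))
  for (i in seq_along(nm)) {
    if (!length(mz)) { status[i] <- "absent"; next }
    d <- abs(mz - pmz[i])
    nearest[i] <- min(d)
    status[i] <- if (nearest[i] <= mass_tol) "confirmed"
      else if (nearest[i] <= wide_tol) "wide_only"
      else "absent"
  }
  data.frame(name = nm, protonated_mz = pmz, status = status,
             nearest_delta = nearest)
}
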