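## Isotopic (M+2) deconvolution of flow-injection lipid MRM data.
##
## Without chromatography all species of a class ionize together, so the
## two-13C isotopologue of a lipid lands exactly on the monoisotopic mass of
## the same-class species with one fewer double bond (+2 Da).  Observed areas
## are therefore a lower-triangular mixture of the true areas, inverted here
## by forward substitution.

.C13_ABUNDANCE <- 0.0107

## Isotope-model backbone carbons added to the fatty-acid count of the name.
.BACKBONE_CARBONS <- c(PC = 8L, lysoPC = 8L, SM = 5L, carnitine = 7L)
.DEFAULT_SPHINGOID <- 18L

#' Parse a lipid species name
#'
#' Grammar of the class/C:DB nomenclature: `PCaaC34:0` / `PCaeC36:4`
#' (diacyl / acyl-alkyl phosphatidylcholine), `lysoPCaC20:2` /
#' `lysoPCeC18:0`, `SM(d18:0/C18:1)` (explicit sphingoid base d-chain and
#' fatty acid; a space before the parenthesis is tolerated), shorthand
#' `SMC16:0`, and acylcarnitines `C2:0` or `C0`.  The grammar does not
#' locate double bonds nor split carbons over side chains.
#'
#' @param name species name.
#' @return A [LipidSpecies-class]; `formatLipidSpecies(parseLipidSpecies(x))`
#'   is the canonical spelling of `x`.
#' @examples
#' parseLipidSpecies("PCaaC34:0")
#' parseLipidSpecies("SM (d18:0/C18:1)")
#' @export
parseLipidSpecies <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  x <- trimws(name)
  mk <- function(class, carbons, db, sph_c = NA_integer_, sph_db = NA_integer_,
                 bond = NA_character_)
    new("LipidSpecies", name = x, lipidClass = class,
        carbons = as.integer(carbons), doubleBonds = as.integer(db),
        sphingoidCarbons = as.integer(sph_c),
        sphingoidDoubleBonds = as.integer(sph_db),
        bondCode = bond)
  m <- regmatches(x, regexec("^PC(aa|ae)C([0-9]+):([0-9]+)$", x))[[1]]
  if (length(m)) return(mk("PC", m[3], m[4], bond = m[2]))
  m <- regmatches(x, regexec("^lysoPC(a|e)C([0-9]+):([0-9]+)$", x))[[1]]
  if (length(m)) return(mk("lysoPC", m[3], m[4], bond = m[2]))
  m <- regmatches(x,
    regexec("^SM ?\\(d([0-9]+):([0-9]+)/C([0-9]+):([0-9]+)\\)$", x))[[1]]
  if (length(m))
    return(mk("SM", as.integer(m[4]) + as.integer(m[2]),
              as.integer(m[5]) + as.integer(m[3]),
              sph_c = m[2], sph_db = m[3], bond = "d"))
  m <- regmatches(x, regexec("^SMC([0-9]+):([0-9]+)$", x))[[1]]
  if (length(m)) return(mk("SM", m[2], m[3], bond = "d"))
  m <- regmatches(x, regexec("^C([0-9]+)(:([0-9]+))?$", x))[[1]]
  if (length(m)) {
    db <- if (nzchar(m[4])) m[4] else 0L
    return(mk("carnitine", m[2], db))
  }
  stop("cannot parse lipid species name: '", name, "'", call. = FALSE)
}

#' @describeIn parseLipidSpecies canonical name of a parsed species.
#' @param species a [LipidSpecies-class].
#' @export
formatLipidSpecies <- function(species) {
  stopifnot(is(species, "LipidSpecies"))
  switch(species@lipidClass,
    PC = sprintf("PC%sC%d:%d", species@bondCode, species@carbons,
                 species@doubleBonds),
    lysoPC = sprintf("lysoPC%sC%d:%d", species@bondCode, species@carbons,
                     species@doubleBonds),
    SM = if (!is.na(species@sphingoidCarbons))
      sprintf("SM(d%d:%d/C%d:%d)", species@sphingoidCarbons,
              species@sphingoidDoubleBonds,
              species@carbons - species@sphingoidCarbons,
              species@doubleBonds - species@sphingoidDoubleBonds)
    else sprintf("SMC%d:%d", species@carbons, species@doubleBonds),
    carnitine = sprintf("C%d:%d", species@carbons, species@doubleBonds))
}

#' Carbon count used for the isotope model
#'
#' The nomenclature only counts fatty-acid (and, for SMs with explicit
#' sphingoid base, chain) carbons; the isotope envelope needs the whole
#' molecule.  A per-class backbone count is added: 8 for PC and lysoPC
#' (glycerol + choline headgroup), 5 for SM (headgroup beyond the chains;
#' shorthand SMs additionally assume an 18-carbon sphingoid base) and 7 for
#' carnitines.  The lookup is exposed so users can override it.
#'
#' @param species a [LipidSpecies-class].
#' @param backbone named integer vector of per-class backbone carbons.
#' @param default_sphingoid sphingoid carbons assumed for shorthand SM names.
#' @return integer carbon count.
#' @export
totalCarbons <- function(species, backbone = .BACKBONE_CARBONS,
                         default_sphingoid = .DEFAULT_SPHINGOID) {
  stopifnot(is(species, "LipidSpecies"))
  n <- species@carbons + backbone[[species@lipidClass]]
  if (species@lipidClass == "SM" && is.na(species@sphingoidCarbons))
    n <- n + default_sphingoid
  as.integer(n)
}

#' Carbon isotope envelope of a species
#'
#' Binomial model over the carbon count with natural 13C abundance
#' p = 0.0107: \eqn{a_k = \binom{n}{k} p^k (1-p)^{n-k}}, truncated to
#' `n_peaks` isotopologues and renormalized to sum 1.  Heavier-element
#' isotopes are ignored: the +2 Da interference of lipids is dominated by
#' the two-13C species.
#'
#' @param n_carbons carbon count (>= 1; 0 allowed as degenerate case).
#' @param n_peaks number of isotopologue abundances returned (>= 3).
#' @param p per-carbon 13C probability.
#' @return numeric vector `a0, a1, ...` summing to 1.
#' @examples
#' isotopeEnvelope(1)   # c(0.9893, 0.0107, 0)
#' @export
isotopeEnvelope <- function(n_carbons, n_peaks = 3L, p = .C13_ABUNDANCE) {
  stopifnot(n_carbons >= 0, n_peaks >= 3L)
  k <- 0:(n_peaks - 1L)
  a <- choose(n_carbons, k) * p^k * (1 - p)^(n_carbons - k)
  a[k > n_carbons] <- 0
  a <- a / sum(a)
  names(a) <- paste0("a", k)
  a
}

#' Isotope-overlap matrix of a same-class lipid series
#'
#' For species of one class and carbon number, sorted by descending double
#' bonds (ascending mass), builds the lower-triangular mixing matrix M with
#' `M[i, i] = a0` of species i and `M[j, i] = a2` of species i where species
#' j lies exactly +2 Da above species i (one fewer double bond).  Observed
#' areas satisfy `observed = M %*% truth`.
#'
#' @param series list of [LipidSpecies-class] (or character names, parsed on
#'   the fly), all of one class and carbon number; any order — the canonical
#'   descending-double-bond order is established internally.
#' @param envelopes optional list of isotope envelopes aligned with the
#'   sorted series; computed via [totalCarbons()] + [isotopeEnvelope()] when
#'   `NULL`.
#' @param backbone passed to [totalCarbons()].
#' @return square numeric matrix with canonical species names as dimnames.
#' @export
overlapMatrix <- function(series, envelopes = NULL,
                          backbone = .BACKBONE_CARBONS) {
  if (is.character(series)) series <- lapply(series, parseLipidSpecies)
  stopifnot(length(series) >= 1L)
  cls <- vapply(series, function(s) s@lipidClass, character(1))
  carb <- vapply(series, function(s) s@carbons, integer(1))
  db <- vapply(series, function(s) s@doubleBonds, integer(1))
  if (length(unique(cls)) != 1L || length(unique(carb)) != 1L)
    stop("all species in a series must share class and carbon number",
         call. = FALSE)
  if (anyDuplicated(db))
    stop("duplicate species in series (double bonds ",
         paste(db[duplicated(db)], collapse = ", "), ")", call. = FALSE)
  ord <- order(db, decreasing = TRUE)  # ascending mass
  series <- series[ord]; db <- db[ord]
  n <- length(series)
  if (is.null(envelopes))
    envelopes <- lapply(series, function(s)
      isotopeEnvelope(totalCarbons(s, backbone)))
  else if (!is.null(ord)) envelopes <- envelopes
  M <- matrix(0, n, n)
  nm <- vapply(series, formatLipidSpecies, character(1))
  dimnames(M) <- list(nm, nm)
  for (i in seq_len(n)) {
    M[i, i] <- envelopes[[i]][["a0"]]
    j <- which(db == db[i] - 1L)  # +2 Da neighbour
    if (length(j)) M[j, i] <- envelopes[[i]][["a2"]]
  }
  M
}

#' Deconvolve observed areas through an overlap matrix
#'
#' Solves `M %*% x = observed` by forward substitution (M is
#' lower-triangular with positive diagonal).  Noise can drive small species
#' negative after subtraction of a large neighbour's isotope contribution;
#' negative solutions are clipped to 0 and flagged via the `"clipped"`
#' attribute (and a warning), because downstream RSD computations need
#' values rather than holes.
#'
#' @param observed numeric vector of observed areas, aligned with `M`.
#' @param M overlap matrix from [overlapMatrix()].
#' @return corrected areas (named as `M`), with logical attribute
#'   `"clipped"`.
#' @export
deconvolveAreas <- function(observed, M) {
  stopifnot(length(observed) == nrow(M), nrow(M) == ncol(M))
  if (any(diag(M) <= 0))
    stop("singular overlap matrix: zero diagonal", call. = FALSE)
  x <- forwardsolve(M, observed)
  clipped <- x < 0
  if (any(clipped)) {
    warning("deconvolution clipped ", sum(clipped),
            " negative area(s) to zero: ",
            paste(rownames(M)[clipped], collapse = ", "), call. = FALSE)
    x[clipped] <- 0
  }
  names(x) <- rownames(M)
  attr(x, "clipped") <- clipped
  x
}

#' Deconvolve a full peak-area matrix
#'
#' Groups the lipid columns of a samples-by-analytes area matrix into
#' same-class, same-carbon series, builds each series' overlap matrix and
#' corrects every sample.  Columns that do not parse as lipid species, and
#' samples with missing values inside a series, are passed through
#' unchanged.
#'
#' @param areas samples-by-analytes numeric matrix.
#' @param backbone passed to [totalCarbons()].
#' @return corrected matrix of identical shape; attribute `"clipped"` is a
#'   logical matrix marking clipped cells.
#' @export
deconvolveLipids <- function(areas, backbone = .BACKBONE_CARBONS) {
  out <- areas
  clipped <- matrix(FALSE, nrow(areas), ncol(areas), dimnames = dimnames(areas))
  parsed <- lapply(colnames(areas), function(nm)
    tryCatch(parseLipidSpecies(nm), error = function(e) NULL))
  is_lipid <- !vapply(parsed, is.null, logical(1))
  if (!any(is_lipid)) return(out)
  key <- rep(NA_character_, ncol(areas))
  key[is_lipid] <- vapply(parsed[is_lipid], function(s)
    paste(s@lipidClass, s@carbons, sep = ":"), character(1))
  for (k in unique(stats::na.omit(key))) {
    cols <- which(!is.na(key) & key == k)
    series <- parsed[cols]
    db <- vapply(series, function(s) s@doubleBonds, integer(1))
    ord <- order(db, decreasing = TRUE)
    cols <- cols[ord]
    M <- overlapMatrix(series[ord], backbone = backbone)
    for (s in seq_len(nrow(areas))) {
      obs <- areas[s, cols]
      if (anyNA(obs)) next
      corr <- withCallingHandlers(deconvolveAreas(unname(obs), M),
                                  warning = function(w)
                                    invokeRestart("muffleWarning"))
      out[s, cols] <- as.numeric(corr)
      clipped[s, cols] <- attr(corr, "clipped")
    }
  }
  attr(out, "clipped") <- clipped
  out
}
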