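#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @import methods
NULL

#' ReflectanceSet: labelled reflectance spectra
#'
#' A container for reflectance spectra, extending
#' \linkS4class{SummarizedExperiment}. The single assay, \code{"reflectance"},
#' is a wavelengths-by-measurements matrix of reflectance proportions in
#' \code{[0, 1]} (values slightly above 1 are tolerated for glossy patches).
#' Row metadata holds the wavelength grid (nm); column metadata carries the
#' measurement labels \code{species}, \code{sex} (\code{"M"}/\code{"F"}),
#' \code{patch}, \code{specimen} and \code{replicate} (\code{NA} once
#' replicates have been averaged).
#'
#' @seealso [readSpectra()], [resampleSpectra()], [averageReplicates()]
#' @export
setClass("ReflectanceSet", contains = "SummarizedExperiment")

.PATCHES <- c("belly", "breast", "throat", "crown", "mantle")
.SEXES <- c("M", "F")

setValidity("ReflectanceSet", function(object) {
  msg <- character()
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'reflectance' is required")
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (is.null(wl)) {
    msg <- c(msg, "rowData column 'wavelength_nm' is required")
  } else {
    if (any(!is.finite(wl)) || any(diff(wl) <= 0))
      msg <- c(msg, "wavelengths must be finite and strictly increasing")
  }
  if (length(msg) == 0L) {
    r <- SummarizedExperiment::assay(object, "reflectance")
    if (any(!is.finite(r))) msg <- c(msg, "reflectance values must be finite")
    else if (any(r < 0)) msg <- c(msg, "reflectance values must be >= 0")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("species", "sex", "patch", "specimen", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if ("sex" %in% colnames(cd) && !all(cd$sex %in% .SEXES))
    msg <- c(msg, "sex must be 'M' or 'F'")
  if (length(msg)) msg else TRUE
})

#' VisualSystem: receptors, noise and illuminant for the RNL model
#'
#' Bundles everything the receptor-noise-limited (RNL) colour-vision model
#' needs: spectral sensitivities of the chromatic single cones (columns of
#' \code{sensitivities}, each normalised to peak 1), their relative
#' abundances, the Weber fraction of the reference (most abundant) cone, the
#' achromatic (double-cone) sensitivity with its own Weber fraction, and the
#' illuminant spectrum. All spectral slots share the wavelength grid in
#' \code{wavelengths}.
#'
#' @slot wavelengths numeric wavelength grid (nm), strictly increasing.
#' @slot sensitivities matrix (wavelengths x receptors) of chromatic cone
#'   sensitivities, peak-normalised, with receptor names as colnames.
#' @slot abundances named numeric, relative cone abundances (> 0).
#' @slot weberReference name of the receptor whose Weber fraction is given.
#' @slot weberFraction Weber fraction of the reference receptor (> 0).
#' @slot achromaticSensitivity numeric, double-cone sensitivity, peak 1.
#' @slot achromaticWeber Weber fraction of the achromatic channel (> 0).
#' @slot illuminant numeric, illuminant spectrum (irradiance, arbitrary units).
#'
#' @seealso [visualSystem()], [blackbirdVisualSystem()], [receptorNoise()]
#' @export
setClass("VisualSystem",
  representation(
    wavelengths = "numeric",
    sensitivities = "matrix",
    abundances = "numeric",
    weberReference = "character",
    weberFraction = "numeric",
    achromaticSensitivity = "numeric",
    achromaticWeber = "numeric",
    illuminant = "numeric"
  )
)

setValidity("VisualSystem", function(object) {
  msg <- character()
  wl <- object@wavelengths
  if (length(wl) < 2L || any(!is.finite(wl)) || any(diff(wl) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing and finite")
  S <- object@sensitivities
  if (nrow(S) != length(wl))
    msg <- c(msg, "sensitivities rows must match wavelengths")
  if (ncol(S) < 2L)
    msg <- c(msg, "at least two chromatic receptors are required")
  if (is.null(colnames(S)) || anyDuplicated(colnames(S)))
    msg <- c(msg, "sensitivities must have unique receptor colnames")
  if (any(S < 0)) msg <- c(msg, "sensitivities must be non-negative")
  eta <- object@abundances
  if (!identical(sort(names(eta)), sort(colnames(S))))
    msg <- c(msg, "abundances must be named by the receptors")
  if (any(eta <= 0)) msg <- c(msg, "abundances must be strictly positive")
  if (!object@weberReference %in% colnames(S))
    msg <- c(msg, "weberReference must name an existing receptor")
  if (object@weberFraction <= 0) msg <- c(msg, "weberFraction must be > 0")
  if (object@achromaticWeber <= 0) msg <- c(msg, "achromaticWeber must be > 0")
  if (length(object@achromaticSensitivity) != length(wl))
    msg <- c(msg, "achromaticSensitivity length must match wavelengths")
  if (length(object@illuminant) != length(wl))
    msg <- c(msg, "illuminant length must match wavelengths")
  if (any(object@illuminant < 0) || any(object@achromaticSensitivity < 0))
    msg <- c(msg, "illuminant and achromatic sensitivity must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RangeGrid: presence-absence grid of breeding ranges
#'
#' A sites-by-species binary occupancy matrix with per-cell coordinates and
#' areas, the letsR-style representation used for range overlap, range size
#' and sympatric-count calculations.
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{lon}, \code{lat},
#'   \code{area_km2}.
#' @slot occupancy integer matrix (cells x species) with entries in
#'   \{0, 1\}; species ids as colnames. Every species occupies >= 1 cell.
#'
#' @seealso [rangeGrid()], [overlapPercent()], [sympatricCount()], [rangeSize()]
#' @export
setClass("RangeGrid",
  representation(cells = "data.frame", occupancy = "matrix")
)

setValidity("RangeGrid", function(object) {
  msg <- character()
  need <- c("cell_id", "lon", "lat", "area_km2")
  miss <- setdiff(need, colnames(object@cells))
  if (length(miss))
    msg <- c(msg, paste("cells is missing columns:", paste(miss, collapse = ", ")))
  occ <- object@occupancy
  if (nrow(occ) != nrow(object@cells))
    msg <- c(msg, "occupancy rows must match cells")
  if (is.null(colnames(occ)) || anyDuplicated(colnames(occ)))
    msg <- c(msg, "occupancy must have unique species colnames")
  if (!all(occ %in% c(0, 1))) msg <- c(msg, "occupancy entries must be 0/1")
  else if (any(colSums(occ) == 0))
    msg <- c(msg, "every species must occupy at least one cell")
  if ("area_km2" %in% colnames(object@cells) &&
      any(object@cells$area_km2 <= 0))
    msg <- c(msg, "cell areas must be > 0")
  if (length(msg)) msg else TRUE
})

#' PosteriorFit: MCMC draws and diagnostics for a fitted model
#'
#' Holds post-warmup draws from the Bayesian phylogenetic binomial
#' regression, arranged as a draws-by-parameter matrix with a chain index,
#' together with convergence diagnostics and the data the model was fit to.
#'
#' @slot draws numeric matrix (total post-warmup draws x parameters);
#'   columns \code{alpha}, coefficient names, \code{sigma_phylo} (if
#'   sampled) and \code{u.<species>} species effects.
#' @slot chain integer vector mapping each draw to its chain.
#' @slot rhat named numeric, split-Rhat per parameter.
#' @slot ess named numeric, effective sample size per parameter.
#' @slot model list: response counts \code{k}, \code{trials}, design matrix
#'   \code{X}, correlation \code{C}, model label, sampler settings, seed.
#' @slot converged logical, TRUE when max Rhat <= 1.01.
#'
#' @seealso [fitDichromatismModel()], [summarizePosterior()], [oddsRatios()]
#' @export
setClass("PosteriorFit",
  representation(
    draws = "matrix",
    chain = "integer",
    rhat = "numeric",
    ess = "numeric",
    model = "list",
    converged = "logical"
  )
)

setValidity("PosteriorFit", function(object) {
  msg <- character()
  if (length(object@chain) != nrow(object@draws))
    msg <- c(msg, "chain index must have one entry per draw")
  if (is.null(colnames(object@draws)))
    msg <- c(msg, "draws must have parameter colnames")
  if (length(msg)) msg else TRUE
})

#' @describeIn VisualSystem-class compact display
#' @param object a \code{VisualSystem}
#' @export
setMethod("show", "VisualSystem", function(object) {
  cat("VisualSystem:", ncol(object@sensitivities), "chromatic receptors (",
      paste(colnames(object@sensitivities), collapse = ", "),
      ") + achromatic channel\n")
  cat("  wavelengths:", min(object@wavelengths), "-", max(object@wavelengths),
      "nm (", length(object@wavelengths), "points )\n")
  cat("  Weber fraction", object@weberFraction, "on", object@weberReference,
      "; achromatic Weber", object@achromaticWeber, "\n")
})

#' @describeIn RangeGrid-class compact display
#' @param object a \code{RangeGrid}
#' @export
setMethod("show", "RangeGrid", function(object) {
  cat("RangeGrid:", nrow(object@occupancy), "cells x",
      ncol(object@occupancy), "species\n")
  cat("  total area:", sum(object@cells$area_km2), "km^2\n")
})

#' @describeIn PosteriorFit-class compact display
#' @param object a \code{PosteriorFit}
#' @export
setMethod("show", "PosteriorFit", function(object) {
  cat("PosteriorFit:", object@model$label, "model,",
      nrow(object@draws), "draws x", ncol(object@draws), "parameters,",
      length(unique(object@chain)), "chains\n")
  cat("  max Rhat:", round(max(object@rhat), 4),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
})
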