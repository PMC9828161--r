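#' A1 visual-pigment absorbance template
#'
#' Evaluates the standard rhodopsin (A1) absorbance template on a wavelength
#' grid: a log-normal-shaped alpha band parameterised only by the pigment's
#' peak absorbance wavelength, plus an optional ultraviolet beta band. The
#' curve is normalised to peak 1 on the grid. This is the template commonly
#' used to reconstruct avian cone sensitivities from published lambda-max
#' values when full sensitivity curves are not available.
#'
#' @param lambdaMax peak absorbance wavelength (nm), within \code{[300, 700]}.
#' @param grid wavelength grid (nm); default 300-700 at 1 nm.
#' @param beta include the beta band (default TRUE).
#' @return numeric vector of sensitivities on \code{grid}, peak 1.
#' @export
pigmentTemplate <- function(lambdaMax, grid = 300:700, beta = TRUE) {
  .assertScalarNumber(lambdaMax, "lambdaMax")
  if (lambdaMax < 300 || lambdaMax > 700)
    stop("lambdaMax must lie in [300, 700] nm", call. = FALSE)
  grid <- as.numeric(grid)
  if (lambdaMax < min(grid) || lambdaMax > max(grid))
    stop("lambdaMax outside the wavelength grid span", call. = FALSE)
  x <- lambdaMax / grid
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  s <- alpha
  if (beta) {
    lmb <- 189 + 0.315 * lambdaMax
    b <- -40.5 + 0.195 * lambdaMax
    s <- s + 0.26 * exp(-((grid - lmb) / b)^2)
  }
  s / max(s)
}

#' Construct a VisualSystem
#'
#' @param sensitivities matrix (wavelengths x receptors) of chromatic cone
#'   sensitivities with receptor colnames; each column is peak-normalised.
#' @param wavelengths the shared wavelength grid (nm).
#' @param abundances named numeric of relative cone abundances.
#' @param weberFraction Weber fraction of the reference receptor.
#' @param weberReference name of the reference receptor; default the most
#'   abundant one.
#' @param achromaticSensitivity double-cone sensitivity (peak-normalised);
#' @param achromaticWeber Weber fraction of the achromatic channel.
#' @param illuminant illuminant spectrum; default ideal (flat).
#' @return a \linkS4class{VisualSystem}
#' @export
visualSystem <- function(sensitivities, wavelengths, abundances,
                         weberFraction = 0.1,
                         weberReference = names(which.max(abundances)),
                         achromaticSensitivity,
                         achromaticWeber = 0.1,
                         illuminant = rep(1, length(wavelengths))) {
  sensitivities <- as.matrix(sensitivities)
  peak <- apply(sensitivities, 2L, max)
  if (any(peak <= 0)) stop("each sensitivity must have a positive peak")
  sensitivities <- sweep(sensitivities, 2L, peak, "/")
  achromaticSensitivity <- achromaticSensitivity / max(achromaticSensitivity)
  new("VisualSystem",
      wavelengths = as.numeric(wavelengths),
      sensitivities = sensitivities,
      abundances = abundances[colnames(sensitivities)],
      weberReference = weberReference,
      weberFraction = weberFraction,
      achromaticSensitivity = as.numeric(achromaticSensitivity),
      achromaticWeber = achromaticWeber,
      illuminant = as.numeric(illuminant))
}

#' Build a VisualSystem from a YAML configuration
#'
#' The config lists, per chromatic receptor, a name, a template
#' \code{lambda_max} (nm) and a relative abundance, plus the achromatic
#' (double-cone) \code{lambda_max}, Weber fractions and the illuminant
#' (\code{"ideal"} for flat, or a numeric vector matching the grid).
#'
#' @param path YAML file path; see
#'   \code{system.file("extdata", "blackbird_visual_system.yaml",
#'   package = "dichromatR")} for the packaged example.
#' @param grid wavelength grid (nm) on which to evaluate templates.
#' @return a \linkS4class{VisualSystem}
#' @export
readVisualSystem <- function(path, grid = 300:700) {
  cfg <- yaml::read_yaml(path)
  grid <- as.numeric(grid)
  recs <- cfg$receptors
  S <- vapply(recs, function(r) pigmentTemplate(r$lambda_max, grid),
              numeric(length(grid)))
  colnames(S) <- vapply(recs, `[[`, character(1L), "name")
  eta <- setNames(vapply(recs, `[[`, numeric(1L), "abundance"), colnames(S))
  ach <- pigmentTemplate(cfg$achromatic$lambda_max, grid)
  ill <- cfg$illuminant
  if (is.character(ill) && identical(ill, "ideal")) {
    ill <- rep(1, length(grid))
  } else {
    ill <- as.numeric(ill)
    if (length(ill) != length(grid))
      stop("numeric illuminant must match the wavelength grid", call. = FALSE)
  }
  visualSystem(S, grid, eta,
               weberFraction = cfg$weber_fraction,
               weberReference = cfg$weber_reference,
               achromaticSensitivity = ach,
               achromaticWeber = cfg$achromatic$weber,
               illuminant = ill)
}

#' Default visual system: European Blackbird (Turdus merula)
#'
#' Loads the packaged configuration for the blackbird's violet-sensitive
#' tetrachromatic visual system (four single cones UVS/SWS/MWS/LWS plus the
#' double-cone achromatic channel), reconstructed from published lambda-max
#' and cone-abundance measurements via the A1 pigment template, with a flat
#' illuminant and 0.1 Weber fractions. See the packaged YAML for the numeric
#' values and their provenance.
#'
#' @param grid wavelength grid (nm); default 300-700 at 1 nm.
#' @return a \linkS4class{VisualSystem}
#' @export
blackbirdVisualSystem <- function(grid = 300:700) {
  readVisualSystem(
    system.file("extdata", "blackbird_visual_system.yaml",
                package = "dichromatR", mustWork = TRUE),
    grid = grid)
}

#' Receptor noise of the chromatic channels
#'
#' Noise-limited channel standard deviations under the relative-abundance
#' scaling of the RNL model:
#' \deqn{e_i = \nu \sqrt{\eta_{ref} / \eta_i}}
#' where \eqn{\nu} is the Weber fraction of the reference receptor and
#' \eqn{\eta} the relative cone abundances.
#'
#' @param vs a \linkS4class{VisualSystem}
#' @return named numeric vector of per-receptor noise values \eqn{e_i}
#' @export
receptorNoise <- function(vs) {
  stopifnot(is(vs, "VisualSystem"))
  eta <- vs@abundances
  vs@weberFraction * sqrt(eta[[vs@weberReference]] / eta)
}
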