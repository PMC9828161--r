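#' Quantum catches of a set of spectra
#'
#' Photoreceptor quantum catches under the receptor-noise-limited model:
#' \deqn{Q_i = \int R(\lambda) S_i(\lambda) I(\lambda)\, d\lambda}
#' integrated by the trapezoidal rule over the shared wavelength grid, for
#' each chromatic receptor and for the achromatic (double-cone) channel
#' (column \code{lum}).
#'
#' @param x a \linkS4class{ReflectanceSet}, already resampled to the visual
#'   system's grid (see [resampleSpectra()]).
#' @param vs a \linkS4class{VisualSystem}.
#' @return numeric matrix (measurements x receptors + \code{lum}); row order
#'   follows the columns of \code{x}.
#' @export
quantumCatches <- function(x, vs) {
  stopifnot(is(x, "ReflectanceSet"), is(vs, "VisualSystem"))
  wl <- wavelengths(x)
  if (length(wl) != length(vs@wavelengths) ||
      any(abs(wl - vs@wavelengths) > 1e-9))
    stop("spectra and visual system are on different wavelength grids; ",
         "resample the spectra first", call. = FALSE)
  w <- trapezoidWeights(wl)
  kernel <- cbind(vs@sensitivities, lum = vs@achromaticSensitivity) *
    (vs@illuminant * w)
  q <- t(reflectance(x)) %*% kernel
  if (any(!is.finite(q)) || any(q <= 0))
    stop("non-positive or non-finite quantum catch; check input spectra",
         call. = FALSE)
  rownames(q) <- colnames(x)
  q
}

## general-n RNL chromatic distance on log-signal differences.
## df: vector (or matrix with one row per comparison) of delta-f values;
## e: per-receptor noise. Weights: for each receptor pair (i, j) the product
## of the squared noises of all OTHER receptors; denominator the sum over
## receptors of the product of all other squared noises.
.deltaS <- function(df, e) {
  if (is.null(dim(df))) df <- matrix(df, nrow = 1L)
  n <- length(e)
  if (ncol(df) != n) stop("receptor count mismatch", call. = FALSE)
  e2 <- e^2
  prodAll <- prod(e2)
  ## products of e2 over k != i (and over k not in {i,j}) via division;
  ## numerically safe here since noises are O(0.1)
  omit1 <- prodAll / e2
  denom <- sum(omit1)
  num <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      wij <- prodAll / (e2[i] * e2[j])
      num <- num + wij * (df[, i] - df[, j])^2
    }
  }
  sqrt(num / denom)
}

#' Chromatic contrast (JND) between two stimuli
#'
#' Receptor-noise-limited chromatic distance between two quantum-catch
#' vectors, in just-noticeable differences. Receptor signals are
#' log-transformed (Fechner), \eqn{\Delta f_i = \ln Q_i(A) - \ln Q_i(B)},
#' and combined with the general n-receptor RNL quadratic form, which for
#' two receptors reduces to
#' \eqn{|\Delta f_1 - \Delta f_2| / \sqrt{e_1^2 + e_2^2}} and for four to
#' the standard tetrachromatic formula.
#'
#' @param qa,qb named numeric vectors of chromatic quantum catches (one
#'   element per receptor of \code{vs}), or single rows of
#'   [quantumCatches()] output.
#' @param vs a \linkS4class{VisualSystem}.
#' @return chromatic contrast \eqn{\Delta S} in JND (>= 0).
#' @export
chromaticContrast <- function(qa, qb, vs) {
  rec <- colnames(vs@sensitivities)
  qa <- qa[rec]; qb <- qb[rec]
  if (anyNA(qa) || anyNA(qb))
    stop("catches must be named by the visual system's receptors",
         call. = FALSE)
  if (any(qa <= 0) || any(qb <= 0))
    stop("quantum catches must be strictly positive", call. = FALSE)
  e <- receptorNoise(vs)[rec]
  as.numeric(.deltaS(log(qa) - log(qb), e))
}

#' Achromatic contrast (JND) between two stimuli
#'
#' Luminance contrast through the double-cone channel:
#' \deqn{\Delta L = |\ln(Q_D(A)/Q_D(B))| / e_D}
#'
#' @param qa,qb achromatic quantum catches: either bare positive numbers or
#'   named vectors containing a \code{lum} element (as returned by
#'   [quantumCatches()]).
#' @param vs a \linkS4class{VisualSystem}.
#' @return achromatic contrast \eqn{\Delta L} in JND (>= 0).
#' @export
achromaticContrast <- function(qa, qb, vs) {
  pick <- function(q) if (!is.null(names(q)) && "lum" %in% names(q))
    q[["lum"]] else as.numeric(q)
  qda <- pick(qa); qdb <- pick(qb)
  if (qda <= 0 || qdb <= 0)
    stop("achromatic catches must be strictly positive", call. = FALSE)
  abs(log(qda / qdb)) / vs@achromaticWeber
}

## vectorised pairwise contrasts between two catch matrices (rows paired)
.contrastRows <- function(qA, qB, vs) {
  rec <- colnames(vs@sensitivities)
  e <- receptorNoise(vs)[rec]
  dS <- .deltaS(log(qA[, rec, drop = FALSE]) - log(qB[, rec, drop = FALSE]), e)
  dL <- abs(log(qA[, "lum"] / qB[, "lum"])) / vs@achromaticWeber
  cbind(chromatic = as.numeric(dS), achromatic = as.numeric(dL))
}
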