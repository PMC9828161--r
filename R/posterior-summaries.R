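#' Highest-density interval
#'
#' Narrowest contiguous interval containing the stated posterior mass,
#' by the sorted shortest-window estimator (ties broken toward the lower
#' window).
#'
#' @param draws numeric vector (>= 100 draws).
#' @param mass interval mass in (0, 1); default 0.90.
#' @return named numeric \code{c(lower, upper)}.
#' @export
hdi <- function(draws, mass = 0.90) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  if (length(draws) < 100L) stop("need at least 100 draws", call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  width <- x[seq.int(m + 1L, n)] - x[seq_len(n - m)]
  i <- which.min(width)  # which.min takes the first minimum: lower window
  c(lower = x[i], upper = x[i + m])
}

#' Probability of direction
#'
#' Fraction of posterior draws sharing the sign of the posterior median; an
#' index of the certainty that an effect is strictly positive or negative.
#' If the median is exactly 0, positives are counted.
#'
#' @param draws numeric vector of posterior draws.
#' @return probability in \code{[0, 1]} (in \code{[0.5, 1]} for unimodal
#'   samples).
#' @export
probDirection <- function(draws) {
  if (!length(draws)) stop("empty draws", call. = FALSE)
  m <- median(draws)
  if (m > 0) mean(draws > 0)
  else if (m < 0) mean(draws < 0)
  else mean(draws > 0)
}

#' Phylogenetic signal as a latent-scale ICC
#'
#' Per draw, \eqn{\lambda = \sigma^2 / (\sigma^2 + \pi^2/3)}: the share of
#' latent (logit-scale) variance attributable to the phylogenetic species
#' effect, the residual being the standard-logistic variance
#' \eqn{\pi^2/3}. Reported as the posterior median with a central credible
#' interval.
#'
#' @param sigmaDraws posterior draws of the phylogenetic scale (>= 0).
#' @param prob credible-interval mass; default 0.90.
#' @return named numeric \code{c(median, lower, upper)}.
#' @export
lambdaICC <- function(sigmaDraws, prob = 0.90) {
  if (any(sigmaDraws < 0)) stop("sigma draws must be >= 0", call. = FALSE)
  lam <- sigmaDraws^2 / (sigmaDraws^2 + pi^2 / 3)
  qs <- quantile(lam, c((1 - prob) / 2, 1 - (1 - prob) / 2), names = FALSE)
  c(median = median(lam), lower = qs[1L], upper = qs[2L])
}

#' Odds-ratio summaries of the fixed effects
#'
#' Exponentiates the intercept and coefficient draws and reports, per
#' predictor, the posterior median odds ratio, the HDI on the odds-ratio
#' scale and the probability of direction (computed on the log-odds
#' draws). Dummy coding: no migration and mainland are the reference
#' categories (see [designMatrix()]).
#'
#' @param fit a \linkS4class{PosteriorFit}.
#' @param prob HDI mass; default 0.90.
#' @param pdRule predictors with pd at or above this value are flagged
#'   (default 0.90).
#' @return data.frame with columns \code{parameter}, \code{or},
#'   \code{hdiLower}, \code{hdiUpper}, \code{pd}, \code{reliable}.
#' @export
oddsRatios <- function(fit, prob = 0.90, pdRule = 0.90) {
  pars <- c("alpha", colnames(fit@model$X))
  rows <- lapply(pars, function(pn) {
    b <- fit@draws[, pn]
    h <- hdi(exp(b), mass = prob)
    pd <- probDirection(b)
    data.frame(parameter = if (pn == "alpha") "Intercept" else pn,
               or = median(exp(b)), hdiLower = h[["lower"]],
               hdiUpper = h[["upper"]], pd = pd, reliable = pd >= pdRule)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a posterior fit
#'
#' Odds ratios, probability of direction and phylogenetic signal for a
#' converged fit. Summaries are withheld (an error) when the sampler did
#' not converge, unless \code{force = TRUE}.
#'
#' @param fit a \linkS4class{PosteriorFit}.
#' @param prob interval mass; default 0.90.
#' @param force return summaries despite non-convergence.
#' @return list with elements \code{predictors} (see [oddsRatios()]),
#'   \code{lambda} (see [lambdaICC()], NULL when sigma was fixed),
#'   \code{maxRhat}, \code{minEss}.
#' @export
summarizePosterior <- function(fit, prob = 0.90, force = FALSE) {
  if (!fit@converged && !force)
    stop("fit did not converge (max Rhat = ",
         round(max(fit@rhat), 3), "); use force = TRUE to summarise anyway",
         call. = FALSE)
  lam <- if (fit@model$sampleSigma)
    lambdaICC(fit@draws[, "sigma_phylo"], prob = prob) else NULL
  list(predictors = oddsRatios(fit, prob = prob),
       lambda = lam,
       maxRhat = max(fit@rhat),
       minEss = min(fit@ess))
}
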