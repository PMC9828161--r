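#' Design matrix for a dichromatism model
#'
#' Builds the fixed-effect design for one of the four candidate models of
#' dichromatic-patch counts. Reference categories: no migration, mainland.
#' \describe{
#'   \item{timing}{z-scored breeding season length, partial/full migration
#'     dummies, and their interactions.}
#'   \item{spacing}{natural-log breeding range size (km^2) and an island
#'     dummy.}
#'   \item{sympatry}{number of sympatric congeners.}
#'   \item{null}{intercept only (zero columns).}
#' }
#'
#' @param traits a predictor table from [buildTraitTable()].
#' @param model one of \code{"timing"}, \code{"spacing"}, \code{"sympatry"},
#'   \code{"null"}.
#' @return numeric matrix with species rownames (possibly zero columns).
#' @export
designMatrix <- function(traits,
                         model = c("timing", "spacing", "sympatry", "null")) {
  model <- match.arg(model)
  if (anyNA(traits)) stop("predictor table contains missing values",
                          call. = FALSE)
  X <- switch(model,
    null = matrix(0, nrow(traits), 0L),
    sympatry = cbind(nSympatric = as.numeric(traits$nSympatric)),
    spacing = cbind(logRangeSize = log(traits$rangeSizeKm2),
                    island = as.numeric(traits$landmass == "island")),
    timing = {
      z <- traits$zBreedingSeason
      mp <- as.numeric(traits$migration == "partial")
      mf <- as.numeric(traits$migration == "full")
      cbind(zSeason = z, migPartial = mp, migFull = mf,
            "zSeason:migPartial" = z * mp, "zSeason:migFull" = z * mf)
    })
  rownames(X) <- traits$species
  X
}

#' Log-posterior of the phylogenetic binomial model
#'
#' Unnormalised log-posterior of the Bayesian phylogenetic binomial
#' logistic regression in its centred parameterisation:
#' binomial likelihood with
#' \eqn{p_s = \mathrm{logit}^{-1}(\alpha + x_s^\top\beta + u_s)}, a
#' \eqn{MVN(0, \sigma^2 C)} density for the species effects \eqn{u},
#' Student-t(3, 0, 10) priors on the intercept and (half-t) on
#' \eqn{\sigma}, and flat (constant) priors on the coefficients.
#' The binomial coefficient is included so that values are comparable
#' across implementations.
#'
#' @param k integer vector of dichromatic-patch counts.
#' @param X design matrix (n x p, possibly p = 0).
#' @param C phylogenetic correlation matrix (n x n), or NULL for identity.
#' @param alpha intercept.
#' @param beta coefficient vector (length p).
#' @param sigma phylogenetic effect scale (>= 0).
#' @param u species effects (length n). With \code{sigma = 0}, all
#'   \code{u} must be 0 and the MVN term is dropped (ordinary logistic
#'   regression).
#' @param trials binomial trials per species (default 5 patches).
#' @param priorDf,priorScale Student-t prior degrees of freedom and scale.
#' @return log-posterior value (finite unless the parameters are outside
#'   the support).
#' @export
logPosterior <- function(k, X, C = NULL, alpha, beta = numeric(0), sigma, u,
                         trials = 5, priorDf = 3, priorScale = 10) {
  n <- length(k)
  if (sigma < 0) return(-Inf)
  eta <- as.numeric(alpha + (if (ncol(X)) X %*% beta else 0) + u)
  ll <- sum(dbinom(k, trials, invlogit(eta), log = TRUE))
  lpU <- if (sigma == 0) {
    if (any(u != 0)) -Inf else 0
  } else {
    Cm <- if (is.null(C)) diag(n) else C
    ch <- chol(Cm)
    q <- backsolve(ch, u, transpose = TRUE)
    -0.5 * (n * log(2 * pi) + 2 * n * log(sigma) +
            2 * sum(log(diag(ch))) + sum(q^2) / sigma^2)
  }
  lpAlpha <- dstudent(alpha, priorDf, priorScale)
  lpSigma <- dstudent(sigma, priorDf, priorScale) + log(2)  # half-t
  ll + lpU + lpAlpha + lpSigma
}
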