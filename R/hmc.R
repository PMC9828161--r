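## Hamiltonian Monte Carlo for the phylogenetic binomial model.
## Non-centred parameterisation: theta = (alpha, beta, tau = log sigma, z)
## with u = sigma * L z, L the lower Cholesky factor of the correlation C.

log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

## target factory: returns function(theta) -> list(lp, grad)
.makeTarget <- function(k, X, L, trials, priorDf = 3, priorScale = 10,
                        sigmaFixed = NULL) {
  n <- length(k)
  p <- ncol(X)
  sampleSigma <- is.null(sigmaFixed)
  s2 <- priorDf * priorScale^2
  nu1 <- priorDf + 1
  function(theta) {
    alpha <- theta[1L]
    beta <- if (p) theta[seq.int(2L, p + 1L)] else numeric(0)
    if (sampleSigma) {
      tau <- theta[p + 2L]
      sigma <- exp(tau)
      z <- theta[seq.int(p + 3L, p + 2L + n)]
      Lz <- as.numeric(L %*% z)
      u <- sigma * Lz
    } else {
      sigma <- sigmaFixed
      u <- if (sigma == 0) rep(0, n) else stop("fixed sigma > 0 unsupported")
    }
    eta <- alpha + (if (p) as.numeric(X %*% beta) else 0) + u
    pfit <- invlogit(eta)
    lp <- sum(k * eta - trials * log1pexp(eta)) -
      0.5 * nu1 * log1p(alpha^2 / s2)
    r <- k - trials * pfit
    ga <- sum(r) - nu1 * alpha / (s2 + alpha^2)
    gb <- if (p) as.numeric(crossprod(X, r)) else numeric(0)
    if (sampleSigma) {
      lp <- lp - 0.5 * nu1 * log1p(sigma^2 / s2) + tau - 0.5 * sum(z^2)
      gtau <- sigma * sum(Lz * r) - nu1 * sigma^2 / (s2 + sigma^2) + 1
      gz <- sigma * as.numeric(crossprod(L, r)) - z
      list(lp = lp, grad = c(ga, gb, gtau, gz))
    } else {
      list(lp = lp, grad = c(ga, gb))
    }
  }
}

## crude reasonable-stepsize search (single leapfrog step, ~50% acceptance)
.findEps <- function(target, q, invM, eps = 0.1) {
  cur <- target(q)
  pmom <- rnorm(length(q)) / sqrt(invM)
  h0 <- cur$lp - 0.5 * sum(pmom^2 * invM)
  step <- function(e) {
    pn <- pmom + 0.5 * e * cur$grad
    qn <- q + e * invM * pn
    prop <- target(qn)
    if (!is.finite(prop$lp)) return(-Inf)
    pn <- pn + 0.5 * e * prop$grad
    (prop$lp - 0.5 * sum(pn^2 * invM)) - h0
  }
  up <- step(eps) > log(0.5)
  for (i in 1:40) {
    eps2 <- if (up) eps * 2 else eps / 2
    ok <- step(eps2) > log(0.5)
    if (up && !ok) break
    eps <- eps2
    if (!up && ok) break
  }
  eps
}

## one HMC chain with dual-averaged step size and one diagonal-mass window
.hmcChain <- function(target, init, iter, warmup, targetAccept = 0.8,
                      maxLeapfrog = 16) {
  d <- length(init)
  q <- init
  cur <- target(q)
  if (!is.finite(cur$lp)) stop("non-finite log-posterior at initial values")
  draws <- matrix(NA_real_, iter, d)
  acc <- numeric(iter)
  invM <- rep(1, d)
  sqrtInvM <- rep(1, d)
  eps <- .findEps(target, q, invM)
  mu <- log(10 * eps)
  Hbar <- 0
  logEpsBar <- log(eps)
  gammaDA <- 0.05; t0 <- 10; kappaDA <- 0.75
  ## two expanding mass-adaptation windows: late draws see a mass matrix
  ## closer to the posterior scale, which matters for heavy-tailed targets
  mWindows <- list(c(max(2L, floor(warmup * 0.15)), floor(warmup * 0.45)),
                   c(floor(warmup * 0.45), floor(warmup * 0.8)))
  mSteps <- 0L
  for (it in seq_len(iter)) {
    pmom <- rnorm(d) / sqrtInvM
    h0 <- cur$lp - 0.5 * sum(pmom^2 * invM)
    nstep <- sample.int(maxLeapfrog, 1L)
    qn <- q
    pn <- pmom + 0.5 * eps * cur$grad
    prop <- cur
    diverged <- FALSE
    for (l in seq_len(nstep)) {
      qn <- qn + eps * invM * pn
      prop <- target(qn)
      if (!is.finite(prop$lp)) { diverged <- TRUE; break }
      if (l < nstep) pn <- pn + eps * prop$grad
    }
    if (!diverged) {
      pn <- pn + 0.5 * eps * prop$grad
      a <- min(1, exp((prop$lp - 0.5 * sum(pn^2 * invM)) - h0))
    } else a <- 0
    if (runif(1L) < a) { q <- qn; cur <- prop }
    acc[it] <- a
    draws[it, ] <- q
    if (it <= warmup) {
      mSteps <- mSteps + 1L
      Hbar <- (1 - 1 / (mSteps + t0)) * Hbar +
        (targetAccept - a) / (mSteps + t0)
      logEps <- mu - sqrt(mSteps) / gammaDA * Hbar
      w <- mSteps^(-kappaDA)
      logEpsBar <- w * logEps + (1 - w) * logEpsBar
      eps <- exp(logEps)
      for (win in mWindows) {
        if (it == win[2L] && win[2L] > win[1L] + 10L) {
          v <- apply(draws[win[1L]:win[2L], , drop = FALSE], 2L, var)
          v[!is.finite(v) | v < 1e-8] <- 1
          invM <- v
          sqrtInvM <- sqrt(invM)
          eps <- .findEps(target, q, invM)
          mu <- log(10 * eps)
          Hbar <- 0
          logEpsBar <- log(eps)
          mSteps <- 0L
        }
      }
      if (it == warmup) eps <- exp(logEpsBar)
    }
  }
  keep <- seq.int(warmup + 1L, iter)
  list(draws = draws[keep, , drop = FALSE],
       acceptRate = mean(acc[keep]), stepSize = eps)
}

#' Split-Rhat convergence diagnostic
#'
#' Gelman-Rubin potential scale reduction computed on chains split in half.
#'
#' @param x numeric vector of draws (all chains concatenated).
#' @param chain integer chain index per draw.
#' @return Rhat (>= 1; 1 when chains agree).
#' @export
splitRhat <- function(x, chain) {
  pieces <- list()
  for (v in split(x, chain)) {
    n2 <- floor(length(v) / 2)
    pieces <- c(pieces, list(v[seq_len(n2)],
                             v[seq.int(length(v) - n2 + 1L, length(v))]))
  }
  n <- min(lengths(pieces))
  pieces <- lapply(pieces, function(v) v[seq_len(n)])
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## Geyer initial-positive-sequence ESS, summed over chains
.essChain <- function(v) {
  n <- length(v)
  if (var(v) == 0) return(n)
  rho <- as.numeric(acf(v, lag.max = min(n - 1L, 400L), plot = FALSE,
                        demean = TRUE)$acf)
  npair <- floor(length(rho) / 2)
  P <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  bad <- which(P <= 0)
  if (length(bad)) P <- P[seq_len(bad[1L] - 1L)]
  tau <- max(2 * sum(P) - 1, 1 / n)
  min(n, n / tau)
}

#' Effective sample size
#' @param x numeric vector of draws (all chains concatenated).
#' @param chain integer chain index per draw.
#' @return estimated number of effectively independent draws.
#' @export
effectiveSize <- function(x, chain) {
  sum(vapply(split(x, chain), .essChain, 0))
}

#' Fit the Bayesian phylogenetic binomial regression
#'
#' Samples the posterior of the dichromatism model (binomial counts out of
#' \code{trials} patches, logit link, fixed effects \code{X}, species
#' random effect with covariance \eqn{\sigma^2 C}) by Hamiltonian Monte
#' Carlo in a non-centred parameterisation, with dual-averaged step size
#' and a diagonal mass matrix adapted during warmup. Priors follow
#' [logPosterior()].
#'
#' @param k named integer vector of dichromatic-patch counts per species.
#' @param X design matrix from [designMatrix()] (rows match \code{k}).
#' @param C phylogenetic correlation from [phyloCorrelation()], or NULL
#'   for independent species.
#' @param trials binomial trials (default 5).
#' @param chains,iter,warmup sampler settings; defaults 6 chains of 6000
#'   iterations, first half warmup.
#' @param seed integer seed; chains use \code{seed + chain}.
#' @param sigma NULL to sample the phylogenetic scale (default), or 0 to
#'   fix it (no random effect).
#' @param maxLeapfrog,targetAccept HMC tuning knobs.
#' @param label model label stored in the fit.
#' @return a \linkS4class{PosteriorFit}
#' @export
fitDichromatismModel <- function(k, X = NULL, C = NULL, trials = 5,
                                 chains = 6, iter = 6000,
                                 warmup = floor(iter / 2), seed = 1,
                                 sigma = NULL, maxLeapfrog = 16,
                                 targetAccept = 0.8, label = "model") {
  n <- length(k)
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X rows must match k", call. = FALSE)
  species <- names(k)
  if (is.null(species)) species <- rownames(X)
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(n))
  if (anyNA(k) || anyNA(X)) stop("missing values in model data", call. = FALSE)
  if (any(k < 0) || any(k > trials)) stop("counts outside [0, trials]",
                                          call. = FALSE)
  sampleSigma <- is.null(sigma)
  L <- if (sampleSigma) {
    Cm <- if (is.null(C)) diag(n) else {
      if (!isTRUE(all.equal(dim(C), c(n, n))))
        stop("C must be n x n", call. = FALSE)
      as.matrix(C)
    }
    ## guard tiny negative eigenvalues from numerically rank-deficient trees
    t(chol(Cm + diag(1e-8, n)))
  } else NULL
  target <- .makeTarget(k, X, L, trials, sigmaFixed = sigma)
  p <- ncol(X)
  d <- if (sampleSigma) p + 2L + n else p + 1L
  parNames <- c("alpha", colnames(X),
                if (sampleSigma) c("sigma_phylo", paste0("u.", species)))
  allDraws <- vector("list", chains)
  chainId <- integer(0)
  for (ch in seq_len(chains)) {
    set.seed(seed * 131L + ch)
    init <- c(rnorm(1L + p, 0, 0.3),
              if (sampleSigma) c(log(runif(1, 0.3, 0.8)), rnorm(n, 0, 0.1)))
    res <- .hmcChain(target, init, iter, warmup,
                     targetAccept = targetAccept, maxLeapfrog = maxLeapfrog)
    dr <- res$draws
    out <- if (sampleSigma) {
      sig <- exp(dr[, p + 2L])
      zcols <- seq.int(p + 3L, p + 2L + n)
      u <- (dr[, zcols, drop = FALSE] %*% t(L)) * sig
      cbind(dr[, seq_len(1L + p), drop = FALSE], sig, u)
    } else {
      dr
    }
    colnames(out) <- parNames
    allDraws[[ch]] <- out
    chainId <- c(chainId, rep.int(ch, nrow(out)))
  }
  draws <- do.call(rbind, allDraws)
  core <- c("alpha", colnames(X), if (sampleSigma) "sigma_phylo")
  rhat <- vapply(colnames(draws), function(j) splitRhat(draws[, j], chainId), 0)
  ess <- vapply(core, function(j) effectiveSize(draws[, j], chainId), 0)
  converged <- max(rhat[core]) <= 1.01
  if (!converged)
    warning(sprintf("model '%s' did not converge (max Rhat = %.3f)",
                    label, max(rhat[core])), call. = FALSE)
  if (p > 0) {
    med <- apply(draws[, colnames(X), drop = FALSE], 2L, median)
    if (any(abs(med) > 15))
      warning("extreme coefficient medians; the data may be separable and ",
              "the flat coefficient prior improper", call. = FALSE)
  }
  new("PosteriorFit",
      draws = draws, chain = chainId, rhat = rhat, ess = ess,
      model = list(k = k, trials = trials, X = X, C = C, label = label,
                   species = species, chains = chains, iter = iter,
                   warmup = warmup, seed = seed,
                   sampleSigma = sampleSigma),
      converged = converged)
}

#' Extract posterior draws
#'
#' @param fit a \linkS4class{PosteriorFit}
#' @param pars optional parameter names
#' @return draws matrix (draws x parameters)
#' @export
posteriorDraws <- function(fit, pars = NULL) {
  if (is.null(pars)) fit@draws else fit@draws[, pars, drop = FALSE]
}
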