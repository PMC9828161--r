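test_that("the sampler is seed-deterministic", {
  d <- simRegData(15, beta = 0.3, sigma = 0.4, seed = 2)
  ## short deliberately under-converged chains: only determinism matters here
  f1 <- suppressWarnings(
    fitDichromatismModel(d$k, d$X, d$C, chains = 2, iter = 400, seed = 5))
  f2 <- suppressWarnings(
    fitDichromatismModel(d$k, d$X, d$C, chains = 2, iter = 400, seed = 5))
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
  f3 <- suppressWarnings(
    fitDichromatismModel(d$k, d$X, d$C, chains = 2, iter = 400, seed = 6))
  expect_false(identical(posteriorDraws(f1), posteriorDraws(f3)))
})

test_that("intercept-only posterior matches a grid-integration oracle", {
  ## star tree, sigma fixed at 0: a one-parameter model
  k <- setNames(c(5L, 5L, 4L, 5L, 5L, 3L, 5L, 4L, 5L, 5L),
                sprintf("sp%02d", 1:10))
  fit <- fitDichromatismModel(k, sigma = 0, chains = 4, iter = 3000,
                              seed = 11)
  med <- median(posteriorDraws(fit)[, "alpha"])
  oracle <- gridPosteriorMedianAlpha(k)
  expect_equal(med, oracle, tolerance = 0.05)
  ## nearly all patches dichromatic: median probability above 0.9
  expect_gt(median(plogis(posteriorDraws(fit)[, "alpha"])), 0.9)
})

test_that("two-parameter posterior matches a 2-D grid oracle", {
  set.seed(31)
  x <- c(-1.5, -1, -0.5, 0, 0, 0.5, 1, 1.5, 2, -2)
  k <- setNames(rbinom(10, 5, plogis(0.3 + 0.8 * x)), sprintf("s%02d", 1:10))
  X <- cbind(x = x)
  fit <- fitDichromatismModel(k, X, sigma = 0, chains = 4, iter = 3000,
                              seed = 13)
  ## 2-D grid integration, marginal medians
  ag <- seq(-4, 4, by = 0.02); bg <- seq(-4, 4, by = 0.02)
  lp <- outer(ag, bg, Vectorize(function(a, b)
    sum(dbinom(k, 5, plogis(a + b * x), log = TRUE)) +
      dt(a / 10, 3, log = TRUE)))
  w <- exp(lp - max(lp))
  margA <- rowSums(w); margB <- colSums(w)
  medA <- ag[which.min(abs(cumsum(margA) / sum(margA) - 0.5))]
  medB <- bg[which.min(abs(cumsum(margB) / sum(margB) - 0.5))]
  expect_lt(abs(median(posteriorDraws(fit)[, "alpha"]) - medA), 0.07)
  expect_lt(abs(median(posteriorDraws(fit)[, "x"]) - medB), 0.07)
})

test_that("posterior medians agree with an independent JAGS fit", {
  skip_if_not_installed("rjags")
  d <- simRegData(40, beta = log(1.4), sigma = 0.5, seed = 8)
  fit <- fitDichromatismModel(d$k, d$X, d$C, chains = 3, iter = 3000,
                              seed = 4)
  ## non-centred in JAGS as well (u = sigma * L z) so the sigma chain
  ## mixes through the funnel
  model <- "
    model {
      for (s in 1:n) {
        z[s] ~ dnorm(0, 1)
        k[s] ~ dbin(ilogit(alpha + beta * x[s] + sigma * Lz[s]), 5)
      }
      Lz <- L %*% z
      alpha ~ dt(0, 1 / 100, 3)
      beta ~ dnorm(0, 1e-4)    # near-flat proper stand-in
      sigma ~ dt(0, 1 / 100, 3) T(0,)
    }"
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(k = unname(d$k), x = unname(d$X[, 1]), n = 40,
                L = t(chol(d$C + diag(1e-8, 40)))),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 99),
    n.chains = 1, quiet = TRUE)
  stats::update(jm, 4000, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("alpha", "beta", "sigma"), 20000,
                            progress.bar = "none")
  jdraws <- as.matrix(js[[1]])
  expect_lt(abs(median(posteriorDraws(fit)[, "alpha"]) -
                median(jdraws[, "alpha"])), 0.2)
  expect_lt(abs(median(posteriorDraws(fit)[, "nSympatric"]) -
                median(jdraws[, "beta"])), 0.1)
  expect_lt(abs(median(posteriorDraws(fit)[, "sigma_phylo"]) -
                median(jdraws[, "sigma"])), 0.2)
})

test_that("convergence diagnostics behave on known chains", {
  set.seed(14)
  good <- rnorm(4000)
  expect_lt(splitRhat(good, rep(1:4, each = 1000)), 1.01)
  ## chains with different means are flagged
  bad <- c(rnorm(1000), rnorm(1000, 3))
  expect_gt(splitRhat(bad, rep(1:2, each = 1000)), 1.2)
  ## independent draws: ESS near the sample size
  expect_gt(effectiveSize(good, rep(1:4, each = 1000)), 2500)
  ## strongly autocorrelated draws: ESS much smaller
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), 2000))
  expect_lt(effectiveSize(ar, rep(1, 2000)), 500)
})

test_that("pd calibration: null effects rarely cross the decision line", {
  ## data simulated with beta = 0: pd is asymptotically Phi(|z|) with
  ## z ~ N(0, 1), so pd < 0.90 in about 80% of replicates; assert at
  ## three binomial standard deviations below that rate
  hits <- 0
  for (r in 1:50) {
    d <- simRegData(40, beta = 0, sigma = 0, seed = 100 + r)
    fit <- suppressWarnings(
      fitDichromatismModel(d$k, d$X, C = NULL, chains = 2, iter = 600,
                           seed = r, sigma = 0))
    pd <- probDirection(posteriorDraws(fit)[, "nSympatric"])
    if (pd < 0.90) hits <- hits + 1
  }
  expect_gte(hits, 32)
})

test_that("summaries are withheld for non-converged fits unless forced", {
  draws <- cbind(alpha = c(rnorm(200), rnorm(200, 5)),
                 sigma_phylo = abs(rnorm(400)))
  fit <- new("PosteriorFit", draws = draws, chain = rep(1:2, each = 200),
             rhat = c(alpha = 2.5, sigma_phylo = 1),
             ess = c(alpha = 5, sigma_phylo = 100),
             model = list(X = matrix(0, 400, 0), sampleSigma = TRUE,
                          label = "toy"),
             converged = FALSE)
  expect_error(summarizePosterior(fit), "did not converge")
  expect_silent(s <- summarizePosterior(fit, force = TRUE))
  expect_true(is.list(s))
})
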