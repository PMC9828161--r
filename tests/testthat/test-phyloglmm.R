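test_that("phylogenetic correlation reflects shared path lengths", {
  ## star tree: no shared history -> identity
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  C <- phyloCorrelation(star)
  expect_equal(C, diag(4), ignore_attr = TRUE)
  ## cherry splitting at depth 0.6 of total depth 1
  tr <- ape::read.tree(text = "((a:0.4,b:0.4):0.6,c:1);")
  C2 <- phyloCorrelation(tr, c("a", "b", "c"))
  expect_equal(C2["a", "b"], 0.6)
  expect_equal(C2["a", "c"], 0)
  expect_equal(diag(C2), rep(1, 3), ignore_attr = TRUE)
  ## PSD and symmetric on a random tree
  tr3 <- simulateTree(25, 1, 3)
  C3 <- phyloCorrelation(tr3)
  expect_equal(C3, t(C3))
  expect_gte(min(eigen(C3, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_error(phyloCorrelation(tr3, c("sp001", "nope")), "not in tree")
})

test_that("log-posterior matches an independently coded density", {
  set.seed(9)
  k <- c(0L, 3L, 5L)
  X <- cbind(x = c(-1, 0, 1.5))
  tr <- ape::read.tree(text = "((a:0.4,b:0.4):0.6,c:1);")
  C <- phyloCorrelation(tr, c("a", "b", "c"))
  for (i in 1:5) {
    alpha <- rnorm(1); beta <- rnorm(1); sigma <- runif(1, 0.2, 2)
    u <- rnorm(3, 0, 0.5)
    expect_equal(
      logPosterior(k, X, C, alpha = alpha, beta = beta, sigma = sigma, u = u),
      oracleLogPosterior(k, X, C, alpha, beta, sigma, u),
      tolerance = 1e-9)
  }
  ## sigma = 0 with u = 0 reduces to the ordinary logistic regression
  ## posterior (binomial likelihood + intercept prior, no MVN term)
  lp0 <- logPosterior(k, X, C, alpha = 0.3, beta = 0.7, sigma = 0,
                      u = rep(0, 3))
  eta <- 0.3 + 0.7 * X[, 1]
  manual <- sum(dbinom(k, 5, plogis(eta), log = TRUE)) +
    dt(0.03, 3, log = TRUE) - log(10) +
    log(2) + dt(0, 3, log = TRUE) - log(10)
  expect_equal(lp0, manual, tolerance = 1e-12)
  expect_equal(logPosterior(k, X, C, alpha = 0, beta = 0.7, sigma = 0,
                            u = c(0, 0.1, 0)), -Inf)
})

test_that("HDI finds the narrowest interval and covers the stated mass", {
  set.seed(21)
  x <- rnorm(1e5)
  h <- hdi(x, 0.90)
  expect_equal(unname(h["lower"]), -1.645, tolerance = 0.05)
  expect_equal(unname(h["upper"]), 1.645, tolerance = 0.05)
  expect_gte(mean(x >= h["lower"] & x <= h["upper"]), 0.89)
  ## constant draws collapse to a point
  expect_equal(hdi(rep(3.2, 200)), c(lower = 3.2, upper = 3.2))
  ## uniform: any 0.9-width window
  u <- runif(2e4)
  hu <- hdi(u, 0.90)
  expect_equal(unname(diff(hu)), 0.9, tolerance = 0.02)
  ## a skewed sample: HDI is narrower than the central interval
  g <- rgamma(5e4, shape = 2)
  hg <- hdi(g, 0.90)
  cg <- quantile(g, c(0.05, 0.95))
  expect_lt(diff(hg), diff(cg))
  expect_gte(mean(g >= hg["lower"] & g <= hg["upper"]), 0.89)
  expect_error(hdi(x, 1.2), "mass")
  expect_error(hdi(1:10), "100 draws")
})

test_that("probability of direction follows the median's sign", {
  expect_equal(probDirection(c(1, 2, 3)), 1.0)
  expect_equal(probDirection(c(1, 2, 3, -1)), 0.75)  # median 1.5 > 0
  expect_equal(probDirection(c(-1, -2, -3, 1)), 0.75)
  set.seed(2)
  expect_equal(probDirection(rnorm(2e5)), 0.5, tolerance = 0.01)
  expect_error(probDirection(numeric(0)), "empty")
})

test_that("lambda is the latent-scale intraclass correlation", {
  expect_equal(unname(lambdaICC(rep(sqrt(pi^2 / 3), 200))["median"]), 0.5)
  expect_equal(unname(lambdaICC(rep(0, 200))["median"]), 0)
  expect_equal(unname(lambdaICC(rep(sqrt(3 * pi^2 / 3), 200))["median"]),
               0.75)
  expect_error(lambdaICC(c(-0.1, 0.2)), ">= 0")
})

test_that("odds ratios transform coefficient draws", {
  ## hand-built fit object with known draws
  draws <- cbind(alpha = rep(0, 400), x = rep(log(2), 400),
                 sigma_phylo = rep(0.5, 400))
  fit <- new("PosteriorFit", draws = draws, chain = rep(1:2, each = 200),
             rhat = c(alpha = 1, x = 1, sigma_phylo = 1),
             ess = c(alpha = 400, x = 400, sigma_phylo = 400),
             model = list(X = cbind(x = 1), sampleSigma = TRUE,
                          label = "toy"),
             converged = TRUE)
  or <- oddsRatios(fit)
  expect_equal(or$or[or$parameter == "x"], 2.0)
  expect_equal(or$or[or$parameter == "Intercept"], 1.0)
  ## beta draws centred on zero: OR ~ 1, pd ~ 0.5, not flagged
  set.seed(5)
  draws2 <- cbind(alpha = rnorm(4000), x = rnorm(4000),
                  sigma_phylo = abs(rnorm(4000)))
  fit2 <- new("PosteriorFit", draws = draws2, chain = rep(1:2, each = 2000),
              rhat = c(alpha = 1, x = 1, sigma_phylo = 1),
              ess = c(alpha = 1, x = 1, sigma_phylo = 1),
              model = list(X = cbind(x = 1), sampleSigma = TRUE,
                           label = "toy"),
              converged = TRUE)
  or2 <- oddsRatios(fit2)
  expect_lt(abs(or2$pd[or2$parameter == "x"] - 0.5), 0.03)
  expect_false(or2$reliable[or2$parameter == "x"])
  ## an OR of 1.4 is a 40% increase in odds per predictor unit
  expect_equal(100 * (exp(log(1.4)) - 1), 40)
})
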