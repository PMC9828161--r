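## Shared fixtures and independent oracles for the test suite.

## Gaussian spectral curve, peak 1 at lambdaMax
gaussSens <- function(grid, lambdaMax, sigma) {
  exp(-(grid - lambdaMax)^2 / (2 * sigma^2))
}

## minimal dichromatic visual system on a given grid
makeDichromat <- function(grid = 300:700, nu = 0.1,
                          abundances = c(s = 1, l = 1)) {
  visualSystem(
    sensitivities = cbind(s = gaussSens(grid, 420, 40),
                          l = gaussSens(grid, 560, 40)),
    wavelengths = grid,
    abundances = abundances,
    weberFraction = nu,
    achromaticSensitivity = gaussSens(grid, 560, 60),
    achromaticWeber = 0.1)
}

## tetrachromat with unequal abundances (so noises differ)
makeTetrachromat <- function(grid = 300:700) {
  visualSystem(
    sensitivities = cbind(u = gaussSens(grid, 370, 30),
                          s = gaussSens(grid, 450, 35),
                          m = gaussSens(grid, 505, 40),
                          l = gaussSens(grid, 560, 45)),
    wavelengths = grid,
    abundances = c(u = 1, s = 1.8, m = 2.2, l = 2),
    weberFraction = 0.1, weberReference = "l",
    achromaticSensitivity = gaussSens(grid, 560, 60),
    achromaticWeber = 0.1)
}

## independent implementation of the tetrachromatic RNL distance: the
## explicit printed four-receptor formula, coded term by term
tetraDeltaS <- function(df, e) {
  num <- (e[1] * e[2])^2 * (df[3] - df[4])^2 +
         (e[1] * e[3])^2 * (df[2] - df[4])^2 +
         (e[1] * e[4])^2 * (df[2] - df[3])^2 +
         (e[2] * e[3])^2 * (df[1] - df[4])^2 +
         (e[2] * e[4])^2 * (df[1] - df[3])^2 +
         (e[3] * e[4])^2 * (df[1] - df[2])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
         (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}

## two-receptor closed form
diDeltaS <- function(df, e) abs(df[1] - df[2]) / sqrt(e[1]^2 + e[2]^2)

## build a ReflectanceSet from a list of reflectance vectors + label rows
makeSpectra <- function(grid, refl, species, sex, patch,
                        specimen = "s1", replicate = 1L) {
  info <- data.frame(species = species, sex = sex, patch = patch,
                     specimen = specimen, replicate = as.integer(replicate))
  reflectanceSet(grid, do.call(cbind, refl), info)
}

## spectra for one species with all five patches and given per-sex bases;
## maleShift: named list patch -> additive offset vector (or NULL)
speciesPatchSpectra <- function(grid, base, nMale = 1, nFemale = 1,
                                species = "spA", maleShift = list()) {
  patches <- c("belly", "breast", "throat", "crown", "mantle")
  cols <- list(); info <- list()
  ci <- 0L
  for (p in patches) {
    shift <- if (!is.null(maleShift[[p]])) maleShift[[p]] else 0
    for (s in seq_len(nMale)) {
      ci <- ci + 1L
      cols[[ci]] <- pmin(pmax(base + shift, 0), 1)
      info[[ci]] <- data.frame(species = species, sex = "M", patch = p,
                               specimen = paste0("s", s), replicate = NA_integer_)
    }
    for (s in seq_len(nFemale)) {
      ci <- ci + 1L
      cols[[ci]] <- base
      info[[ci]] <- data.frame(species = species, sex = "F", patch = p,
                               specimen = paste0("s", s), replicate = NA_integer_)
    }
  }
  reflectanceSet(grid, do.call(cbind, cols), do.call(rbind, info))
}

## independently coded log-posterior of the phylogenetic binomial model
## (textbook term sums; kept free of the package's internal helpers)
oracleLogPosterior <- function(k, X, C, alpha, beta, sigma, u, trials = 5) {
  eta <- alpha + as.numeric(X %*% beta) + u
  ll <- sum(dbinom(k, trials, 1 / (1 + exp(-eta)), log = TRUE))
  n <- length(k)
  Sig <- sigma^2 * C
  mvn <- -0.5 * (n * log(2 * pi) +
                 as.numeric(determinant(Sig, logarithm = TRUE)$modulus) +
                 as.numeric(t(u) %*% solve(Sig) %*% u))
  pa <- dt(alpha / 10, df = 3, log = TRUE) - log(10)
  ps <- log(2) + dt(sigma / 10, df = 3, log = TRUE) - log(10)
  ll + mvn + pa + ps
}

## grid-integration posterior median for the intercept-only model with no
## random effect (1-D reduction)
gridPosteriorMedianAlpha <- function(k, trials = 5,
                                     grid = seq(-10, 10, by = 0.002)) {
  lp <- vapply(grid, function(a) {
    sum(dbinom(k, trials, 1 / (1 + exp(-a)), log = TRUE)) +
      dt(a / 10, df = 3, log = TRUE) - log(10)
  }, 0)
  w <- exp(lp - max(lp))
  cdf <- cumsum(w) / sum(w)
  grid[which.min(abs(cdf - 0.5))]
}

## brute-force range metrics on a toy grid (pure set operations)
bruteOverlap <- function(occ, focal, other) {
  a <- which(occ[, focal] == 1)
  b <- which(occ[, other] == 1)
  100 * length(intersect(a, b)) / length(a)
}

## small simulated regression dataset with a sympatry-like predictor
simRegData <- function(n, beta, sigma, seed, trials = 5) {
  tree <- simulateTree(n, 1, seed)
  set.seed(seed + 5000)
  x <- rpois(n, 5)
  X <- cbind(nSympatric = x)
  rownames(X) <- tree$tip.label
  C <- phyloCorrelation(tree)
  u <- if (sigma > 0) as.numeric(sigma * t(chol(C + diag(1e-10, n))) %*%
                                 rnorm(n)) else rep(0, n)
  eta <- -2 + beta * x + u
  k <- rbinom(n, trials, 1 / (1 + exp(-eta)))
  list(k = setNames(k, tree$tip.label), X = X, C = C, tree = tree,
       beta = beta, sigma = sigma)
}
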