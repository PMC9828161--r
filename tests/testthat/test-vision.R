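test_that("pigment template peaks at lambda-max and is unimodal nearby", {
  s <- pigmentTemplate(560, 300:700)
  expect_equal(s[560 - 299], 1.0, tolerance = 1e-9)
  expect_lt(s[640 - 299], s[560 - 299])
  expect_lt(s[480 - 299], s[560 - 299])
  expect_error(pigmentTemplate(250), "300")
})

test_that("pigment template matches an independent coding of its equations", {
  ## alpha band and beta band recoded inline, term by term
  lmax <- 560; lam <- 600
  x <- lmax / lam
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lmax
  bw <- -40.5 + 0.195 * lmax
  expected <- alpha + 0.26 * exp(-((lam - lmb) / bw)^2)
  grid <- 300:700
  s <- pigmentTemplate(lmax, grid)
  ## the package normalises by the on-grid peak; undo that for comparison
  peakVal <- max(vapply(grid, function(l) {
    xx <- lmax / l
    al <- 1 / (exp(69.7 * (a - xx)) + exp(28 * (0.922 - xx)) +
               exp(-14.9 * (1.104 - xx)) + 0.674)
    al + 0.26 * exp(-((l - lmb) / bw)^2)
  }, 0))
  expect_equal(s[grid == lam] * peakVal, expected, tolerance = 1e-9)
})

test_that("quantum catches integrate reflectance x sensitivity x illuminant", {
  grid <- seq(300, 700, by = 1)
  ## unit-area box sensitivity: R = 1, I = 1 -> Q = 1
  box <- ifelse(grid >= 400 & grid <= 500, 1, 0)
  vsBox <- visualSystem(cbind(a = box, b = box), grid,
                        c(a = 1, b = 1), achromaticSensitivity = box)
  x1 <- makeSpectra(grid, list(rep(1, length(grid))), "a", "M", "belly")
  q1 <- quantumCatches(x1, vsBox)
  ## 100 nm of interior segments plus two half-weight edge points
  expect_equal(unname(q1[1, "a"]), 101, tolerance = 1e-9)
  ## halving reflectance halves every catch
  xh <- makeSpectra(grid, list(rep(0.5, length(grid))), "a", "M", "belly")
  expect_equal(quantumCatches(xh, vsBox), q1 / 2, tolerance = 1e-12)
})

test_that("1-nm trapezoid catches match a 0.1-nm oracle for smooth spectra", {
  grid <- seq(300, 700, by = 1)
  fine <- seq(300, 700, by = 0.1)
  sens <- function(g) gaussSens(g, 500, 50)
  refl <- function(g) 0.5 + 0 * g
  vs <- visualSystem(cbind(a = sens(grid), b = gaussSens(grid, 420, 40)),
                     grid, c(a = 1, b = 1),
                     achromaticSensitivity = sens(grid))
  x <- makeSpectra(grid, list(refl(grid)), "a", "M", "belly")
  q <- quantumCatches(x, vs)
  ## independent 0.1-nm trapezoid
  w <- rep(0.1, length(fine))
  w[c(1, length(fine))] <- 0.05
  oracle <- sum(refl(fine) * sens(fine) * w)
  expect_equal(oracle, 62.67, tolerance = 1e-3)
  expect_lt(abs(q[1, "a"] - oracle) / oracle, 1e-3)

  ## Gaussian-mixture reflectance, same bound
  reflMix <- function(g) 0.2 * gaussSens(g, 450, 30) + 0.5 * gaussSens(g, 620, 60)
  xm <- makeSpectra(grid, list(reflMix(grid)), "a", "M", "belly")
  qm <- quantumCatches(xm, vs)
  oracleM <- sum(reflMix(fine) * sens(fine) * w)
  expect_lt(abs(qm[1, "a"] - oracleM) / oracleM, 1e-3)
})

test_that("receptor noise follows the abundance-ratio rule", {
  vs <- makeDichromat(abundances = c(s = 1, l = 4))
  e <- receptorNoise(vs)
  expect_equal(unname(e["l"]), 0.1)           # reference receptor
  expect_equal(unname(e["s"]), 0.1 * sqrt(4)) # 0.1 * sqrt(eta_ref / eta)
  ## doubling all abundances changes nothing
  vs2 <- makeDichromat(abundances = c(s = 2, l = 8))
  expect_equal(receptorNoise(vs2), receptorNoise(vs))
})

test_that("chromatic contrast matches the two-receptor closed form", {
  vs <- makeDichromat(abundances = c(s = 1, l = 4))
  e <- receptorNoise(vs)  # (0.2, 0.1)
  qa <- c(s = exp(0.1), l = exp(0.3))
  qb <- c(s = 1, l = 1)
  expect_equal(chromaticContrast(qa, qb, vs),
               abs(0.1 - 0.3) / sqrt(e[["s"]]^2 + e[["l"]]^2),
               tolerance = 1e-12)
  ## the printed worked case: e = (0.1, 0.2), delta-f = (0.1, 0.3)
  vsEq <- makeDichromat(abundances = c(s = 4, l = 1))  # e = (0.1, 0.2)
  expect_equal(chromaticContrast(c(s = exp(0.1), l = exp(0.3)),
                                 c(s = 1, l = 1), vsEq),
               0.2 / sqrt(0.05), tolerance = 1e-9)
  expect_equal(0.2 / sqrt(0.05), 0.8944, tolerance = 1e-4)
})

test_that("contrasts are symmetric, zero on identity, scale-invariant", {
  vs <- makeTetrachromat()
  set.seed(42)
  for (i in 1:20) {
    qa <- setNames(exp(rnorm(4, 0, 0.5)), c("u", "s", "m", "l"))
    qb <- setNames(exp(rnorm(4, 0, 0.5)), c("u", "s", "m", "l"))
    expect_equal(chromaticContrast(qa, qb, vs), chromaticContrast(qb, qa, vs))
    expect_gte(chromaticContrast(qa, qb, vs), 0)
    ## multiplying both stimuli (e.g. a brighter illuminant) cancels
    expect_equal(chromaticContrast(qa * 7, qb * 7, vs),
                 chromaticContrast(qa, qb, vs), tolerance = 1e-12)
  }
  qa <- c(u = 1.3, s = 0.7, m = 2.1, l = 0.4)
  expect_equal(chromaticContrast(qa, qa, vs), 0)
  expect_equal(achromaticContrast(5, 5, vs), 0)
  expect_equal(achromaticContrast(2, 8, vs), achromaticContrast(8, 2, vs))
})

test_that("achromatic contrast is the Weber-scaled log ratio", {
  vs <- makeDichromat()
  expect_equal(achromaticContrast(1, exp(0.2), vs), 2.0, tolerance = 1e-12)
  expect_error(achromaticContrast(-1, 2, vs), "positive")
})

test_that("illuminant scaling leaves JNDs unchanged end to end", {
  grid <- 300:700
  vs1 <- makeTetrachromat()
  vs7 <- vs1
  vs7@illuminant <- vs1@illuminant * 7
  x <- makeSpectra(grid,
                   list(0.3 * gaussSens(grid, 480, 80),
                        0.3 * gaussSens(grid, 560, 80)),
                   c("a", "a"), c("M", "F"), "belly",
                   c("s1", "s1"), c(1L, 1L))
  q1 <- quantumCatches(x, vs1)
  q7 <- quantumCatches(x, vs7)
  expect_equal(chromaticContrast(q7[1, ], q7[2, ], vs7),
               chromaticContrast(q1[1, ], q1[2, ], vs1), tolerance = 1e-12)
  expect_equal(achromaticContrast(q7[1, ], q7[2, ], vs7),
               achromaticContrast(q1[1, ], q1[2, ], vs1), tolerance = 1e-12)
})

test_that("the packaged blackbird system loads with four cones", {
  vs <- blackbirdVisualSystem()
  expect_s4_class(vs, "VisualSystem")
  expect_equal(colnames(vs@sensitivities), c("uvs", "sws", "mws", "lws"))
  expect_equal(vs@weberFraction, 0.1)
  expect_equal(max(vs@sensitivities[, "uvs"]), 1)
  ## grids must match between spectra and visual system
  x <- makeSpectra(seq(300, 700, 2), list(rep(0.5, 201)), "a", "M", "belly")
  expect_error(quantumCatches(x, vs), "grid")
})
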