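test_that("Yule trees are ultrametric, unit depth and seed-deterministic", {
  tr2 <- simulateTree(2, 1, 1)
  d2 <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(d2, c(1, 1))
  expect_identical(ape::write.tree(simulateTree(30, 1, 9)),
                   ape::write.tree(simulateTree(30, 1, 9)))
  tr <- simulateTree(100, 1, 4)
  expect_equal(length(tr$tip.label), 100L)
  depths <- ape::node.depth.edgelength(tr)[1:100]
  expect_lt(max(abs(depths - 1)), 1e-9)
  expect_equal(tr$tip.label[1], "sp001")
  expect_error(simulateTree(1), ">= 2")
})

test_that("trait draws match the configured truncated normal", {
  n <- 1e4
  set.seed(77)
  draws <- dichromatR:::.rtruncnorm(n, 5.4, 2.3, 1, 12)
  expect_true(all(draws >= 1 & draws <= 12))
  ## truncation to [1, 12] shifts the mean of N(5.4, 2.3) only slightly;
  ## Monte-Carlo mean of the truncated distribution
  m <- 5.4; s <- 2.3
  a <- (1 - m) / s; b <- (12 - m) / s
  truncMean <- m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_equal(mean(draws), truncMean, tolerance = 0.1)
  expect_equal(mean(draws), 5.4, tolerance = 0.15)
})

test_that("simulated ranges respect island quotas and match brute force", {
  tr <- simulateTree(20, 1, 5)
  cfg <- simulationConfig(nSpecies = 20)
  tg <- simulateTraits(tr, cfg, 5)
  isl <- tg$traits$landmass == "island"
  if (any(isl)) {
    cellCounts <- colSums(tg$grid@occupancy)[tg$traits$species[isl]]
    expect_true(all(cellCounts <= cfg$islandMaxCells))
  }
  ## overlaps on the emitted grid equal brute-force cell intersection
  occ <- tg$grid@occupancy
  sp <- sample(colnames(occ), 5)
  for (a in sp) for (b in sp)
    expect_equal(overlapPercent(tg$grid, a, b), bruteOverlap(occ, a, b))
  ## trait table is complete
  expect_false(anyNA(tg$traits))
  expect_equal(nrow(tg$traits), 20L)
})

test_that("dichromatism counts follow the latent regression", {
  ## alpha = 0, beta = 0, sigma = 0: p = 0.5, mean k = 2.5
  tr <- simulateTree(10000, 1, 2)
  traits <- data.frame(species = tr$tip.label)
  sim <- simulateDichromatismCounts(
    tr, traits, list(model = "null", alpha = 0, beta = numeric(0),
                     sigma = 0), seed = 3)
  expect_equal(mean(sim$scores$k), 2.5, tolerance = 0.05)
  expect_true(all(sim$truth$u == 0))
  ## positive beta induces a positive rank correlation with the predictor
  tr2 <- simulateTree(300, 1, 6)
  traits2 <- data.frame(species = tr2$tip.label,
                        migration = "none",
                        breedingSeasonMonths = 5,
                        landmass = "mainland",
                        rangeSizeKm2 = 1e5,
                        nSympatric = rpois(300, 5),
                        zBreedingSeason = 0)
  sim2 <- simulateDichromatismCounts(
    tr2, traits2, list(model = "sympatry", alpha = -2,
                       beta = c(nSympatric = 1), sigma = 0), seed = 4)
  expect_gt(cor(traits2$nSympatric, sim2$scores$k, method = "spearman"), 0.3)
  expect_error(simulateDichromatismCounts(
    tr2, traits2, list(model = "sympatry", alpha = 0,
                       beta = c(nSympatric = 0), sigma = -1), seed = 1),
    ">= 0")
})

test_that("spectral offsets calibrate to requested JND targets", {
  vs <- blackbirdVisualSystem()
  grid <- wavelengths(vs)
  base <- 0.1 + 0.25 * gaussSens(grid, 600, 70)
  expect_equal(calibrateSpectralOffset(base, 0, vs), 0)
  for (target in c(0.5, 1.5, 3, 4.5, 6)) {
    a <- calibrateSpectralOffset(base, target, vs, bumpCenter = 470)
    shifted <- pmin(pmax(base + a * gaussSens(grid, 470, 45 / sqrt(2)), 0), 1)
    ## recompute the achieved JND directly
    x <- makeSpectra(grid, list(base, shifted), c("a", "a"), c("F", "M"),
                     "belly", c("s1", "s2"), c(1L, 1L))
    q <- quantumCatches(x, vs)
    achieved <- chromaticContrast(q[2, ], q[1, ], vs)
    expect_equal(achieved, target, tolerance = 0.05)
  }
  ## JND grows monotonically with offset magnitude up to the point where
  ## reflectance clipping starts to saturate the bump
  jnds <- vapply(seq(0, 0.6, length.out = 50), function(a) {
    x <- makeSpectra(grid,
                     list(base, pmin(base + a * gaussSens(grid, 470, 45), 1)),
                     c("a", "a"), c("F", "M"), "belly", c("s1", "s2"),
                     c(1L, 1L))
    q <- quantumCatches(x, vs)
    chromaticContrast(q[2, ], q[1, ], vs)
  }, 0)
  expect_true(all(diff(jnds) > -1e-6))
  expect_error(calibrateSpectralOffset(base, 50, vs), "unreachable")
})

test_that("simulated spectra parse cleanly and recover intended scores", {
  vs <- blackbirdVisualSystem()
  scores <- data.frame(species = sprintf("sp%03d", 1:12),
                       k = rep(0:5, 2), nPatches = 5)
  cfg <- simulationConfig(nSpecies = 12)
  sp <- simulateSpectra(scores, cfg, vs, seed = 2)
  expect_equal(ncol(sp), 12 * 6 * 5 * 3)
  ## the emitted CSV parses through readSpectra with no warnings
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(sp, tmp)
  expect_no_warning(rt <- readSpectra(tmp))
  expect_equal(ncol(rt), ncol(sp))
  ## round trip: jnd -> score recovers the intended counts
  sc <- scoreSpecies(patchContrasts(averageReplicates(sp), vs))
  comb <- sc[sc$channel == "combined" & sc$threshold == cfg$threshold, ]
  recovered <- comb$k[match(scores$species, comb$species)]
  expect_gte(sum(recovered == scores$k), 11L)
  ## a species with no dimorphic patches stays monomorphic after noise
  expect_equal(recovered[scores$k == 0], rep(0L, sum(scores$k == 0)))
  expect_error(simulateSpectra(data.frame(species = "a", k = 6), cfg, vs, 1),
               "exceed")
})

test_that("study bundles are self-describing and seed-deterministic", {
  cfg <- simulationConfig(nSpecies = 8)
  b1 <- simulateStudy(cfg, seed = 3, spectra = FALSE)
  b2 <- simulateStudy(cfg, seed = 3, spectra = FALSE)
  expect_identical(b1$scores, b2$scores)
  expect_identical(b1$traits, b2$traits)
  expect_equal(sort(names(b1$truth$u)), sort(b1$traits$species))
  dir <- withr::local_tempdir()
  paths <- writeBundle(b1, dir)
  expect_true(all(file.exists(paths)))
  gt <- jsonlite::read_json(paths[["truth"]])
  expect_equal(gt$alpha, b1$truth$alpha)
})
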