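#' Default simulation configuration
#'
#' Parameters of the synthetic study generator, sized to emulate the
#' comparative dataset the pipeline targets: 77 species, 5 plumage patches,
#' 3 male + 3 female specimens measured in triplicate, breeding season
#' ~ Normal(5.4, 2.3) months truncated to [1, 12], and gridded breeding
#' ranges clustered in a few biogeographic hotspots so that sympatric
#' counts have a median near 6 among species with any sympatric congener.
#'
#' @param nSpecies number of species (>= 4).
#' @param ... overrides for any listed element.
#' @return a named list of generator settings.
#' @export
simulationConfig <- function(nSpecies = 77, ...) {
  cfg <- list(
    nSpecies = nSpecies,
    birthRate = 1,
    migrationProbs = c(none = 0.45, partial = 0.30, full = 0.25),
    seasonMean = 5.4, seasonSd = 2.3, seasonRange = c(1, 12),
    islandProb = 0.15, islandMaxCells = 4,
    nLon = 72, nLat = 36, cellAreaKm2 = 12300,  # ~111 km squares at equator
    nHotspots = 5, hotspotSpread = 1.1, pClustered = 0.55,
    rangeMeanCells = 6, rangeSdLog = 0.45,
    truth = list(model = "sympatry", alpha = -2, beta = c(nSympatric = log(1.4)),
                 sigma = 0.5),
    threshold = 2,               # scoring threshold the counts k refer to
    targetJndMargin = 1.5,       # dimorphic patches aim at threshold + margin
    patchPeaks = c(belly = 620, breast = 560, throat = 480, crown = 420,
                   mantle = 660),
    bumpWidth = 45,
    specimenNoiseSd = 0.010,     # multiplicative, log scale
    replicateNoiseSd = 0.004,    # multiplicative, log scale
    smoothNoiseSd = 0.004,       # additive smooth bump amplitude
    nMale = 3, nFemale = 3, nReplicates = 3
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  if (cfg$nSpecies < 4) stop("nSpecies must be >= 4", call. = FALSE)
  if (any(cfg$migrationProbs < 0) ||
      abs(sum(cfg$migrationProbs) - 1) > 1e-8)
    stop("migrationProbs must be a probability vector", call. = FALSE)
  cfg
}

#' Simulate a Yule tree
#'
#' Pure-birth ultrametric tree with tips \code{sp001, sp002, ...} and depth
#' normalised to 1.
#'
#' @param n number of tips (>= 2).
#' @param birthRate speciation rate.
#' @param seed integer seed.
#' @return an [ape::phylo] tree.
#' @export
simulateTree <- function(n, birthRate = 1, seed = 1) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  set.seed(seed)
  tr <- ape::rphylo(n, birth = birthRate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(n))
  tr
}

## truncated-normal draws by inverse-CDF
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate species traits and breeding ranges
#'
#' Draws migration categories (multinomial), breeding season lengths
#' (truncated normal) and island/mainland status, places breeding ranges
#' as random rectangles clustered around a few hotspot centres on the
#' presence-absence grid (island species get small ranges), and derives
#' range size, sympatric counts and the breeding-season z-score via the
#' sympatry module.
#'
#' @param tree tree from [simulateTree()]; its tips define the species.
#' @param config list from [simulationConfig()].
#' @param seed integer seed.
#' @return list with \code{traits} (predictor table) and \code{grid}
#'   (\linkS4class{RangeGrid}).
#' @export
simulateTraits <- function(tree, config = simulationConfig(), seed = 1) {
  species <- tree$tip.label
  n <- length(species)
  set.seed(seed + 1000L)
  migration <- sample(names(config$migrationProbs), n, replace = TRUE,
                      prob = config$migrationProbs)
  season <- .rtruncnorm(n, config$seasonMean, config$seasonSd,
                        config$seasonRange[1L], config$seasonRange[2L])
  landmass <- ifelse(runif(n) < config$islandProb, "island", "mainland")
  ## grid: lon/lat cell centres, area shrinking with latitude
  lon <- seq_len(config$nLon) - 0.5
  lat <- seq_len(config$nLat) - 0.5 - config$nLat / 2  # centred latitudes
  cells <- expand.grid(lon = lon, lat = lat)
  cells <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(cells))),
                      lon = cells$lon, lat = cells$lat,
                      area_km2 = config$cellAreaKm2 *
                        cos(pi * cells$lat / (2 * config$nLat)))
  hot <- cbind(runif(config$nHotspots, config$nLon * 0.15, config$nLon * 0.85),
               runif(config$nHotspots, -config$nLat * 0.35, config$nLat * 0.35))
  occ <- matrix(0L, nrow(cells), n, dimnames = list(NULL, species))
  for (i in seq_len(n)) {
    ## two-tier placement: a share of species crowd into tight hotspots
    ## (high sympatry), the rest scatter over the whole grid
    ctr <- if (runif(1L) < config$pClustered) {
      hot[sample.int(config$nHotspots, 1L), ] +
        rnorm(2L, 0, config$hotspotSpread)
    } else {
      c(runif(1L, 2, config$nLon - 2),
        runif(1L, -config$nLat / 2 + 2, config$nLat / 2 - 2))
    }
    if (landmass[i] == "island") {
      half <- c(0.6, 0.6)  # <= islandMaxCells cells
    } else {
      half <- rlnorm(2L, log(config$rangeMeanCells / 2), config$rangeSdLog)
    }
    inside <- abs(cells$lon - ctr[1L]) <= half[1L] &
              abs(cells$lat - ctr[2L]) <= half[2L]
    if (!any(inside)) {  # centre fell off-grid: occupy the nearest cell
      d2 <- (cells$lon - ctr[1L])^2 + (cells$lat - ctr[2L])^2
      inside <- seq_len(nrow(cells)) == which.min(d2)
    }
    if (landmass[i] == "island" && sum(inside) > config$islandMaxCells)
      inside <- which(inside)[seq_len(config$islandMaxCells)]
    occ[inside, i] <- 1L
  }
  grid <- rangeGrid(cells, occ)
  traits <- data.frame(species = species, migration = migration,
                       breedingSeasonMonths = season, landmass = landmass)
  traits <- buildTraitTable(traits, grid)
  list(traits = traits, grid = grid)
}

#' Simulate dichromatism counts with known ground truth
#'
#' Draws species effects \eqn{u \sim MVN(0, \sigma^2 C)} on the tree,
#' forms \eqn{p_s = \mathrm{logit}^{-1}(\alpha + x_s^\top\beta + u_s)} and
#' samples counts \eqn{k_s \sim Binomial(5, p_s)}.
#'
#' @param tree the species tree.
#' @param traits predictor table from [simulateTraits()].
#' @param truth list with \code{model}, \code{alpha}, named \code{beta},
#'   \code{sigma}; see [simulationConfig()].
#' @param seed integer seed.
#' @param trials binomial trials (default 5).
#' @return list with \code{scores} (data.frame \code{species}, \code{k},
#'   \code{nPatches}) and \code{truth} (inputs plus realised \code{u} and
#'   \code{p}).
#' @export
simulateDichromatismCounts <- function(tree, traits, truth, seed = 1,
                                       trials = 5) {
  if (truth$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  X <- designMatrix(traits, truth$model)
  beta <- if (ncol(X)) truth$beta[colnames(X)] else numeric(0)
  if (ncol(X) && anyNA(beta))
    stop("truth$beta must be named by the design columns: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  n <- nrow(traits)
  set.seed(seed + 2000L)
  u <- if (truth$sigma > 0) {
    C <- phyloCorrelation(tree, traits$species)
    L <- t(chol(C + diag(1e-10, n)))
    as.numeric(truth$sigma * (L %*% rnorm(n)))
  } else rep(0, n)
  eta <- truth$alpha + (if (ncol(X)) as.numeric(X %*% beta) else 0) + u
  p <- invlogit(eta)
  k <- rbinom(n, trials, p)
  list(scores = data.frame(species = traits$species, k = k,
                           nPatches = trials),
       truth = c(truth, list(u = setNames(u, traits$species),
                             p = setNames(p, traits$species))))
}

## quantum catches of a bare reflectance vector on the vs grid
.quantumCatchVec <- function(r, vs) {
  w <- trapezoidWeights(vs@wavelengths)
  kernel <- cbind(vs@sensitivities, lum = vs@achromaticSensitivity) *
    (vs@illuminant * w)
  q <- as.numeric(crossprod(kernel, r))
  names(q) <- colnames(kernel)
  q
}

#' Calibrate a spectral offset to a target chromatic JND
#'
#' Finds, by 1-D root finding, the amplitude of a Gaussian reflectance bump
#' which, added to the base spectrum (clipped to [0, 1]), yields the
#' requested chromatic contrast against the unmodified base.
#'
#' @param base reflectance vector on the grid of \code{vs}.
#' @param targetJnd requested chromatic JND (>= 0).
#' @param vs a \linkS4class{VisualSystem}.
#' @param bumpCenter,bumpWidth Gaussian bump location and width (nm).
#' @param tol convergence tolerance in JND (default 0.05).
#' @return bump amplitude (0 for target 0); error when the target is not
#'   reachable within reflectance bounds.
#' @export
calibrateSpectralOffset <- function(base, targetJnd, vs, bumpCenter = 550,
                                    bumpWidth = 45, tol = 0.05) {
  if (targetJnd < 0) stop("targetJnd must be >= 0", call. = FALSE)
  if (targetJnd == 0) return(0)
  grid <- vs@wavelengths
  bump <- exp(-((grid - bumpCenter) / bumpWidth)^2)
  q0 <- .quantumCatchVec(base, vs)
  jndAt <- function(a) {
    q1 <- .quantumCatchVec(pmin(pmax(base + a * bump, 0), 1), vs)
    chromaticContrast(q1, q0, vs)
  }
  aMax <- 1.5
  if (jndAt(aMax) < targetJnd)
    stop(sprintf("target of %.2f JND unreachable within reflectance bounds",
                 targetJnd), call. = FALSE)
  root <- uniroot(function(a) jndAt(a) - targetJnd, c(0, aMax),
                  tol = 1e-6)$root
  if (abs(jndAt(root) - targetJnd) > tol)
    stop("offset calibration did not converge", call. = FALSE)
  root
}

## smooth additive noise bump for one specimen
.smoothBump <- function(grid, sdAmp) {
  rnorm(1L, 0, sdAmp) * exp(-((grid - runif(1L, 350, 650)) / 50)^2)
}

#' Simulate reflectance spectra realising intended dichromatism scores
#'
#' Per species: 3 male + 3 female specimens, 5 patches, 3 replicates. A
#' species' \code{k} dichromatic patches (randomly chosen) receive a sex
#' offset calibrated (via [calibrateSpectralOffset()]) to a chromatic JND
#' of \code{threshold + targetJndMargin}; the remaining patches share the
#' same base spectrum between sexes. Specimen- and replicate-level noise is
#' multiplicative (log-normal) plus a small smooth additive bump, so that
#' re-scoring the output recovers the intended counts for the vast
#' majority of species.
#'
#' @param scores data.frame \code{species}, \code{k} from
#'   [simulateDichromatismCounts()].
#' @param config list from [simulationConfig()].
#' @param vs a \linkS4class{VisualSystem} (sets the wavelength grid).
#' @param seed integer seed.
#' @return a \linkS4class{ReflectanceSet} of raw (replicate-level) spectra.
#' @export
simulateSpectra <- function(scores, config = simulationConfig(), vs,
                            seed = 1) {
  if (any(scores$k > length(.PATCHES)))
    stop("k cannot exceed the number of patches", call. = FALSE)
  grid <- vs@wavelengths
  set.seed(seed + 3000L)
  nSpec <- config$nMale + config$nFemale
  nCol <- nrow(scores) * nSpec * length(.PATCHES) * config$nReplicates
  refl <- matrix(NA_real_, length(grid), nCol)
  info <- vector("list", nrow(scores))
  target <- config$threshold + config$targetJndMargin
  col <- 0L
  infoRows <- list()
  for (i in seq_len(nrow(scores))) {
    sp <- scores$species[i]
    dimorphic <- .PATCHES[sample.int(length(.PATCHES), scores$k[i])]
    for (patch in .PATCHES) {
      peak <- config$patchPeaks[[patch]] + rnorm(1L, 0, 12)
      amp <- runif(1L, 0.18, 0.32)
      base <- 0.08 + amp * exp(-((grid - peak) / 70)^2)
      maleOffset <- if (patch %in% dimorphic) {
        ## a bump on top of the base peak is nearly achromatic; place the
        ## sex difference on the opposite flank so the target is reachable
        ctr <- if (peak > 510) runif(1L, 420, 480) else runif(1L, 540, 600)
        a <- calibrateSpectralOffset(base, target, vs, bumpCenter = ctr,
                                     bumpWidth = config$bumpWidth)
        a * exp(-((grid - ctr) / config$bumpWidth)^2)
      } else 0
      for (s in seq_len(nSpec)) {
        sex <- if (s <= config$nMale) "M" else "F"
        specBase <- pmin(pmax(
          (base + if (sex == "M") maleOffset else 0) *
            exp(rnorm(1L, 0, config$specimenNoiseSd)) +
            .smoothBump(grid, config$smoothNoiseSd), 1e-4), 1)
        for (r in seq_len(config$nReplicates)) {
          col <- col + 1L
          refl[, col] <- pmin(pmax(
            specBase * exp(rnorm(1L, 0, config$replicateNoiseSd)), 1e-4), 1)
          infoRows[[col]] <- c(sp, sex, patch,
                               sprintf("s%d", if (sex == "M") s
                                       else s - config$nMale), r)
        }
      }
    }
  }
  info <- as.data.frame(do.call(rbind, infoRows), stringsAsFactors = FALSE)
  colnames(info) <- c("species", "sex", "patch", "specimen", "replicate")
  info$replicate <- as.integer(info$replicate)
  reflectanceSet(grid, refl, info)
}

#' Simulate a complete study bundle
#'
#' Runs every generator stage (tree, traits + ranges, counts with ground
#' truth, and optionally the reflectance spectra realising the counts) from
#' a single seed.
#'
#' @param config list from [simulationConfig()].
#' @param seed integer master seed.
#' @param vs a \linkS4class{VisualSystem}; default the packaged blackbird
#'   system.
#' @param spectra also generate reflectance spectra (slowest stage).
#' @return list with \code{tree}, \code{traits}, \code{grid},
#'   \code{scores}, \code{truth}, and (optionally) \code{spectra}.
#' @export
simulateStudy <- function(config = simulationConfig(), seed = 1,
                          vs = blackbirdVisualSystem(), spectra = TRUE) {
  tree <- simulateTree(config$nSpecies, config$birthRate, seed)
  tg <- simulateTraits(tree, config, seed)
  sim <- simulateDichromatismCounts(tree, tg$traits, config$truth, seed)
  out <- list(tree = tree, traits = tg$traits, grid = tg$grid,
              scores = sim$scores, truth = sim$truth, config = config,
              seed = seed)
  if (spectra)
    out$spectra <- simulateSpectra(sim$scores, config, vs, seed)
  out
}

#' Write a study bundle to disk
#'
#' Emits exactly the formats the pipeline consumes: spectra CSV, trait CSV,
#' grid CSV, Newick tree, scores CSV and a ground-truth JSON.
#'
#' @param bundle list from [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             traits = file.path(dir, "traits.csv"),
             grid = file.path(dir, "grid.csv"),
             scores = file.path(dir, "scores.csv"),
             truth = file.path(dir, "ground_truth.json"))
  ape::write.tree(bundle$tree, paths[["tree"]])
  write.csv(bundle$traits, paths[["traits"]], row.names = FALSE)
  writeRangeGrid(bundle$grid, paths[["grid"]])
  write.csv(bundle$scores, paths[["scores"]], row.names = FALSE)
  jsonlite::write_json(bundle$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(bundle$spectra)) {
    paths <- c(paths, spectra = file.path(dir, "spectra.csv"))
    writeSpectra(bundle$spectra, paths[["spectra"]])
  }
  invisible(paths)
}
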