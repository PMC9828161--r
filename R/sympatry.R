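#' Construct a RangeGrid
#'
#' @param cells data.frame with columns \code{cell_id}, \code{lon},
#'   \code{lat}, \code{area_km2}.
#' @param occupancy 0/1 matrix (cells x species) with species colnames.
#' @return a \linkS4class{RangeGrid}
#' @export
rangeGrid <- function(cells, occupancy) {
  occupancy <- as.matrix(occupancy)
  storage.mode(occupancy) <- "integer"
  new("RangeGrid", cells = as.data.frame(cells), occupancy = occupancy)
}

#' Read a presence-absence grid CSV
#'
#' Columns: \code{cell_id, lon, lat, area_km2, <species...>} with 0/1
#' entries.
#'
#' @param path CSV path
#' @return a \linkS4class{RangeGrid}
#' @export
readRangeGrid <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  meta <- c("cell_id", "lon", "lat", "area_km2")
  if (!all(meta %in% colnames(d)))
    stop("grid CSV must have columns ", paste(meta, collapse = ", "),
         call. = FALSE)
  rangeGrid(d[meta], as.matrix(d[setdiff(colnames(d), meta)]))
}

#' Write a RangeGrid as CSV
#' @param grid a \linkS4class{RangeGrid}
#' @param path output path
#' @export
writeRangeGrid <- function(grid, path) {
  write.csv(cbind(grid@cells, as.data.frame(grid@occupancy)), path,
            row.names = FALSE)
  invisible(path)
}

#' Species occupying a RangeGrid
#' @param grid a \linkS4class{RangeGrid}
#' @export
gridSpecies <- function(grid) colnames(grid@occupancy)

.speciesColumn <- function(grid, species) {
  j <- match(species, colnames(grid@occupancy))
  if (is.na(j)) stop("unknown species: ", species, call. = FALSE)
  grid@occupancy[, j]
}

#' Breeding-range overlap percentage
#'
#' Percentage of the focal species' occupied cells that the other species
#' also occupies: \code{100 * |focal & other| / |focal|}. Asymmetric by
#' construction.
#'
#' @param grid a \linkS4class{RangeGrid}
#' @param focal,other species ids
#' @return overlap percent in \code{[0, 100]}
#' @export
overlapPercent <- function(grid, focal, other) {
  a <- .speciesColumn(grid, focal)
  b <- .speciesColumn(grid, other)
  100 * sum(a & b) / sum(a)
}

#' All pairwise overlap percentages
#'
#' @param grid a \linkS4class{RangeGrid}
#' @return data.frame \code{focal}, \code{other}, \code{overlap} for every
#'   ordered pair of distinct species.
#' @export
overlapTable <- function(grid) {
  occ <- grid@occupancy
  shared <- crossprod(occ)            # species x species shared-cell counts
  sizes <- diag(shared)
  pct <- 100 * sweep(shared, 1L, sizes, "/")
  sp <- colnames(occ)
  idx <- which(row(pct) != col(pct), arr.ind = TRUE)
  data.frame(focal = sp[idx[, 1L]], other = sp[idx[, 2L]],
             overlap = pct[idx])
}

#' Number of sympatric congeners
#'
#' Counts the other species whose breeding-range overlap with the focal
#' species exceeds the threshold (strictly, by default).
#'
#' @param grid a \linkS4class{RangeGrid}
#' @param focal focal species id
#' @param threshold overlap threshold in percent (default 30)
#' @param strict use strict \code{>} (default) or \code{>=}
#' @return integer count
#' @export
sympatricCount <- function(grid, focal, threshold = 30, strict = TRUE) {
  if (threshold < 0 || threshold > 100)
    stop("threshold must be in [0, 100]", call. = FALSE)
  others <- setdiff(gridSpecies(grid), focal)
  ov <- vapply(others, function(o) overlapPercent(grid, focal, o), 0)
  if (strict) sum(ov > threshold) else sum(ov >= threshold)
}

#' Breeding range size from a grid
#'
#' Sum of the areas of the cells the species occupies.
#'
#' @param grid a \linkS4class{RangeGrid}
#' @param species species id
#' @return range size in km^2
#' @export
rangeSize <- function(grid, species) {
  sum(grid@cells$area_km2[.speciesColumn(grid, species) == 1L])
}

#' Classify a migration description
#'
#' Maps free-text handbook descriptions onto the three migration
#' categories: a statement that the species "migrates" is full migration;
#' altitudinal/latitudinal migration or non-breeding-season movement is
#' partial; "resident"/"sedentary" is none. Anything else is an error (no
#' silent default).
#'
#' @param description character vector of descriptions
#' @return character vector with values \code{"none"}, \code{"partial"},
#'   \code{"full"}
#' @export
parseMigration <- function(description) {
  d <- tolower(trimws(description))
  if (any(!nzchar(d))) stop("empty migration description", call. = FALSE)
  partialPhrases <- c("altitudinal migration", "latitudinal migration",
                      "movement during non-breeding season",
                      "movement during non‐breeding season")
  out <- rep(NA_character_, length(d))
  out[vapply(d, function(s) any(vapply(partialPhrases, grepl, TRUE, x = s,
                                       fixed = TRUE)), TRUE)] <- "partial"
  out[is.na(out) & grepl("\\bmigrates\\b", d)] <- "full"
  out[is.na(out) & grepl("resident|sedentary", d)] <- "none"
  if (anyNA(out))
    stop("unclassifiable migration description(s): ",
         paste(unique(description[is.na(out)]), collapse = "; "),
         call. = FALSE)
  out
}

#' Z-score standardisation
#'
#' \code{(x - mu) / sigma}; used to centre and scale breeding season length
#' by the analysis dataset's mean and standard deviation.
#'
#' @param x numeric vector
#' @param mu centre
#' @param sigma scale (> 0)
#' @export
standardize <- function(x, mu, sigma) {
  .assertScalarNumber(sigma, "sigma", positive = TRUE)
  (x - mu) / sigma
}

#' Assemble the species predictor table
#'
#' Joins a raw trait table (species, migration, breeding season length,
#' landmass) with range size and sympatric counts derived from the grid,
#' and adds the z-scored breeding season length.
#'
#' @param traits data.frame with columns \code{species}, \code{migration}
#'   (none/partial/full), \code{breedingSeasonMonths}, \code{landmass}
#'   (mainland/island).
#' @param grid a \linkS4class{RangeGrid} covering all species in
#'   \code{traits}.
#' @param overlapThreshold sympatry overlap threshold (percent).
#' @param strict strict overlap comparison (see [sympatricCount()]).
#' @param mu,sigma centring constants for the breeding-season z-score;
#'   defaults to the dataset's own mean and sd.
#' @return the trait table with added \code{rangeSizeKm2},
#'   \code{nSympatric}, \code{zBreedingSeason} columns.
#' @export
buildTraitTable <- function(traits, grid, overlapThreshold = 30,
                            strict = TRUE,
                            mu = mean(traits$breedingSeasonMonths),
                            sigma = sd(traits$breedingSeasonMonths)) {
  stopifnot(all(traits$migration %in% c("none", "partial", "full")),
            all(traits$landmass %in% c("mainland", "island")))
  miss <- setdiff(traits$species, gridSpecies(grid))
  if (length(miss))
    stop("species missing from grid: ", paste(miss, collapse = ", "),
         call. = FALSE)
  traits$rangeSizeKm2 <- vapply(traits$species, rangeSize, 0, grid = grid)
  traits$nSympatric <- vapply(traits$species, sympatricCount, 0L,
                              grid = grid, threshold = overlapThreshold,
                              strict = strict)
  traits$zBreedingSeason <- standardize(traits$breedingSeasonMonths, mu, sigma)
  traits
}
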