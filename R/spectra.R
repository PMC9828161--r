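#' Construct a ReflectanceSet
#'
#' @param wavelengths numeric wavelength grid in nm, strictly increasing.
#' @param reflectance matrix (length(wavelengths) x n measurements) of
#'   reflectance proportions.
#' @param info data.frame with one row per measurement and columns
#'   \code{species}, \code{sex}, \code{patch}, \code{specimen},
#'   \code{replicate}.
#' @return a \linkS4class{ReflectanceSet}
#' @export
reflectanceSet <- function(wavelengths, reflectance, info) {
  reflectance <- as.matrix(reflectance)
  if (nrow(reflectance) != length(wavelengths))
    stop("reflectance must have one row per wavelength")
  if (nrow(info) != ncol(reflectance))
    stop("info must have one row per measurement")
  cd <- S4Vectors::DataFrame(info)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = reflectance),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = cd
  )
  new("ReflectanceSet", se)
}

#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Wavelength grid of a spectral object
#'
#' @param x a \linkS4class{ReflectanceSet} or \linkS4class{VisualSystem}
#' @return numeric vector of wavelengths (nm)
#' @name wavelengths
#' @export
setMethod("wavelengths", "ReflectanceSet", function(x)
  SummarizedExperiment::rowData(x)$wavelength_nm)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "VisualSystem", function(x) x@wavelengths)

#' @rdname reflectance
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' Reflectance matrix (wavelengths x measurements)
#' @param x a \linkS4class{ReflectanceSet}
#' @name reflectance
#' @export
setMethod("reflectance", "ReflectanceSet", function(x)
  SummarizedExperiment::assay(x, "reflectance"))

#' Measurement labels of a ReflectanceSet
#'
#' @param x a \linkS4class{ReflectanceSet}
#' @return a data.frame of species/sex/patch/specimen/replicate labels
#' @export
spectraInfo <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

## parse "species_sex_patch_specimen_replicate" column names
.parseSpectrumName <- function(nm) {
  parts <- strsplit(nm, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 5L
  if (any(bad))
    stop("malformed spectrum column name(s): ",
         paste(nm[bad], collapse = ", "),
         " (expected species_sex_patch_specimen_replicate)", call. = FALSE)
  p <- do.call(rbind, parts)
  sex <- toupper(p[, 2L])
  sex[sex %in% c("MALE")] <- "M"
  sex[sex %in% c("FEMALE")] <- "F"
  if (!all(sex %in% .SEXES))
    stop("sex field must be M/F (or male/female): ",
         paste(unique(p[!sex %in% .SEXES, 2L]), collapse = ", "), call. = FALSE)
  rep <- suppressWarnings(as.integer(sub("^r", "", p[, 5L])))
  if (any(is.na(rep)) || any(rep < 1L))
    stop("replicate field must be a positive integer (e.g. 'r1' or '1')",
         call. = FALSE)
  data.frame(species = p[, 1L], sex = sex, patch = tolower(p[, 3L]),
             specimen = p[, 4L], replicate = rep)
}

#' Read reflectance spectra from a wide CSV
#'
#' Expects a first column \code{wl} (wavelength in nm) and one column per
#' measurement named \code{species_sex_patch_specimen_replicate}
#' (e.g. \code{Tmerula_M_breast_s1_r1}). Alternatively a sidecar metadata
#' CSV with columns \code{column, species, sex, patch, specimen, replicate}
#' may supply the labels for arbitrary column names.
#'
#' @param path path to the wide CSV.
#' @param dialect \code{"proportion"} (default) or \code{"percent"}; percent
#'   values are divided by 100.
#' @param clampNegative if TRUE, small negative raw values (a common
#'   spectrometer artefact) are clamped to 0 with a warning; if FALSE
#'   (default) negative values are an error.
#' @param metadata optional path to the sidecar metadata CSV.
#' @return a \linkS4class{ReflectanceSet} on the measured grid.
#' @export
readSpectra <- function(path, dialect = c("proportion", "percent"),
                        clampNegative = FALSE, metadata = NULL) {
  dialect <- match.arg(dialect)
  raw <- read.csv(path, check.names = FALSE)
  if (colnames(raw)[1L] != "wl")
    stop("first column must be 'wl'", call. = FALSE)
  wl <- as.numeric(raw[[1L]])
  if (any(!is.finite(wl)) || any(diff(wl) <= 0))
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (dialect == "percent") mat <- mat / 100
  if (any(mat < 0)) {
    if (clampNegative) {
      nneg <- sum(mat < 0)
      mat[mat < 0] <- 0
      warning(sprintf("clamped %d negative reflectance value(s) to 0", nneg),
              call. = FALSE)
    } else {
      stop("negative reflectance values found; set clampNegative = TRUE ",
           "to clamp them to 0", call. = FALSE)
    }
  }
  if (is.null(metadata)) {
    info <- .parseSpectrumName(colnames(mat))
  } else {
    md <- read.csv(metadata, stringsAsFactors = FALSE)
    need <- c("column", "species", "sex", "patch", "specimen", "replicate")
    if (!all(need %in% colnames(md)))
      stop("metadata CSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    idx <- match(colnames(mat), md$column)
    if (any(is.na(idx)))
      stop("metadata is missing rows for some spectra columns", call. = FALSE)
    info <- md[idx, c("species", "sex", "patch", "specimen", "replicate")]
    info$replicate <- as.integer(info$replicate)
  }
  reflectanceSet(wl, mat, info)
}

#' Write a ReflectanceSet as a wide CSV
#'
#' Inverse of [readSpectra()]: column names encode the labels.
#' @param x a \linkS4class{ReflectanceSet}
#' @param path output path
#' @export
writeSpectra <- function(x, path) {
  info <- spectraInfo(x)
  nm <- sprintf("%s_%s_%s_%s_r%d", info$species, info$sex, info$patch,
                info$specimen, as.integer(info$replicate))
  out <- data.frame(wl = wavelengths(x), reflectance(x), check.names = FALSE)
  colnames(out) <- c("wl", nm)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Resample spectra onto a new wavelength grid
#'
#' Linear interpolation of every measurement onto \code{grid}. The grid must
#' lie within the measured range (no extrapolation).
#'
#' @param x a \linkS4class{ReflectanceSet}
#' @param grid target wavelengths (nm); default 300-700 nm at 1-nm steps.
#' @return a \linkS4class{ReflectanceSet} on \code{grid}
#' @export
resampleSpectra <- function(x, grid = 300:700) {
  wl <- wavelengths(x)
  grid <- as.numeric(grid)
  if (min(grid) < min(wl) || max(grid) > max(wl))
    stop(sprintf("grid [%g, %g] outside measured range [%g, %g]",
                 min(grid), max(grid), min(wl), max(wl)), call. = FALSE)
  r <- reflectance(x)
  ## shared abscissa: precompute interval index + weight once for all columns
  idx <- findInterval(grid, wl, rightmost.closed = TRUE)
  idx[idx >= length(wl)] <- length(wl) - 1L
  w <- (grid - wl[idx]) / (wl[idx + 1L] - wl[idx])
  out <- r[idx, , drop = FALSE] * (1 - w) + r[idx + 1L, , drop = FALSE] * w
  reflectanceSet(grid, out, spectraInfo(x))
}

#' Average replicate measurements
#'
#' Pointwise arithmetic mean of replicate spectra within each
#' (species, sex, patch, specimen) group; the replicate label becomes NA.
#'
#' @param x a \linkS4class{ReflectanceSet} (all spectra on a shared grid).
#' @param by grouping columns; default specimen-level means.
#' @return a \linkS4class{ReflectanceSet} with one column per group.
#' @export
averageReplicates <- function(x, by = c("species", "sex", "patch", "specimen")) {
  info <- spectraInfo(x)
  key <- interaction(info[by], drop = TRUE, lex.order = TRUE)
  r <- reflectance(x)
  groups <- split(seq_len(ncol(r)), key)
  out <- vapply(groups, function(j) rowMeans(r[, j, drop = FALSE]),
                numeric(nrow(r)))
  first <- vapply(groups, `[`, integer(1L), 1L)
  newInfo <- info[first, , drop = FALSE]
  newInfo$replicate <- NA_integer_
  rownames(newInfo) <- NULL
  reflectanceSet(wavelengths(x), out, newInfo)
}
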