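#' Male-female patch contrasts per species
#'
#' For every species-by-patch combination, computes chromatic and achromatic
#' JNDs between every male and every female specimen-mean spectrum (with 3
#' specimens per sex this gives 9 pairs per patch) and averages them
#' arithmetically per channel.
#'
#' @param x a \linkS4class{ReflectanceSet} of specimen-mean spectra (run
#'   [averageReplicates()] first), resampled to the grid of \code{vs}.
#' @param vs a \linkS4class{VisualSystem}.
#' @return data.frame with columns \code{species}, \code{patch},
#'   \code{meanChromatic}, \code{meanAchromatic}, \code{nPairs}.
#' @export
patchContrasts <- function(x, vs) {
  info <- spectraInfo(x)
  q <- quantumCatches(x, vs)
  groups <- split(seq_len(nrow(info)),
                  list(species = info$species, patch = info$patch),
                  drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    m <- idx[info$sex[idx] == "M"]
    f <- idx[info$sex[idx] == "F"]
    if (length(m) == 0L || length(f) == 0L)
      stop("species ", info$species[idx[1L]], " patch ", info$patch[idx[1L]],
           " is missing one sex", call. = FALSE)
    pairs <- expand.grid(m = m, f = f)
    jnd <- .contrastRows(q[pairs$m, , drop = FALSE],
                         q[pairs$f, , drop = FALSE], vs)
    data.frame(species = info$species[idx[1L]], patch = info$patch[idx[1L]],
               meanChromatic = mean(jnd[, "chromatic"]),
               meanAchromatic = mean(jnd[, "achromatic"]),
               nPairs = nrow(pairs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species, out$patch), , drop = FALSE]
}

#' Score species dichromatism by JND thresholds
#'
#' Counts, per species and channel, how many of the five plumage patches
#' have a mean male-female contrast strictly above each JND threshold. The
#' \code{combined} channel counts a patch as dichromatic when either the
#' chromatic or the achromatic mean exceeds the threshold (union rule;
#' switch to \code{rule = "intersection"} for a sensitivity analysis).
#'
#' @param summaries output of [patchContrasts()]; every species must carry
#'   exactly the five patches (belly, breast, throat, crown, mantle).
#' @param thresholds JND thresholds; default \code{c(1, 2, 3)}.
#' @param rule \code{"union"} (default) or \code{"intersection"} for the
#'   combined channel.
#' @return data.frame with columns \code{species}, \code{channel}
#'   (chromatic/achromatic/combined), \code{threshold}, \code{k},
#'   \code{nPatches}.
#' @export
scoreSpecies <- function(summaries, thresholds = c(1, 2, 3),
                         rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  out <- lapply(split(summaries, summaries$species), function(d) {
    if (nrow(d) != length(.PATCHES) ||
        !setequal(d$patch, .PATCHES) || anyDuplicated(d$patch))
      stop("species ", d$species[1L], ": expected exactly the patches ",
           paste(.PATCHES, collapse = ", "), call. = FALSE)
    rows <- lapply(thresholds, function(t) {
      kc <- sum(d$meanChromatic > t)
      ka <- sum(d$meanAchromatic > t)
      kb <- if (rule == "union")
        sum(d$meanChromatic > t | d$meanAchromatic > t)
      else
        sum(d$meanChromatic > t & d$meanAchromatic > t)
      data.frame(species = d$species[1L],
                 channel = c("chromatic", "achromatic", "combined"),
                 threshold = t, k = c(kc, ka, kb),
                 nPatches = length(.PATCHES))
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Proportion of sexually monomorphic species
#'
#' Fraction of species whose dichromatic-patch count is zero for the given
#' channel and threshold.
#'
#' @param scores output of [scoreSpecies()].
#' @param channel one of \code{"chromatic"}, \code{"achromatic"},
#'   \code{"combined"}.
#' @param threshold JND threshold present in \code{scores}.
#' @return proportion in \code{[0, 1]}.
#' @export
monomorphicProportion <- function(scores, channel = "combined", threshold = 1) {
  sel <- scores$channel == channel & scores$threshold == threshold
  if (!any(sel)) stop("no scores for that channel/threshold", call. = FALSE)
  mean(scores$k[sel] == 0)
}

#' Within-sex interspecific plumage divergence by range-overlap bin
#'
#' For each ordered pair of species sharing the requested sex, computes
#' patch-level cross-species JND means over all specimen pairs, counts
#' patches above each threshold per channel, and attaches the pair's range
#' overlap binned in 10% increments (0, 10, ..., 90; overlaps >= 100 are
#' capped at the 90 bin).
#'
#' @param x specimen-mean spectra (\linkS4class{ReflectanceSet}).
#' @param vs a \linkS4class{VisualSystem}.
#' @param sex \code{"M"} or \code{"F"}.
#' @param overlaps data.frame with columns \code{focal}, \code{other},
#'   \code{overlap} (percent, asymmetric; see [overlapPercent()]). Only the
#'   listed pairs are evaluated.
#' @param thresholds JND thresholds; default \code{c(1, 2, 3)}.
#' @return data.frame with columns \code{sex}, \code{focal}, \code{other},
#'   \code{overlapBin}, \code{channel}, \code{threshold},
#'   \code{nDiscriminable}.
#' @export
interspecificDivergence <- function(x, vs, sex, overlaps,
                                    thresholds = c(1, 2, 3)) {
  stopifnot(sex %in% .SEXES)
  info <- spectraInfo(x)
  keep <- info$sex == sex
  info <- info[keep, , drop = FALSE]
  q <- quantumCatches(x[, keep], vs)
  out <- lapply(seq_len(nrow(overlaps)), function(r) {
    spA <- overlaps$focal[r]; spB <- overlaps$other[r]
    patchMeans <- vapply(.PATCHES, function(p) {
      ia <- which(info$species == spA & info$patch == p)
      ib <- which(info$species == spB & info$patch == p)
      if (length(ia) == 0L || length(ib) == 0L)
        stop("species ", if (length(ia) == 0L) spA else spB,
             " lacks sex ", sex, " patch ", p, call. = FALSE)
      pairs <- expand.grid(a = ia, b = ib)
      jnd <- .contrastRows(q[pairs$a, , drop = FALSE],
                           q[pairs$b, , drop = FALSE], vs)
      colMeans(jnd)
    }, numeric(2L))
    bin <- min(90, 10 * floor(overlaps$overlap[r] / 10))
    rows <- expand.grid(channel = c("chromatic", "achromatic"),
                        threshold = thresholds, stringsAsFactors = FALSE)
    rows$nDiscriminable <- mapply(function(ch, t)
      sum(patchMeans[ch, ] > t), rows$channel, rows$threshold)
    data.frame(sex = sex, focal = spA, other = spB, overlapBin = bin, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
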