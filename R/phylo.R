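#' Phylogenetic correlation matrix from a tree
#'
#' Brownian-motion variance-covariance of the tips (shared root-to-MRCA
#' path lengths, via [ape::vcv]) scaled to unit diagonal, restricted and
#' reordered to the requested species.
#'
#' @param tree an [ape::phylo] tree with branch lengths; tips are species
#'   ids.
#' @param species species to keep (default: all tips, in tip order).
#' @return correlation matrix (species x species), symmetric, PSD, unit
#'   diagonal.
#' @export
phyloCorrelation <- function(tree, species = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(species, tree$tip.label)
  if (length(miss))
    stop("species not in tree: ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(species) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, species)
  V <- ape::vcv(tree)
  if (any(diag(V) <= 0))
    stop("zero-depth tip(s): ",
         paste(rownames(V)[diag(V) <= 0], collapse = ", "), call. = FALSE)
  C <- stats::cov2cor(V)
  C <- C[species, species]
  ## exact symmetry for the Cholesky downstream
  (C + t(C)) / 2
}
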