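## Phylogenies -> unit-diagonal correlation matrices for taxon-level random
## effects. Tree handling is delegated to ape; this module adds taxon-name
## normalization, exclusion reporting, and the correlation scaling used by
## the meta-analytic models.

#' Normalize a taxon name for matching
#'
#' Lower-cases, trims, and collapses underscores/whitespace to single spaces,
#' so `"Brassica_oleracea"` and `" brassica oleracea "` match. No fuzzy or
#' genus-level substitution is attempted.
#'
#' @param x Character vector of taxon names.
#' @return Normalized names.
#' @export
normalize_taxon <- function(x) {
  tolower(gsub("[_[:space:]]+", " ", trimws(x)))
}

#' Read a Newick phylogeny
#'
#' @param path Path to a Newick file.
#' @return An `ape` `phylo` object; tip labels must be unique after
#'   normalization.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  .check_tree(tree)
  tree
}

.check_tree <- function(tree) {
  norm <- normalize_taxon(tree$tip.label)
  if (anyDuplicated(norm))
    stop("tip labels not unique after normalization: ",
         paste(unique(norm[duplicated(norm)])[1:3], collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Prune a phylogeny to a set of taxa
#'
#' Keeps the induced subtree on the requested tips (unary internal nodes
#' collapsed, branch lengths summed). Requested taxa absent from the tree are
#' not an error: they are returned as an exclusion list, mirroring the
#' treatment of species missing from a megatree (such records are excluded
#' from phylogeny-augmented sensitivity fits rather than guessed).
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of requested taxa (matched after
#'   [normalize_taxon()]).
#' @return List with `tree` (the pruned `phylo`) and `excluded` (requested
#'   taxa not present). At least 2 taxa must match.
#' @export
prune_to_taxa <- function(tree, taxa) {
  .check_tree(tree)
  want <- unique(normalize_taxon(taxa))
  have <- normalize_taxon(tree$tip.label)
  hit <- match(want, have)
  excluded <- unique(taxa)[is.na(hit)]
  keep <- tree$tip.label[hit[!is.na(hit)]]
  if (length(keep) < 2L)
    stop("fewer than 2 requested taxa present in the tree")
  ## retain the path from the original root to the kept tips' MRCA as a root
  ## edge, so shared history (and hence the correlation) is measured from the
  ## same root before and after pruning
  pruned <- ape::keep.tip(tree, keep)
  d_orig <- ape::node.depth.edgelength(tree)[match(keep[1], tree$tip.label)]
  d_new <- ape::node.depth.edgelength(pruned)[match(keep[1],
                                                    pruned$tip.label)]
  lost <- max(d_orig - d_new, 0)
  prior <- if (isTRUE(is.finite(tree$root.edge))) tree$root.edge else 0
  if (lost + prior > 0) pruned$root.edge <- lost + prior
  list(tree = pruned, excluded = excluded)
}

#' Brownian-motion correlation matrix from a phylogeny
#'
#' Converts a tree into the phylogenetic variance-covariance matrix
#' (`VCV[i,j]` = shared root-to-MRCA path length) and scales it to unit
#' diagonal: `corr[i,j] = VCV[i,j] / sqrt(depth_i * depth_j)`. On ultrametric
#' trees this is the usual proportion of shared evolutionary history; on
#' non-ultrametric trees the same scaling still yields a valid correlation
#' matrix. Row/column names are the tip labels.
#'
#' @param tree A `phylo` object with nonnegative branch lengths; every tip
#'   must have positive root-to-tip depth.
#' @param corr If `FALSE`, return the raw covariance (shared path lengths)
#'   instead of the unit-diagonal correlation.
#' @return Symmetric positive-semidefinite matrix keyed by tip label.
#' @export
correlation_from_tree <- function(tree, corr = TRUE) {
  .check_tree(tree)
  V <- ape::vcv(tree, corr = FALSE)
  if (isTRUE(is.finite(tree$root.edge) && tree$root.edge > 0))
    V <- V + tree$root.edge          # shared history above the subtree root
  if (any(diag(V) <= 0))
    stop("zero-depth tip(s): ",
         paste(rownames(V)[diag(V) <= 0][1:3], collapse = ", "))
  if (corr) V <- V / sqrt(tcrossprod(diag(V)))
  ## guard against asymmetry from floating-point accumulation
  V <- (V + base::t(V)) / 2
  V
}

#' Validate a phylogenetic correlation matrix
#'
#' Checks the contract assumed by [fit_multilevel()]'s taxon term: symmetric
#' within 1e-12, unit diagonal, eigenvalues >= -1e-10, dimnames present.
#'
#' @param R Matrix to check.
#' @return `R`, invisibly; errors describe the violated property.
#' @export
validate_phylo_correlation <- function(R) {
  if (is.null(rownames(R)) || !identical(rownames(R), colnames(R)))
    stop("correlation matrix must carry identical row and column taxon names")
  if (max(abs(R - base::t(R))) > 1e-12) stop("matrix is not symmetric")
  if (max(abs(diag(R) - 1)) > 1e-12) stop("diagonal must be exactly 1")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("matrix is not positive semidefinite")
  invisible(R)
}
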