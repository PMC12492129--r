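# Tree-derived Brownian covariance and Pagel's lambda transform

#' Brownian-motion covariance matrix of a tree
#'
#' `C[i, j]` is the shared root-to-tip path length of tips i and j (the depth
#' of their most recent common ancestor); the diagonal holds tip depths.
#' Computed by accumulating each edge's length onto all tip pairs descending
#' from it.
#'
#' @param tree An [ape::phylo] tree with non-negative branch lengths.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
tree_to_covariance <- function(tree) {
  if (any(tree$edge.length < 0)) abort("negative branch length")
  n <- length(tree$tip.label)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  tips_below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) tips_below[[i]] <- i
  # postorder: children processed before parents
  ord <- rev(ape::postorder(tree))
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    tips_below[[parent]] <- c(tips_below[[parent]], tips_below[[child]])
  }
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_below[[tree$edge[e, 2]]]
    C[tips, tips] <- C[tips, tips] + tree$edge.length[e]
  }
  C
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal elements by `lambda`, leaving tip variances
#' unchanged: `lambda = 1` is pure Brownian motion, `lambda = 0` a star
#' phylogeny.
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Signal parameter in `[0, 1]` (no extrapolation).
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    abort("lambda must lie in [0, 1]")
  }
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

#' Scale a covariance matrix to unit height
#' @param C Phylogenetic covariance matrix.
#' @return `C / max(diag(C))`.
#' @export
scale_to_unit_height <- function(C) C / max(diag(C))
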