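# Time-calibrated species trees (ape backend) and cherry utilities

#' Read a time-calibrated Newick tree
#'
#' Tip labels must be unique. Trees that are not ultrametric within
#' `1e-6 * height` are accepted with a warning (descriptor tables may come
#' from non-ultrametric sources); duplicate labels are an error.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick_timetree <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tree <- tryCatch(
    ape::read.tree(path),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("Newick parse error: no tree found")
  validate_timetree(tree)
}

validate_timetree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip label(s): ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch length")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (h > 0 && diff(range(depths)) > 1e-6 * h) {
    warn("tree is not ultrametric within 1e-6 of its height")
  }
  tree
}

#' Tree height (maximum root-to-tip path length)
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Numeric height.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Find cherries (sister-tip pairs) of a tree
#'
#' A cherry is an internal node both of whose children are tips.
#'
#' @param tree An [ape::phylo] tree.
#' @return A tibble with columns `tip1`, `tip2` (tip labels).
#' @export
tree_cherries <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rows <- keep(kids, function(k) length(k) == 2 && all(k <= n_tip))
  tibble(
    tip1 = map_chr(rows, function(k) tree$tip.label[k[1]]),
    tip2 = map_chr(rows, function(k) tree$tip.label[k[2]])
  )
}

#' Count sister-species pairs with discordant thermal groups
#'
#' Counts cherries whose two tips are assigned to different thermal groups —
#' the phylogenetic-replication statistic for thermal-group transitions.
#'
#' @param tree An [ape::phylo] tree.
#' @param groups Named character vector or list mapping every tip label to a
#'   thermal group.
#' @return Integer count of discordant cherries.
#' @export
count_discordant_sister_pairs <- function(tree, groups) {
  groups <- unlist(groups)
  missing <- setdiff(tree$tip.label, names(groups))
  if (length(missing) > 0) {
    abort(paste0("tip(s) missing from groups: ", paste(missing, collapse = ", ")))
  }
  ch <- tree_cherries(tree)
  if (nrow(ch) == 0) return(0L)
  sum(groups[ch$tip1] != groups[ch$tip2])
}

#' Induced subtree for a species subset
#'
#' @param tree An [ape::phylo] tree.
#' @param species Tip labels to keep (must all be present).
#' @return The induced subtree.
#' @export
induced_subtree <- function(tree, species) {
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("species not in tree: ", paste(missing, collapse = ", ")))
  }
  ape::keep.tip(tree, species)
}
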