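# Average contact networks per thermal group
#
# Every column of a (group, type) binary contact matrix gets a
# phylogenetically corrected presence probability: trivially 0 or 1 for
# constant columns, otherwise from a threshold-model fit on the group's
# induced subtree. Edges with probability at or above the cutoff form the
# group's average network.

#' Phylogenetically corrected presence probability of one contact column
#'
#' All-zero columns have probability 0 and all-one columns probability 1
#' without any model; mixed columns are fitted with the phylogenetic
#' threshold model on the induced subtree of the proteins in the column
#' (rescaled to unit height) and summarised by [contact_probability()].
#'
#' @param column Named binary vector (names = protein/species ids).
#' @param tree An [ape::phylo] tree containing all the ids.
#' @param control [mcmc_control()] settings for the threshold sampler
#'   (default: threshold family defaults).
#' @return A probability in `[0, 1]`.
#' @export
column_probability <- function(column, tree, control = NULL) {
  if (!all(column %in% c(0, 1))) abort("column must be binary")
  if (all(column == 0)) return(0)
  if (all(column == 1)) return(1)
  if (is.null(names(column))) abort("column must be named by species")
  if (is.null(control)) control <- mcmc_control("threshold")
  df <- tibble(species = names(column), presence = as.numeric(column))
  fit <- fit_threshold(df, "presence", species = "species", tree = tree,
                       phylo = TRUE, control = control)
  contact_probability(fit)
}

#' Build probability-weighted average contact networks
#'
#' Applies [column_probability()] to every column of every (thermal group,
#' contact type) binary matrix and keeps edges whose probability is at least
#' `cutoff` (0.4 by default; 0.7 gives the stricter variant).
#'
#' @param matrices Named list of binary matrices from
#'   [build_contact_matrices()] (names `"<group>.<type>"`; rows named by
#'   protein/species ids; columns named `"<column_i>-<column_j>"`).
#' @param tree An [ape::phylo] tree containing all row ids.
#' @param cutoff Minimum contact probability for an edge (default 0.4).
#' @param control [mcmc_control()] settings for the per-column threshold
#'   fits.
#' @return An object of class `adk_networks`: list with `edges` (tibble:
#'   `group`, `column_i`, `column_j`, `type`, `probability` — the retained
#'   edges), `probabilities` (same shape, all columns, before the cutoff),
#'   and `cutoff`.
#' @export
build_average_network <- function(matrices, tree, cutoff = 0.4, control = NULL) {
  if (is.null(control)) control <- mcmc_control("threshold")
  rows <- imap(matrices, function(m, key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (ncol(m) == 0) return(NULL)
    probs <- map_dbl(seq_len(ncol(m)), function(j) {
      column_probability(setNames(m[, j], rownames(m)), tree, control = control)
    })
    ij <- do.call(rbind, strsplit(colnames(m), "-", fixed = TRUE))
    tibble(
      group = parts[1], type = parts[2],
      column_i = as.integer(ij[, 1]), column_j = as.integer(ij[, 2]),
      probability = probs
    )
  })
  probabilities <- bind_rows(rows) %>%
    arrange(.data$group, .data$type, .data$column_i, .data$column_j)
  edges <- filter(probabilities, .data$probability >= cutoff)
  structure(
    list(edges = edges, probabilities = probabilities, cutoff = cutoff),
    class = "adk_networks"
  )
}

#' @export
print.adk_networks <- function(x, ...) {
  cat(sprintf(
    "<adk_networks> cutoff %.2f: %d edge(s) retained of %d contact columns\n",
    x$cutoff, nrow(x$edges), nrow(x$probabilities)
  ))
  if (nrow(x$edges) > 0) print(count(x$edges, .data$group, .data$type))
  invisible(x)
}

#' Summarise average networks across thermal groups
#'
#' Computes per-(group, type) retained-edge counts, each edge's sharing
#' pattern over the four thermal groups (a 4-character bitmask in the order
#' psychrophile, mesophile, thermophile, hyperthermophile), and the fraction
#' of all observed contact columns falling below the cutoff.
#'
#' @param networks An `adk_networks` object.
#' @return A list: `edge_counts` (tibble by group and type), `sharing`
#'   (tibble: `column_i`, `column_j`, `type`, `mask`, `n_groups`),
#'   `fraction_below_cutoff` (scalar).
#' @export
network_summary <- function(networks) {
  edges <- networks$edges
  edge_counts <- count(edges, .data$group, .data$type, name = "n_edges")
  sharing <- edges %>%
    group_by(.data$column_i, .data$column_j, .data$type) %>%
    summarise(
      mask = paste(as.integer(THERMAL_GROUPS %in% .data$group), collapse = ""),
      n_groups = dplyr::n_distinct(.data$group),
      .groups = "drop"
    )
  frac_below <- if (nrow(networks$probabilities) == 0) NA_real_ else {
    mean(networks$probabilities$probability < networks$cutoff)
  }
  list(
    edge_counts = edge_counts,
    sharing = sharing,
    fraction_below_cutoff = frac_below
  )
}

#' Plot an average contact network
#'
#' Nodes are alignment columns on a deterministic circular layout ordered by
#' column index (no claim is made about structural positions); edge width is
#' proportional to contact probability.
#'
#' @param object An `adk_networks` object.
#' @param ... Unused.
#' @return A ggplot faceted by thermal group.
#' @export
autoplot.adk_networks <- function(object, ...) {
  edges <- object$edges
  if (nrow(edges) == 0) abort("no edges to plot")
  cols <- sort(unique(c(edges$column_i, edges$column_j)))
  theta <- setNames(2 * pi * (match(cols, cols) - 1) / length(cols), cols)
  edges <- edges %>%
    mutate(
      x = cos(theta[as.character(.data$column_i)]),
      y = sin(theta[as.character(.data$column_i)]),
      xend = cos(theta[as.character(.data$column_j)]),
      yend = sin(theta[as.character(.data$column_j)])
    )
  ggplot2::ggplot(edges) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$type,
                   linewidth = .data$probability),
      alpha = 0.8
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), limits = c(0, 1)) +
    ggplot2::facet_wrap(~group) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "contact type", linewidth = "probability")
}
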