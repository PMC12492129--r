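# Phylogenetic PCA with simultaneous maximum-likelihood estimation of
# Pagel's lambda.
#
# Model: trait matrix X (species x traits) is multivariate Brownian on the
# tree with signal lambda, i.e. vec(X) ~ N(1 kron a, R kron C(lambda)).
# The GLS phylogenetic mean and the evolutionary covariance R are profiled
# out, leaving a 1-D likelihood in lambda maximised on [0, 1]. Components
# come from the eigendecomposition of R; scores project the mean-centred
# data onto the loadings.

ppca_profile_loglik <- function(lambda, X, C) {
  n <- nrow(X); p <- ncol(X)
  Cl <- lambda_transform(C, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Ci <- chol2inv(ch)
  one <- rep(1, n)
  denom <- sum(Ci)
  a <- crossprod(one, Ci %*% X) / denom          # 1 x p GLS mean
  Xc <- X - one %*% a
  S <- crossprod(Xc, Ci %*% Xc)                  # p x p scatter
  R_ml <- S / n
  logdetC <- 2 * sum(log(diag(ch)))
  logdetR <- determinant(R_ml, logarithm = TRUE)$modulus
  if (!is.finite(logdetR)) return(-Inf)
  # profile multivariate normal log-likelihood (trace term collapses to n p)
  -0.5 * (n * p * log(2 * pi) + n * logdetR + p * logdetC + n * p)
}

#' Phylogenetic principal component analysis
#'
#' Estimates Pagel's lambda by maximising the multivariate Brownian profile
#' likelihood on `[0, 1]`, computes the GLS phylogenetic mean, the
#' evolutionary covariance `R = (X - 1a)' C(lambda)^-1 (X - 1a) / (n - 1)`,
#' and returns components of `R` with species scores.
#'
#' @param data A data frame with one row per species: a species-id column
#'   plus numeric trait columns.
#' @param tree An [ape::phylo] tree containing every species as a tip.
#' @param species Name of the species-id column (default `"species"`).
#' @param traits Trait column names (default: all numeric columns).
#' @param mode `"standardized"` (default) z-scores each trait first — the
#'   descriptors have incommensurate units — or `"raw"` to analyse the raw
#'   covariance.
#' @param lambda Fix lambda instead of estimating it (optional).
#' @return An object of class `adk_ppca`: list with `lambda`, `loglik`,
#'   `loadings`, `eigenvalues`, `scores` (tibble with species ids),
#'   `phylo_mean`, `evol_cov`, `mode`, `traits`.
#' @export
phylo_pca <- function(data, tree, species = "species", traits = NULL,
                      mode = c("standardized", "raw"), lambda = NULL) {
  mode <- match.arg(mode)
  stopifnot(species %in% names(data))
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
    traits <- setdiff(traits, species)
  }
  if (length(traits) < 2) abort("phylogenetic PCA needs at least 2 traits")
  X <- as.matrix(data[, traits, drop = FALSE])
  if (any(!is.finite(X))) abort("non-finite trait values")
  sp <- as.character(data[[species]])
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("species not in tree: ", paste(missing, collapse = ", ")))
  }
  tree <- induced_subtree(tree, sp)
  C <- tree_to_covariance(tree)[sp, sp]
  if (mode == "standardized") {
    X <- scale(X)
    if (any(!is.finite(X))) abort("a trait has zero variance; cannot standardize")
  }
  if (is.null(lambda)) {
    opt <- optimize(ppca_profile_loglik, c(0, 1), X = X, C = C,
                    maximum = TRUE, tol = 1e-6)
    # guard the interior optimum against the boundary values
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective,
            ppca_profile_loglik(0, X, C), ppca_profile_loglik(1, X, C))
    lambda_hat <- cand[which.max(ll)]
    loglik <- max(ll)
  } else {
    lambda_hat <- lambda
    loglik <- ppca_profile_loglik(lambda, X, C)
  }
  n <- nrow(X)
  Cl <- lambda_transform(C, lambda_hat)
  ch <- tryCatch(chol(Cl), error = function(e) {
    abort("C(lambda) is singular; consider jittering branch lengths")
  })
  Ci <- chol2inv(ch)
  one <- rep(1, n)
  a <- drop(crossprod(one, Ci %*% X) / sum(Ci))
  Xc <- X - one %*% t(a)
  R <- crossprod(Xc, Ci %*% Xc) / (n - 1)
  eig <- eigen(R, symmetric = TRUE)
  loadings <- eig$vectors
  dimnames(loadings) <- list(traits, paste0("PC", seq_len(ncol(loadings))))
  scores <- Xc %*% loadings
  scores_tbl <- as_tibble(scores)
  names(scores_tbl) <- colnames(loadings)
  scores_tbl <- dplyr::bind_cols(tibble(!!species := sp), scores_tbl)
  structure(
    list(
      lambda = lambda_hat, loglik = loglik,
      loadings = loadings, eigenvalues = eig$values,
      scores = scores_tbl, phylo_mean = setNames(a, traits),
      evol_cov = R, mode = mode, traits = traits, species_col = species
    ),
    class = "adk_ppca"
  )
}

#' @export
print.adk_ppca <- function(x, ...) {
  cat(sprintf(
    "<adk_ppca> %d species x %d traits (%s mode)\n  lambda = %.4f, logLik = %.2f\n",
    nrow(x$scores), length(x$traits), x$mode, x$lambda, x$loglik
  ))
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat("  variance explained:", paste0(sprintf("PC%d %.1f%%", seq_along(pct), pct), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname phylo_pca
#' @param x An `adk_ppca` object.
#' @param ... Unused.
#' @export
tidy.adk_ppca <- function(x, ...) {
  as_tibble(x$loadings, rownames = "trait") %>%
    tidyr::pivot_longer(-"trait", names_to = "component", values_to = "loading")
}

#' @rdname phylo_pca
#' @export
glance.adk_ppca <- function(x, ...) {
  tibble(
    lambda = x$lambda, loglik = x$loglik,
    n_species = nrow(x$scores), n_traits = length(x$traits),
    prop_var_pc1 = x$eigenvalues[1] / sum(x$eigenvalues)
  )
}

#' @rdname phylo_pca
#' @param object An `adk_ppca` object.
#' @param colour_by Optional vector (length = species) to colour points by,
#'   e.g. thermal group.
#' @export
autoplot.adk_ppca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  pct <- 100 * object$eigenvalues / sum(object$eigenvalues)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour_by)) {
    df$.colour <- colour_by
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$.colour)) +
      ggplot2::labs(colour = NULL)
  }
  p +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("pPC1 (%.1f%%)", pct[1]),
      y = sprintf("pPC2 (%.1f%%)", pct[2])
    ) +
    ggplot2::theme_minimal()
}
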