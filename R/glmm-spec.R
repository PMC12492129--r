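# Model specification and enumeration for the phylogenetic mixed models

GLMM_FAMILIES <- c("gaussian_mev", "poisson", "threshold")

#' MCMC control settings
#'
#' Defaults mirror the chain lengths the three model families need for
#' convergence at full scale: Gaussian meta-analytic 1e6 generations / 1e5
#' burn-in / thin 100; Poisson 5e7 / 5e6 / 15000; threshold 5e5 / 5e4 / 50.
#' The `scale` knob multiplies generation counts (and burn-in) while keeping
#' the retained-sample count of order 1e3-1e4, so exploratory and test runs
#' can use `scale` well below 1.
#'
#' @param family Model family.
#' @param n_iter,burn_in,thin Override the family defaults directly.
#' @param n_chains Number of independent chains (default 3).
#' @param seed Master seed; chain `c` uses `seed + c`.
#' @param scale Multiplier applied to the family-default `n_iter` and
#'   `burn_in` (thin is rescaled to keep the retained count).
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(family = c("gaussian_mev", "poisson", "threshold"),
                         n_iter = NULL, burn_in = NULL, thin = NULL,
                         n_chains = 3, seed = 1, scale = 1) {
  family <- match.arg(family)
  defaults <- list(
    gaussian_mev = c(1e6, 1e5, 100),
    poisson      = c(5e7, 5e6, 15000),
    threshold    = c(5e5, 5e4, 50)
  )[[family]]
  if (is.null(n_iter)) n_iter <- max(200, round(defaults[1] * scale))
  if (is.null(burn_in)) burn_in <- max(50, round(defaults[2] * scale))
  if (is.null(thin)) thin <- max(1, round(defaults[3] * scale))
  if (burn_in >= n_iter) abort("burn_in must be smaller than n_iter")
  structure(
    list(family = family, n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         n_chains = as.integer(n_chains), seed = as.integer(seed)),
    class = "mcmc_control"
  )
}

#' Enumerate candidate model specifications
#'
#' All subsets of the candidate fixed effects (always including the
#' intercept-only model), each with and without a phylogenetic random effect
#' on the intercept: `2^k * 2` specifications for `k` candidates.
#'
#' @param candidates Character vector of candidate fixed-effect column names
#'   (may be empty).
#' @param allow_phylo Include the phylogenetic variants (default `TRUE`).
#' @return A tibble with list-column `fixed` (character vectors) and logical
#'   `phylo`; one row per specification.
#' @export
enumerate_models <- function(candidates = character(), allow_phylo = TRUE) {
  k <- length(candidates)
  subsets <- map(0:k, function(size) {
    if (size == 0) return(list(character()))
    combn(candidates, size, simplify = FALSE)
  })
  subsets <- unlist(subsets, recursive = FALSE)
  phylo_opts <- if (allow_phylo) c(FALSE, TRUE) else FALSE
  grid <- tidyr::expand_grid(i = seq_along(subsets), phylo = phylo_opts)
  tibble(
    model_id = seq_len(nrow(grid)),
    fixed = subsets[grid$i],
    phylo = grid$phylo
  )
}

# Build the design matrix from named data columns: numeric columns enter
# as-is, character/factor columns are dummy-coded (treatment contrasts).
build_design <- function(data, fixed) {
  n <- nrow(data)
  if (length(fixed) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  missing <- setdiff(fixed, names(data))
  if (length(missing) > 0) {
    abort(paste0("fixed effect column(s) not in data: ", paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(data[, fixed, drop = FALSE])
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  X <- stats::model.matrix(~ ., data = df)
  zero_col <- apply(X[, -1, drop = FALSE], 2, function(v) all(v == 0))
  if (any(zero_col)) {
    abort(paste0("all-zero design column(s): ",
                 paste(names(zero_col)[zero_col], collapse = ", ")))
  }
  X
}
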