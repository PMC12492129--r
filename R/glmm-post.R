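# Post-processing of fitted models: DIC, R2, HPD summaries, convergence
# diagnostics, contact probability, and the HPD+DIC model-selection rule.

fit_par_names <- function(fit) {
  setdiff(colnames(fit$samples), "deviance")
}

#' @export
print.adk_fit <- function(x, ...) {
  cat(sprintf(
    "<adk_fit> %s model of '%s'%s%s\n  %d chains x %d retained samples\n",
    x$family, x$response,
    if (length(x$fixed) > 0) paste0(" ~ ", paste(x$fixed, collapse = " + ")) else " (intercept-only)",
    if (x$phylo) " + phylo" else "", x$control$n_chains, nrow(x$chains[[1]])
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy posterior summary of a fitted model
#'
#' One row per model parameter with posterior mean, standard deviation, 95%
#' HPD bounds, effective sample size (summed over chains) and PSRF.
#'
#' @param x An `adk_fit` object.
#' @param mass HPD mass (default 0.95).
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `hpd.lower`,
#'   `hpd.upper`, `ess`, `psrf`.
#' @export
tidy.adk_fit <- function(x, mass = 0.95, ...) {
  pars <- fit_par_names(x)
  rows <- map(pars, function(pn) {
    pooled <- x$samples[, pn]
    h <- if (length(pooled) >= 100) hpd_interval(pooled, mass) else c(NA_real_, NA_real_)
    chains <- lapply(x$chains, function(m) m[, pn])
    tibble(
      term = pn,
      estimate = mean(pooled),
      std.error = sd(pooled),
      hpd.lower = h[1], hpd.upper = h[2],
      ess = sum(map_dbl(chains, function(ch) if (length(ch) >= 4) ess(ch) else NA_real_)),
      psrf = if (length(chains) >= 2) psrf(chains) else NA_real_
    )
  })
  bind_rows(rows)
}

#' One-row summary of a fitted model
#'
#' @param x An `adk_fit` object.
#' @param ... Unused.
#' @return A tibble with `family`, `response`, `n_fixed`, `phylo`, `dic`,
#'   `r2_marginal`, `r2_conditional`, `min_ess`, `max_psrf`, `converged`
#'   (at the default thresholds ESS >= 1000, PSRF < 1.1).
#' @export
glance.adk_fit <- function(x, ...) {
  td <- tidy(x)
  r2 <- r2_nakagawa(x)
  tibble(
    family = x$family, response = x$response,
    n_fixed = length(x$fixed), phylo = x$phylo,
    dic = dic(x),
    r2_marginal = r2$r2_marginal, r2_conditional = r2$r2_conditional,
    min_ess = min(td$ess, na.rm = TRUE),
    max_psrf = max(td$psrf, na.rm = TRUE),
    converged = min(td$ess, na.rm = TRUE) >= 1000 & max(td$psrf, na.rm = TRUE) < 1.1
  )
}

#' Deviance information criterion of a fit
#'
#' `DIC = 2 * mean(D(theta_s)) - D(mean theta)`, with the deviance of the
#' non-Gaussian families evaluated conditionally on the latent effects (the
#' convention of the phylogenetic-MCMC tradition this pipeline follows).
#'
#' @param fit An `adk_fit` object.
#' @return The DIC value.
#' @export
dic <- function(fit) {
  if (is.na(fit$d_bar)) abort("DIC undefined for a prior-only fit")
  2 * fit$d_bar - fit$d_hat
}

#' Marginal and conditional R-squared (Nakagawa-Schielzeth)
#'
#' `R2_marginal` is the variance captured by the fixed effects,
#' `R2_conditional` that captured by fixed plus random effects:
#' `sigma2_fixed` is the variance of `X beta_hat` over the observations, and
#' the denominator adds the phylogenetic and residual variances. For the
#' Poisson family a lognormal observation-level variance
#' `log(1 + 1/lambda_bar)` is added to the denominator. Measurement-error
#' variances (`se^2`) are excluded from the denominator by default.
#'
#' @param fit An `adk_fit` object.
#' @param include_mev Add the mean `se^2` to the denominator (default
#'   `FALSE`).
#' @return A tibble with `r2_marginal` and `r2_conditional`.
#' @export
r2_nakagawa <- function(fit, include_mev = FALSE) {
  beta_hat <- colMeans(fit$samples[, colnames(fit$X), drop = FALSE])
  s2_f <- if (nrow(fit$X) > 1) var(drop(fit$X %*% beta_hat)) else 0
  s2_p <- if (fit$phylo) mean(fit$samples[, "sigma2_phylo"]) else 0
  s2_e <- if (fit$family == "threshold") 1 else mean(fit$samples[, "sigma2_e"])
  s2_d <- 0
  if (fit$family == "poisson") {
    lambda_bar <- exp(mean(fit$latent_mean))
    s2_d <- log(1 + 1 / lambda_bar)
  }
  s2_mev <- if (include_mev) mean(fit$se2) else 0
  denom <- s2_f + s2_p + s2_e + s2_d + s2_mev
  tibble(
    r2_marginal = s2_f / denom,
    r2_conditional = (s2_f + s2_p) / denom
  )
}

#' Posterior contact probability from a threshold-model fit
#'
#' The intercept is the phylogenetically corrected liability, so the contact
#' probability is the fraction of pooled post-burn-in intercept samples that
#' are at least 0.
#'
#' @param fit An `adk_fit` from [fit_threshold()].
#' @return A probability in `[0, 1]`.
#' @export
contact_probability <- function(fit) {
  if (fit$family != "threshold") abort("contact_probability needs a threshold fit")
  mean(fit$samples[, "(Intercept)"] >= 0)
}

#' Select the best model by the HPD-then-DIC rule
#'
#' Fits failing the convergence thresholds are rejected first. Among the
#' converged fits, any model with a non-intercept fixed-effect coefficient
#' whose 95% HPD interval includes zero is excluded; the survivor with the
#' lowest DIC wins. If no model survives the HPD filter, the intercept-only
#' models compete by DIC as a documented fallback.
#'
#' @param fits List of `adk_fit` objects.
#' @param ess_min Minimum per-parameter ESS (summed over chains) a fit must
#'   reach (default 1000).
#' @param psrf_max Maximum per-parameter PSRF (default 1.1).
#' @return A list: `best` (the winning `adk_fit`), `table` (a tibble ranking
#'   all fits: `model`, `fixed`, `phylo`, `converged`, `hpd_pass`, `dic`,
#'   `selected`).
#' @export
select_model <- function(fits, ess_min = 1000, psrf_max = 1.1) {
  if (length(fits) == 0) abort("no fits supplied")
  info <- map(seq_along(fits), function(i) {
    fit <- fits[[i]]
    td <- tidy(fit)
    conv <- min(td$ess, na.rm = TRUE) >= ess_min && max(td$psrf, na.rm = TRUE) < psrf_max
    slopes <- td[!(td$term %in% c("(Intercept)", "sigma2_phylo", "sigma2_e")), ]
    hpd_pass <- nrow(slopes) == 0 ||
      all(slopes$hpd.lower > 0 | slopes$hpd.upper < 0)
    tibble(
      model = i,
      fixed = paste(fit$fixed, collapse = "+"),
      phylo = fit$phylo,
      n_fixed = length(fit$fixed),
      converged = conv,
      hpd_pass = hpd_pass,
      dic = dic(fit)
    )
  }) %>% bind_rows()
  candidates <- filter(info, .data$converged, .data$hpd_pass)
  if (nrow(candidates) == 0) {
    candidates <- filter(info, .data$converged, .data$n_fixed == 0)
  }
  if (nrow(candidates) == 0) {
    abort("no converged candidate models; increase chain length or inspect diagnostics")
  }
  best_row <- candidates$model[which.min(candidates$dic)]
  info$selected <- info$model == best_row
  list(best = fits[[best_row]], table = info)
}

#' Trace/density plot of a fitted model's parameters
#'
#' @param object An `adk_fit` object.
#' @param pars Parameters to show (default: all but the deviance).
#' @param ... Unused.
#' @return A ggplot faceted by parameter with one trace per chain.
#' @export
autoplot.adk_fit <- function(object, pars = NULL, ...) {
  if (is.null(pars)) pars <- fit_par_names(object)
  df <- map(seq_along(object$chains), function(cid) {
    m <- object$chains[[cid]][, pars, drop = FALSE]
    as_tibble(m) %>%
      mutate(iteration = dplyr::row_number(), chain = factor(cid))
  }) %>%
    bind_rows() %>%
    tidyr::pivot_longer(all_of(pars), names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "retained sample", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}
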