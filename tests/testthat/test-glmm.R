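small_ctl <- function(family, seed = 1, n_iter = 2000, burn_in = 600,
                      thin = 1, n_chains = 2) {
  mcmc_control(family, n_iter = n_iter, burn_in = burn_in, thin = thin,
               n_chains = n_chains, seed = seed)
}

test_that("model enumeration covers all subsets times the phylo toggle", {
  expect_equal(nrow(enumerate_models(c("a", "b", "c", "d"))), 32)
  expect_equal(nrow(enumerate_models(c("a", "b", "c"))), 16)
  specs0 <- enumerate_models(character())
  expect_equal(nrow(specs0), 2)
  expect_equal(lengths(specs0$fixed), c(0, 0))
  expect_setequal(specs0$phylo, c(TRUE, FALSE))
  # every subset appears exactly once per phylo setting
  specs <- enumerate_models(c("a", "b"))
  keys <- paste(purrr::map_chr(specs$fixed, paste, collapse = "+"), specs$phylo)
  expect_equal(anyDuplicated(keys), 0)
})

test_that("HPD intervals match analytic widths", {
  expect_equal(unname(hpd_interval(rep(3.3, 200))), c(3.3, 3.3))
  set.seed(1)
  u <- runif(1e5)
  hu <- hpd_interval(u)
  expect_equal(unname(hu[2] - hu[1]), 0.95, tolerance = 0.011)
  z <- rnorm(1e5)
  hz <- hpd_interval(z)
  expect_equal(unname(hz[1]), -1.96, tolerance = 0.03)
  expect_equal(unname(hz[2]), 1.96, tolerance = 0.03)
  expect_error(hpd_interval(rnorm(50)), "100 samples")
})

test_that("effective sample size tracks the autocorrelation structure", {
  set.seed(2)
  iid <- rnorm(5000)
  expect_gte(ess(iid), 4000)
  expect_lte(ess(iid), 6000)

  rho <- 0.9
  n <- 20000
  ar <- as.vector(arima.sim(list(ar = rho), n))
  want <- n * (1 - rho) / (1 + rho)
  expect_equal(ess(ar), want, tolerance = 0.3)
  # independent oracle on the same chain
  expect_equal(ess(ar), unname(coda::effectiveSize(coda::mcmc(ar))),
               tolerance = 0.25)
})

test_that("PSRF is 1 for identical chains and flags split chains", {
  set.seed(3)
  x <- rnorm(2000)
  expect_equal(psrf(list(x, x, x)), 1, tolerance = 0.01)
  expect_gt(psrf(list(x, x + 3)), 1.5)
  expect_error(psrf(list(x)), "2 chains")
  expect_error(psrf(list(x, x[1:10])), "equal length")
})

test_that("the Gaussian sampler matches least squares when priors vanish", {
  set.seed(4)
  n <- 80
  x <- runif(n, -2, 2)
  y <- 1.5 + 0.8 * x + rnorm(n, 0, 0.3)
  dat <- tibble::tibble(species = paste0("s", 1:n), y = y, x = x, se = 0)
  fit <- fit_gaussian_mev(dat, "y", se = "se", fixed = "x", phylo = FALSE,
                          control = small_ctl("gaussian_mev", 4, n_iter = 4000, burn_in = 1000))
  ls <- coef(lm(y ~ x))
  td <- tidy(fit)
  for (k in 1:2) {
    mc_se <- td$std.error[k] / sqrt(td$ess[k])
    expect_lt(abs(td$estimate[k] - ls[k]), 3 * mc_se + 0.01 * abs(ls[k]) + 1e-4)
  }
})

test_that("measurement-error variances widen the Gaussian posterior", {
  set.seed(14)
  n <- 60
  x <- runif(n, -2, 2)
  y <- 0.5 + 0.3 * x + rnorm(n, 0, 0.2)
  base <- tibble::tibble(species = paste0("s", 1:n), y = y, x = x, se = 0)
  noisy <- dplyr::mutate(base, se = 0.6)
  f0 <- fit_gaussian_mev(base, "y", se = "se", fixed = "x", phylo = FALSE,
                         control = small_ctl("gaussian_mev", 5))
  f1 <- fit_gaussian_mev(noisy, "y", se = "se", fixed = "x", phylo = FALSE,
                         control = small_ctl("gaussian_mev", 5))
  expect_gt(tidy(f1)$std.error[2], tidy(f0)$std.error[2])
})

test_that("degenerate constant data collapse onto the intercept", {
  dat <- tibble::tibble(species = paste0("s", 1:30), y = 2.5, se = 0)
  fit <- fit_gaussian_mev(dat, "y", se = "se", phylo = FALSE,
                          control = small_ctl("gaussian_mev", 6))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "(Intercept)"], 2.5, tolerance = 1e-3)
  expect_lt(mean(fit$samples[, "sigma2_e"]), 1e-3)
})

test_that("the Poisson sampler honours the lognormal mean identity", {
  dat <- tibble::tibble(species = paste0("s", 1:150), y = 7L)
  fit <- fit_poisson(dat, "y", phylo = FALSE,
                     control = small_ctl("poisson", 7, n_iter = 6000, burn_in = 2000))
  b0 <- mean(fit$samples[, "(Intercept)"])
  s2 <- mean(fit$samples[, "sigma2_e"])
  expect_equal(exp(b0 + s2 / 2), 7, tolerance = 0.1)
  expect_error(fit_poisson(dplyr::mutate(dat, y = -1L), "y"), "non-negative")
})

test_that("all-zero counts drive the Poisson intercept to large negatives", {
  dat <- tibble::tibble(species = paste0("s", 1:40), y = 0L)
  fit <- fit_poisson(dat, "y", phylo = FALSE,
                     control = small_ctl("poisson", 8))
  expect_lt(mean(fit$samples[, "(Intercept)"]), -1)
  expect_true(all(is.finite(fit$samples[, "(Intercept)"])))
})

test_that("a balanced threshold response centres the liability at zero", {
  star <- ape::stree(40, "star")
  star$edge.length <- rep(1, 40)
  star$tip.label <- paste0("s", 1:40)
  dat <- tibble::tibble(species = star$tip.label, y = rep(c(0, 1), 20))
  fit <- fit_threshold(dat, "y", tree = star,
                       control = small_ctl("threshold", 9, n_iter = 4000, burn_in = 1000))
  h <- hpd_interval(fit$samples[, "(Intercept)"])
  expect_lt(h[1], 0)
  expect_gt(h[2], 0)
  expect_error(fit_threshold(dplyr::mutate(dat, y = 1), "y", tree = star),
               "constant response")
  expect_error(fit_threshold(dplyr::mutate(dat, y = y * 2), "y", tree = star),
               "0/1")
})

test_that("a clade-confined trait pulls phylogenetic variance off zero", {
  tr <- simulate_tree(40, 19)
  C <- tree_to_covariance(tr)
  # presence = one deep clade: pick the larger side of the root split
  clade <- rownames(C)[C[, 1] > 0.3][1:12]
  clade <- clade[!is.na(clade)]
  dat <- tibble::tibble(species = tr$tip.label,
                        y = as.numeric(tr$tip.label %in% clade))
  fit <- fit_threshold(dat, "y", tree = tr,
                       control = small_ctl("threshold", 10, n_iter = 4000, burn_in = 1000))
  expect_gt(stats::quantile(fit$samples[, "sigma2_phylo"], 0.25), 0.1)
})

test_that("contact probability is the positive fraction of intercepts", {
  mk <- function(vals) {
    m <- matrix(vals, ncol = 1, dimnames = list(NULL, "(Intercept)"))
    fake_fit(m, family = "threshold", phylo = FALSE)
  }
  expect_equal(contact_probability(mk(c(-1, 1, 0, 2))), 0.75)
  expect_equal(contact_probability(mk(c(0.2, 3, 0.1))), 1)
  expect_error(contact_probability(fake_fit(
    matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)")))), "threshold")
})

test_that("probabilities of a column and its complement sum to one", {
  star <- ape::stree(30, "star")
  star$edge.length <- rep(1, 30)
  star$tip.label <- paste0("s", 1:30)
  col <- setNames(rep(c(0, 1), 15), star$tip.label)
  ctl <- small_ctl("threshold", 11, n_iter = 4000, burn_in = 1000)
  p <- column_probability(col, star, control = ctl)
  q <- column_probability(1 - col, star, control = ctl)
  expect_equal(p + q, 1, tolerance = 0.1)
})

test_that("DIC reduces to the common deviance when deviance is constant", {
  m <- cbind("(Intercept)" = rnorm(300), deviance = 123.4)
  f <- fake_fit(m, phylo = FALSE, d_bar = 123.4, d_hat = 123.4)
  expect_equal(dic(f), 123.4)
})

test_that("DIC matches a closed-form conjugate-posterior computation", {
  # known-variance normal, flat-prior limit: posterior mu ~ N(ybar, s2/n)
  set.seed(12)
  s2 <- 0.49
  n <- 40
  y <- rnorm(n, 2, sqrt(s2))
  dat <- tibble::tibble(species = paste0("s", 1:n), y = y, se = 0)
  fit <- fit_gaussian_mev(dat, "y", se = "se", phylo = FALSE,
                          control = small_ctl("gaussian_mev", 12, n_iter = 20000, burn_in = 4000, thin = 4))
  # exact normal-inverse-gamma posterior (flat-prior limit on the mean):
  # sigma2 | y ~ IG(a + (n-1)/2, b + S/2), mu | sigma2, y ~ N(ybar, sigma2/n)
  S <- sum((y - mean(y))^2)
  n_draw <- 2e5
  s2s <- 1 / rgamma(n_draw, 0.001 + (n - 1) / 2, rate = 0.001 + S / 2)
  mus <- rnorm(n_draw, mean(y), sqrt(s2s / n))
  dev <- vapply(seq(1, n_draw, by = 20), function(i) {
    -2 * sum(dnorm(y, mus[i], sqrt(s2s[i]), log = TRUE))
  }, numeric(1))
  d_bar_cf <- mean(dev)
  d_hat_cf <- -2 * sum(dnorm(y, mean(mus), sqrt(mean(s2s)), log = TRUE))
  expect_equal(dic(fit), 2 * d_bar_cf - d_hat_cf, tolerance = 0.02)
})

test_that("R-squared follows the variance decomposition arithmetic", {
  # constructed decomposition: s2_f = 6.4, s2_p = 2.0, s2_e = 1.6
  n <- 1000
  x <- seq(-1, 1, length.out = n) * sqrt(6.4) / sd(seq(-1, 1, length.out = n))
  X <- cbind("(Intercept)" = 1, x = x)
  m <- cbind("(Intercept)" = rep(0, 200), x = 1, sigma2_phylo = 2.0,
             sigma2_e = 1.6, deviance = 0)
  f <- fake_fit(m, X = X)
  r2 <- r2_nakagawa(f)
  expect_equal(r2$r2_marginal, 0.64, tolerance = 1e-3)
  expect_equal(r2$r2_conditional, 0.84, tolerance = 1e-3)

  # zero slopes give zero marginal R2; no random effect equates the two
  m0 <- cbind("(Intercept)" = rep(1.7, 200), sigma2_e = 1.0, deviance = 0)
  f0 <- fake_fit(m0, X = matrix(1, 50, 1, dimnames = list(NULL, "(Intercept)")),
                 phylo = FALSE)
  r20 <- r2_nakagawa(f0)
  expect_equal(r20$r2_marginal, 0)
  expect_equal(r20$r2_marginal, r20$r2_conditional)
})

test_that("model selection applies the HPD filter before DIC", {
  set.seed(13)
  n <- 80
  x <- runif(n, -1, 1)
  noise <- runif(n, -1, 1)
  y <- 1 + 0.9 * x + rnorm(n, 0, 0.3)
  dat <- tibble::tibble(species = paste0("s", 1:n), y = y, x = x,
                        noise = noise, se = 0)
  fits <- list(
    fit_gaussian_mev(dat, "y", se = "se", fixed = "noise", phylo = FALSE,
                     control = small_ctl("gaussian_mev", 13)),
    fit_gaussian_mev(dat, "y", se = "se", fixed = "x", phylo = FALSE,
                     control = small_ctl("gaussian_mev", 14))
  )
  sel <- select_model(fits, ess_min = 100)
  expect_equal(sel$best$fixed, "x")
  expect_false(sel$table$hpd_pass[1])     # noise slope HPD covers zero
  expect_true(sel$table$selected[2])

  # the winner always satisfies the declared convergence thresholds
  td <- tidy(sel$best)
  expect_gte(min(td$ess), 100)
  expect_lt(max(td$psrf), 1.1)
  expect_error(select_model(list()), "no fits")
})

test_that("adding a pure-noise covariate raises DIC most of the time", {
  worse <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    x <- runif(n, -1, 1)
    y <- 0.5 + x + rnorm(n, 0, 0.4)
    dat <- tibble::tibble(species = paste0("s", 1:n), y = y, x = x,
                          junk = rnorm(n), se = 0)
    f_true <- fit_gaussian_mev(dat, "y", se = "se", fixed = "x", phylo = FALSE,
                               control = small_ctl("gaussian_mev", s))
    f_junk <- fit_gaussian_mev(dat, "y", se = "se", fixed = c("x", "junk"),
                               phylo = FALSE,
                               control = small_ctl("gaussian_mev", s + 50))
    dic(f_junk) > dic(f_true)
  })
  expect_gte(mean(worse), 0.7)
})

test_that("with no data the samplers return their priors", {
  ctl <- mcmc_control("gaussian_mev", n_iter = 140000, burn_in = 20000,
                      thin = 1, n_chains = 1, seed = 21)
  fit <- fit_gaussian_mev(tibble::tibble(), "y", phylo = TRUE, control = ctl)
  b <- fit$samples[, "(Intercept)"]
  expect_gt(length(b), 1e5)
  expect_lt(abs(mean(b)) / sqrt(1e10), 0.05)
  expect_equal(var(b), 1e10, tolerance = 0.05)
})

test_that("fit objects print, tidy, glance and plot", {
  set.seed(15)
  dat <- tibble::tibble(species = paste0("s", 1:30),
                        y = rnorm(30, 1), x = rnorm(30), se = 0)
  fit <- fit_gaussian_mev(dat, "y", se = "se", fixed = "x", phylo = FALSE,
                          control = small_ctl("gaussian_mev", 15))
  expect_output(print(fit), "gaussian_mev")
  expect_named(glance(fit),
               c("family", "response", "n_fixed", "phylo", "dic", "r2_marginal",
                 "r2_conditional", "min_ess", "max_psrf", "converged"))
  expect_s3_class(autoplot(fit), "ggplot")
})
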