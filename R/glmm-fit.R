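# Gibbs / Metropolis-within-Gibbs samplers for the three phylogenetic mixed
# model families.
#
# All three share one Gaussian hierarchy on a (pseudo-)response w:
#   w = X beta + Z u + eps,  eps ~ N(0, sigma2_e I),  u ~ N(0, sigma2_phylo C*)
# with C* the phylogenetic covariance scaled to unit height. The families
# differ only in how w relates to the data:
#   gaussian_mev: w = y - m, with per-row measurement-error deviates
#                 m_i ~ N(0, se_i^2) sampled conjugately;
#   poisson:      w = eta, the log-rate latent, updated by adaptive
#                 random-walk Metropolis against the Poisson likelihood;
#   threshold:    w = l, the liability, a truncated normal given the binary
#                 state, with sigma2_e fixed to 1.
# Priors: beta ~ N(0, 1e10); sigma2_e ~ IG(0.001, 0.001); the phylogenetic
# variance uses parameter expansion u = alpha * v, v ~ N(0, eta2 C*),
# alpha ~ N(0, 1e3), eta2 ~ IG(0.001, 0.001), so sigma2_phylo = alpha^2 eta2
# mixes well even near zero.

PRIOR_BETA_VAR <- 1e10
PRIOR_ALPHA_VAR <- 1e3
PRIOR_IG_SHAPE <- 0.001
PRIOR_IG_RATE <- 0.001

rinvgamma1 <- function(shape, rate) 1 / rgamma(1, shape = shape, rate = rate)

# sample N(P^-1 b, P^-1) from precision P and linear term b
rmvnorm_prec <- function(b, P) {
  R <- chol(P)
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  drop(mu + backsolve(R, rnorm(length(b))))
}

rtruncnorm1 <- function(n, mean, lower, upper) {
  # one-sided truncated normal (sd 1) by inverse CDF on the log scale, so
  # extreme tails stay exact and the truncation cannot silently break
  lo <- lower - mean
  up <- upper - mean
  u <- runif(n)
  out <- numeric(n)
  left <- is.infinite(lo)              # support (-Inf, up]
  if (any(left)) {
    lF <- pnorm(up[left], log.p = TRUE)
    out[left] <- qnorm(log(u[left]) + lF, log.p = TRUE)
  }
  if (any(!left)) {                    # support [lo, Inf)
    lS <- pnorm(lo[!left], lower.tail = FALSE, log.p = TRUE)
    out[!left] <- -qnorm(log(u[!left]) + lS, log.p = TRUE)
  }
  mean + out
}

run_glmm_chain <- function(y, se2, X, Z, Cs, family, control, chain_id,
                           n_trials = NULL) {
  set.seed(control$seed + chain_id)
  n <- length(y); p <- ncol(X)
  phylo <- !is.null(Cs)
  n_sp <- if (phylo) ncol(Z) else 0L
  if (phylo) {
    Cinv <- chol2inv(chol(Cs))
    # rows -> species index; Z is one-hot so Z v = v[sp_idx] and
    # Z' r = rowsum(r, sp_idx)
    sp_idx <- max.col(Z, ties.method = "first")
    counts <- tabulate(sp_idx, n_sp)
    # generalized eigenstructure of the v-conditional precision
    # P = (alpha^2/s2e) D + Cinv/eta2 = D^1/2 Q (a I + Lam/eta2) Q' D^1/2
    d_half <- sqrt(counts)
    M <- Cinv / outer(d_half, d_half)
    eM <- eigen(M, symmetric = TRUE)
    Qm <- eM$vectors
    lam <- pmax(eM$values, 1e-12)
    # eigenstructure of the observation-level phylo covariance Z C* Z',
    # used to draw beta with the random effect integrated out (blocked
    # update; breaks the intercept/random-intercept ridge)
    Cobs <- Cs[sp_idx, sp_idx]
    eO <- eigen(Cobs, symmetric = TRUE)
    Uo <- eO$vectors
    psi <- pmax(eO$values, 0)
    UX <- crossprod(Uo, X)
  }
  XtX <- crossprod(X)

  # state
  beta <- rep(0, p); beta[1] <- mean(y)
  sigma2_e <- max(var(y), 0.1)
  if (family == "threshold") sigma2_e <- 1
  v <- rep(0, max(n_sp, 1)); alpha <- 1; eta2 <- 0.1
  m <- rep(0, n)                       # measurement-error deviates (mev only)
  if (family == "poisson") {
    w <- log(y + 0.5)                  # latent log rate
    mh_sd <- rep(0.5, n); mh_acc <- rep(0, n); mh_n <- 0
  } else if (family == "threshold") {
    w <- ifelse(y > 0, 0.5, -0.5)
  } else {
    w <- y - m
  }

  keep <- seq(control$burn_in + control$thin, control$n_iter, by = control$thin)
  n_keep <- length(keep)
  par_names <- c(colnames(X),
                 if (phylo) "sigma2_phylo",
                 if (family != "threshold") "sigma2_e",
                 "deviance")
  out <- matrix(NA_real_, n_keep, length(par_names),
                dimnames = list(NULL, par_names))
  u_sum <- rep(0, max(n_sp, 1))
  lat_sum <- rep(0, n)                 # running sum of the latent predictor
  k_out <- 0

  for (it in seq_len(control$n_iter)) {
    u_obs <- if (phylo) (alpha * v)[sp_idx] else rep(0, n)

    # response layer
    if (family == "gaussian_mev") {
      mu_i <- drop(X %*% beta) + u_obs
      has_se <- se2 > 0
      if (any(has_se)) {
        post_var <- 1 / (1 / se2[has_se] + 1 / sigma2_e)
        post_mean <- post_var * (y[has_se] - mu_i[has_se]) / sigma2_e
        m[has_se] <- rnorm(sum(has_se), post_mean, sqrt(post_var))
      }
      w <- y - m
    } else if (family == "poisson") {
      mu_i <- drop(X %*% beta) + u_obs
      prop <- w + rnorm(n, 0, mh_sd)
      log_r <- (y * prop - exp(prop)) - (y * w - exp(w)) +
        (-(prop - mu_i)^2 + (w - mu_i)^2) / (2 * sigma2_e)
      acc <- log(runif(n)) < log_r
      w[acc] <- prop[acc]
      if (it <= control$burn_in) {     # adapt toward ~40 % acceptance
        mh_acc <- mh_acc + acc; mh_n <- mh_n + 1
        if (mh_n %% 50 == 0) {
          rate <- mh_acc / 50
          mh_sd <- mh_sd * ifelse(rate > 0.5, 1.25, ifelse(rate < 0.3, 0.8, 1))
          mh_acc <- rep(0, n)
        }
      }
    } else if (family == "threshold") {
      mu_i <- drop(X %*% beta) + u_obs
      w <- rtruncnorm1(n, mu_i,
                       lower = ifelse(y > 0, 0, -Inf),
                       upper = ifelse(y > 0, Inf, 0))
    }

    # beta update; with a phylogenetic effect, beta is drawn jointly with v
    # as a block: first from p(beta | w, variances) with v integrated out
    # (w ~ N(X beta, sigma2_e I + alpha^2 eta2 Z C* Z')), then v | beta
    if (phylo) {
      denom <- sigma2_e + (alpha^2 * eta2) * psi
      tw <- crossprod(Uo, w)
      P <- crossprod(UX, UX / denom) + diag(1 / PRIOR_BETA_VAR, p)
      beta <- rmvnorm_prec(crossprod(UX, tw / denom), P)
    } else {
      r1 <- w - u_obs
      P <- XtX / sigma2_e + diag(1 / PRIOR_BETA_VAR, p)
      beta <- rmvnorm_prec(crossprod(X, r1) / sigma2_e, P)
    }

    # phylogenetic effect via parameter expansion; the v-conditional is
    # sampled in the precomputed eigenbasis (exact, O(n^2) per draw)
    if (phylo) {
      r2 <- w - drop(X %*% beta)
      b <- (alpha / sigma2_e) * drop(rowsum(r2, sp_idx))  # every species occurs

      d_eig <- alpha^2 / sigma2_e + lam / eta2
      wq <- crossprod(Qm, b / d_half)
      v <- (Qm %*% (wq / d_eig + rnorm(n_sp) / sqrt(d_eig)))[, 1] / d_half
      zv <- v[sp_idx]
      prec_a <- sum(zv^2) / sigma2_e + 1 / PRIOR_ALPHA_VAR
      alpha <- rnorm(1, (sum(zv * r2) / sigma2_e) / prec_a, sqrt(1 / prec_a))
      eta2 <- rinvgamma1(PRIOR_IG_SHAPE + n_sp / 2,
                         PRIOR_IG_RATE + drop(crossprod(v, Cinv %*% v)) / 2)
      u_obs <- alpha * zv
    }

    # residual variance
    if (family != "threshold") {
      resid <- w - drop(X %*% beta) - u_obs
      sigma2_e <- rinvgamma1(PRIOR_IG_SHAPE + n / 2,
                             PRIOR_IG_RATE + sum(resid^2) / 2)
    }

    if (it %in% keep) {
      k_out <- k_out + 1
      lin <- drop(X %*% beta) + u_obs
      dev <- switch(family,
        gaussian_mev = -2 * sum(dnorm(y, lin, sqrt(sigma2_e + se2), log = TRUE)),
        poisson = -2 * sum(dpois(y, exp(w), log = TRUE)),
        threshold = {
          pr <- pnorm(lin)
          pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
          -2 * sum(y * log(pr) + (1 - y) * log(1 - pr))
        }
      )
      row <- c(beta,
               if (phylo) alpha^2 * eta2,
               if (family != "threshold") sigma2_e,
               dev)
      out[k_out, ] <- row
      if (phylo) u_sum <- u_sum + alpha * v
      lat_sum <- lat_sum + (if (family == "poisson") w else lin)
    }
  }
  list(samples = out,
       u_mean = if (phylo) u_sum / n_keep else NULL,
       latent_mean = lat_sum / n_keep)
}

# sample directly from the priors (used when data are absent, to check that
# the samplers' prior layer is what it claims to be)
prior_only_fit <- function(p, par_names, phylo, family, control) {
  n_keep <- length(seq(control$burn_in + control$thin, control$n_iter,
                       by = control$thin))
  chains <- lapply(seq_len(control$n_chains), function(cid) {
    set.seed(control$seed + cid)
    draws <- matrix(rnorm(n_keep * p, 0, sqrt(PRIOR_BETA_VAR)), n_keep, p)
    cols <- list(draws)
    if (phylo) {
      a <- rnorm(n_keep, 0, sqrt(PRIOR_ALPHA_VAR))
      e2 <- 1 / rgamma(n_keep, PRIOR_IG_SHAPE, rate = PRIOR_IG_RATE)
      cols <- c(cols, list(a^2 * e2))
    }
    if (family != "threshold") {
      cols <- c(cols, list(1 / rgamma(n_keep, PRIOR_IG_SHAPE, rate = PRIOR_IG_RATE)))
    }
    cols <- c(cols, list(rep(NA_real_, n_keep)))
    m <- do.call(cbind, cols)
    colnames(m) <- par_names
    list(samples = m, u_mean = NULL, latent_mean = NULL)
  })
  chains
}

fit_glmm_engine <- function(data, response, fixed, species, tree, family,
                            se = NULL, phylo = TRUE, control = NULL,
                            scale_C = TRUE) {
  if (is.null(control)) control <- mcmc_control(family)
  prior_only <- nrow(data) == 0

  X <- if (prior_only) {
    matrix(1, 0, 1 + length(fixed),
           dimnames = list(NULL, c("(Intercept)", fixed)))
  } else {
    build_design(data, fixed)
  }
  p <- ncol(X)
  par_names <- c(colnames(X), if (phylo) "sigma2_phylo",
                 if (family != "threshold") "sigma2_e", "deviance")

  if (prior_only) {
    chains <- prior_only_fit(p, par_names, phylo, family, control)
    y <- numeric(0); se2 <- numeric(0); Z <- NULL; Cs <- NULL; sp <- character(0)
  } else {
    y <- data[[response]]
    if (any(!is.finite(y))) abort("non-finite response values")
    sp <- as.character(data[[species]])
    se2 <- if (is.null(se)) rep(0, nrow(data)) else {
      sev <- data[[se]]
      sev[is.na(sev)] <- 0
      if (any(sev < 0)) abort("negative standard errors")
      sev^2
    }
    Cs <- NULL; Z <- NULL
    if (phylo) {
      if (is.null(tree)) abort("phylogenetic model needs a tree (or covariance matrix)")
      C <- if (is.matrix(tree)) tree else {
        missing <- setdiff(unique(sp), tree$tip.label)
        if (length(missing) > 0) {
          abort(paste0("species not in tree: ", paste(missing, collapse = ", ")))
        }
        tree_to_covariance(induced_subtree(tree, unique(sp)))
      }
      sp_levels <- intersect(rownames(C), unique(sp))
      C <- C[sp_levels, sp_levels]
      Cs <- if (scale_C) scale_to_unit_height(C) else C
      ev <- eigen(Cs, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 1e-10 * max(ev)) abort("phylogenetic covariance is not positive definite")
      Z <- matrix(0, nrow(data), length(sp_levels),
                  dimnames = list(NULL, sp_levels))
      Z[cbind(seq_len(nrow(data)), match(sp, sp_levels))] <- 1
    }
    chains <- lapply(seq_len(control$n_chains), function(cid) {
      run_glmm_chain(y, se2, X, Z, Cs, family, control, cid)
    })
  }

  sample_mats <- lapply(chains, `[[`, "samples")
  pooled <- do.call(rbind, sample_mats)
  u_mean <- if (phylo && !prior_only) {
    Reduce(`+`, lapply(chains, `[[`, "u_mean")) / length(chains)
  } else NULL
  latent_mean <- if (!prior_only) {
    Reduce(`+`, lapply(chains, `[[`, "latent_mean")) / length(chains)
  } else NULL

  # deviance at the posterior means (conditional-on-latents convention)
  d_hat <- NA_real_
  if (!prior_only) {
    beta_hat <- colMeans(pooled[, colnames(X), drop = FALSE])
    lin_hat <- drop(X %*% beta_hat) + (if (phylo) drop(Z %*% u_mean) else 0)
    d_hat <- switch(family,
      gaussian_mev = {
        s2 <- mean(pooled[, "sigma2_e"])
        -2 * sum(dnorm(y, lin_hat, sqrt(s2 + se2), log = TRUE))
      },
      poisson = -2 * sum(dpois(y, exp(latent_mean), log = TRUE)),
      threshold = {
        pr <- pmin(pmax(pnorm(lin_hat), 1e-12), 1 - 1e-12)
        -2 * sum(y * log(pr) + (1 - y) * log(1 - pr))
      }
    )
  }

  structure(
    list(
      family = family, response = response, fixed = fixed, phylo = phylo,
      control = control, X = X, species = sp,
      chains = sample_mats, samples = pooled,
      u_mean = u_mean, latent_mean = latent_mean,
      d_bar = if (prior_only) NA_real_ else mean(pooled[, "deviance"]),
      d_hat = d_hat,
      se2 = se2, y = y
    ),
    class = "adk_fit"
  )
}

#' Fit a Gaussian meta-analytic phylogenetic mixed model
#'
#' Response values carry known per-row measurement-error standard errors
#' (`se` column), which enter the likelihood as an extra known variance:
#' `y_i ~ N(x_i' beta + u_species(i), sigma2_e + se_i^2)`, with an optional
#' phylogenetic random intercept `u ~ N(0, sigma2_phylo C)`. Fitting is by
#' Gibbs sampling with measurement-error data augmentation and a
#' parameter-expanded update for the phylogenetic variance.
#'
#' @param data Tibble with the response, `se`, fixed-effect and species
#'   columns. A zero-row tibble triggers a prior-only run.
#' @param response Name of the response column.
#' @param se Name of the standard-error column (`NULL` for none).
#' @param fixed Character vector of fixed-effect column names (may be empty
#'   for an intercept-only model).
#' @param species Name of the species column (default `"species"`).
#' @param tree An [ape::phylo] tree (or a precomputed covariance matrix with
#'   dimnames) covering all species; only needed when `phylo = TRUE`.
#' @param phylo Include the phylogenetic random intercept (default `TRUE`).
#' @param control An [mcmc_control()] object (default: family defaults).
#' @return An `adk_fit` object; see [tidy.adk_fit()], [glance.adk_fit()],
#'   [dic()], [r2_nakagawa()].
#' @export
fit_gaussian_mev <- function(data, response, se = NULL, fixed = character(),
                             species = "species", tree = NULL, phylo = TRUE,
                             control = NULL) {
  if (is.null(control)) control <- mcmc_control("gaussian_mev")
  fit_glmm_engine(data, response, fixed, species, tree, "gaussian_mev",
                  se = se, phylo = phylo, control = control)
}

#' Fit a Poisson phylogenetic mixed model
#'
#' Log-link latent model `y_i ~ Poisson(exp(eta_i))`,
#' `eta_i = x_i' beta + u_species(i) + e_i`, `e_i ~ N(0, sigma2_e)`; the
#' latent log-rates are updated by adaptive random-walk Metropolis inside an
#' otherwise conjugate Gibbs sweep.
#'
#' @inheritParams fit_gaussian_mev
#' @return An `adk_fit` object.
#' @export
fit_poisson <- function(data, response, fixed = character(),
                        species = "species", tree = NULL, phylo = TRUE,
                        control = NULL) {
  if (is.null(control)) control <- mcmc_control("poisson")
  if (nrow(data) > 0) {
    y <- data[[response]]
    if (any(y < 0) || any(y != round(y))) abort("Poisson response must be non-negative integers")
  }
  fit_glmm_engine(data, response, fixed, species, tree, "poisson",
                  phylo = phylo, control = control)
}

#' Fit a phylogenetic threshold (probit liability) model
#'
#' A binary state is governed by a latent Gaussian liability
#' `l_i ~ N(beta_0 + u_species(i), 1)`: the state is present iff `l_i >= 0`.
#' The residual liability variance is not identifiable and is fixed to 1.
#' The fixed part is intercept-only; the phylogenetic random effect acts on
#' the intercept. Constant responses (all 0 or all 1) are rejected — their
#' probability is 0 or 1 without a model (see [column_probability()]).
#'
#' @inheritParams fit_gaussian_mev
#' @param response Name of the binary (0/1) response column.
#' @return An `adk_fit` object.
#' @export
fit_threshold <- function(data, response, species = "species", tree = NULL,
                          phylo = TRUE, control = NULL) {
  if (is.null(control)) control <- mcmc_control("threshold")
  if (nrow(data) > 0) {
    y <- data[[response]]
    if (!all(y %in% c(0, 1))) abort("threshold response must be 0/1")
    if (all(y == 0) || all(y == 1)) {
      abort("constant response: probability is 0 or 1 without a model; use column_probability()")
    }
  }
  fit_glmm_engine(data, response, character(), species, tree, "threshold",
                  phylo = phylo, control = control)
}
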