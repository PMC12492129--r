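# Posterior-sample diagnostics: HPD intervals, effective sample size,
# potential scale reduction factor.

#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples.
#'
#' @param samples Numeric vector of posterior samples (>= 100 for a
#'   meaningful interval; fewer are rejected).
#' @param mass Probability mass (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 100) abort("need at least 100 samples for an HPD interval")
  if (mass <= 0 || mass > 1) abort("mass must be in (0, 1]")
  x <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Effective sample size of one MCMC chain
#'
#' Autocorrelation-sum estimator: `n / (1 + 2 * sum(rho_k))` with the sum
#' truncated by Geyer's initial positive sequence (consecutive
#' even/odd autocorrelation pairs are accumulated while their sum stays
#' positive).
#'
#' @param samples Numeric vector (a single chain).
#' @return Effective sample size (capped at `n`).
#' @export
ess <- function(samples) {
  n <- length(samples)
  if (n < 4) abort("need at least 4 samples")
  if (sd(samples) == 0) return(n)
  max_lag <- min(n - 1, max(50, floor(10 * log10(n)) * 5))
  rho <- drop(acf(samples, lag.max = max_lag, plot = FALSE)$acf)[-1]
  s <- 0
  k <- 1
  while (k <= length(rho)) {
    pair <- rho[k] + (if (k + 1 <= length(rho)) rho[k + 1] else 0)
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  min(n, n / (1 + 2 * s))
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Classic between/within-chain variance ratio for >= 2 chains of equal
#' length; values near 1 indicate convergence.
#'
#' @param chains List of numeric vectors (one per chain), all equal length.
#' @return The PSRF point estimate.
#' @export
psrf <- function(chains) {
  m <- length(chains)
  if (m < 2) abort("PSRF needs at least 2 chains")
  lens <- lengths(chains)
  if (length(unique(lens)) != 1) abort("chains must have equal length")
  n <- lens[1]
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  B_over_n <- var(means)
  if (W == 0) return(1)
  v_hat <- (n - 1) / n * W + (1 + 1 / m) * B_over_n
  sqrt(v_hat / W)
}
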