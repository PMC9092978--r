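# Cell-level heterogeneity: a Gaussian copula ties together the latent
# resting potential, excitability, rebound propensity and latency scale with
# prescribed Spearman rank correlations, while each margin keeps its own
# archetype-specific distribution.

latent_names <- c("rmp", "exc", "reb", "lat")

# Spearman rho of a bivariate Gaussian copula with latent Pearson r is
# (6/pi) asin(r/2); invert to hit the requested rank correlation regardless
# of the marginal transforms.
spearman_to_latent <- function(rho) 2 * sin(pi * rho / 6)

build_latent_correlation <- function(copula_targets) {
  R <- diag(4)
  dimnames(R) <- list(latent_names, latent_names)
  for (tg in copula_targets) {
    pair <- strsplit(tg[["pair"]], ":", fixed = TRUE)[[1]]
    rho <- as.numeric(tg[["rho"]])
    if (!all(pair %in% latent_names))
      stop("unknown copula pair: ", tg[["pair"]])
    if (abs(rho) >= 1) stop("copula target |rho| must be < 1")
    r <- spearman_to_latent(rho)
    R[pair[1], pair[2]] <- r
    R[pair[2], pair[1]] <- r
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10)
    stop(sprintf(paste0("copula targets yield a non positive-definite ",
                        "latent correlation matrix (min eigenvalue %.3g); ",
                        "relax the requested correlations"), min(ev)))
  R
}

# mean-1 gamma quantile; cv = 0 degenerates to the constant 1
qgamma_unit <- function(u, cv) {
  if (cv <= 0) return(rep(1, length(u)))
  shape <- 1 / cv^2
  stats::qgamma(u, shape = shape, scale = cv^2)
}

qlnorm_median <- function(u, median, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::qlnorm(u, meanlog = log(median), sdlog = sdlog)
}

#' Draw cell-level latent properties for one archetype
#'
#' Samples `n` cells from the archetype's cell-level distribution: resting
#' membrane potential, excitability factor (mean 1), rebound propensity
#' (mean 1) and first-spike latency scale (ms) are drawn from a Gaussian
#' copula whose pairwise Spearman correlations equal the archetype's
#' `copula_targets`; input resistance, sag ratio, per-cell excitability
#' trend, resting-potential drift deviation and end-of-experiment electrode
#' offset are drawn independently.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param params a [cell_type_params()] list.
#' @param n number of cells.
#' @return data.frame with one row per cell.
#' @export
sample_cell_latents <- function(params, n) {
  stopifnot(inherits(params, "cell_type_params"), n >= 0)
  R <- build_latent_correlation(params$copula_targets)
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * 4), nrow = n) %*% L
  U <- stats::pnorm(Z)
  # guard against u exactly 0/1 in quantile transforms
  U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
  # RMP marginal: normal truncated to the observed -65..-35 mV range
  p_lo <- stats::pnorm(-65, params$rmp_mean, params$rmp_sd)
  p_hi <- stats::pnorm(-35, params$rmp_mean, params$rmp_sd)
  rmp0 <- stats::qnorm(p_lo + U[, 1] * (p_hi - p_lo),
                       mean = params$rmp_mean, sd = params$rmp_sd)
  exc0 <- qgamma_unit(U[, 2], params$excitability_cv)
  reb0 <- qgamma_unit(U[, 3], params$rebound_cv)
  lat0 <- qlnorm_median(U[, 4], params$latency_median, params$latency_cv)
  rin <- qlnorm_median(stats::runif(n), params$input_resistance_median,
                       params$input_resistance_cv)
  sag <- pmax(stats::rnorm(n, params$sag_ratio_mean, params$sag_ratio_sd),
              0.005)
  trend <- pmax(stats::rnorm(n, params$excitability_trend,
                             params$excitability_trend_sd), -0.95)
  drift_dev <- stats::rnorm(n, 0, params$rmp_drift_sd)
  offset_end <- stats::rnorm(n, -2.66, 3.37)   # mV, electrode offset at 600 s
  data.frame(rmp0 = rmp0, exc0 = exc0, reb0 = reb0, lat0 = lat0,
             rin = rin, sag_ratio = sag, trend = trend,
             drift_dev = drift_dev, offset_end = offset_end)
}

#' Trial-dependent excitability factor
#'
#' e(trial) = e0 * (1 + trend * (1 - exp(-(trial-1)/tau))): a saturating
#' exponential approach from the initial excitability toward its asymptote,
#' rising for mechanoreceptor archetypes and falling for Retzius cells. With
#' the default tau of 3 trials more than 95% of the change is completed
#' within the first 10 trials.
#'
#' @param e0 initial excitability factor(s).
#' @param trend signed asymptotic fractional change.
#' @param trial trial index (1-based).
#' @param tau time constant in trials.
#' @return excitability factor(s) at `trial`, floored at 0.
#' @export
excitability_at_trial <- function(e0, trend, trial, tau) {
  stopifnot(trial >= 1)
  pmax(e0 * (1 + trend * (1 - exp(-(trial - 1) / tau))), 0)
}
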