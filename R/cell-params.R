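# Archetype parameter sets for the synthetic-cohort generator.
#
# Three archetypes are emulated:
#   T3 -- touch mechanoreceptor: highly variable spike count (CV ~0.86),
#         short precise latency (~8 ms), decelerating ISIs (~23 ms median),
#         several rebound spikes, excitability rises over trials.
#   P1 -- pressure mechanoreceptor: variable count (CV ~0.98), rhythmic ISIs
#         around 42 ms, typically one rebound spike, excitability rises.
#   Rz -- Retzius neuron: consistent 2-5 spikes (CV ~0.27), long variable
#         latency (~36 ms), no rebound spikes, excitability falls.
#
# Numeric defaults are calibrated so that the full pipeline
# (simulate -> detect -> extract -> summarize) recovers the field-typical
# summary statistics listed in each parameter's comment; the trace model
# itself (RC passive response + sag + template spikes + rate/latency laws)
# is phenomenological.

#' Default parameters for a cell archetype
#'
#' Returns the full parameter list of the synthetic generator for one of the
#' three archetypes. Any element can be overridden via `...` to explore
#' counterfactual cohorts (e.g. zeroed trends for null calibration).
#'
#' @param archetype one of "T3", "P1", "Rz".
#' @param ... named overrides of individual parameters.
#' @return a list of class `cell_type_params`.
#' @export
cell_type_params <- function(archetype = c("T3", "P1", "Rz"), ...) {
  archetype <- match.arg(archetype)
  base <- switch(archetype,
    T3 = list(
      rmp_mean = -50, rmp_sd = 6,              # mV; cohort range ~ -65..-35
      input_resistance_median = 30,            # MOhm
      input_resistance_cv = 0.45,
      membrane_tau = 18,                       # ms
      fI_threshold = 0.3,                      # nA
      fI_gain = 6.7,                           # spikes/nA (per unit drive)
      fI_saturation = 26,                      # spikes per 500 ms pulse
      excitability_cv = 0.87,                  # -> initial-count CV ~0.86
      latency_median = 8.1, latency_cv = 0.29, # ms
      isi_pattern = "decelerating",
      isi_median = 20.5, isi_cv = 0.18,        # ms; starting ISI scale
      isi_gamma = 0.08,                        # per-step deceleration
      rebound_mean = 2.2, rebound_cv = 0.9,    # spikes after the -2 nA pulse
      sag_ratio_mean = 0.18, sag_ratio_sd = 0.04,
      excitability_trend = 1.95,               # fractional rise, asymptotic
      excitability_trend_sd = 1.35,
      excitability_tau_trials = 3,
      rebound_trend = -0.4,
      latency_trend = 0.35,
      rmp_drift_stim = -0.79, rmp_drift_cont = 0,   # mV, asymptotic
      rmp_drift_sd = 1.8,
      count_noise_sd = 0.16,                   # multiplicative, per trial
      psp_rate_control = 0.25,                 # Hz, quiet-period PSP bumps
      copula_targets = list(
        c(pair = "rmp:exc",  rho = -0.49),
        c(pair = "exc:reb",  rho =  0.49),
        c(pair = "exc:lat",  rho = -0.32))),
    P1 = list(
      rmp_mean = -40, rmp_sd = 6,
      input_resistance_median = 20,
      input_resistance_cv = 0.45,
      membrane_tau = 20,
      fI_threshold = 0.3,
      fI_gain = 6.1,
      fI_saturation = 16,
      excitability_cv = 0.98,
      latency_median = 10.8, latency_cv = 0.24,
      isi_pattern = "rhythmic",
      isi_median = 42, isi_cv = 0.10,          # cell-level preferred ISI
      isi_gamma = 0,
      rebound_mean = 1.1, rebound_cv = 0.35,
      sag_ratio_mean = 0.15, sag_ratio_sd = 0.04,
      excitability_trend = 6.0,
      excitability_trend_sd = 2.2,
      excitability_tau_trials = 3,
      rebound_trend = -0.4,
      latency_trend = 0.35,
      rmp_drift_stim = -5.0, rmp_drift_cont = 0,
      rmp_drift_sd = 1.8,
      count_noise_sd = 0.16,
      psp_rate_control = 0,
      copula_targets = list(
        c(pair = "rmp:exc", rho = -0.67))),
    Rz = list(
      rmp_mean = -50, rmp_sd = 6,
      input_resistance_median = 18,
      input_resistance_cv = 0.45,
      membrane_tau = 25,
      fI_threshold = 0.3,
      fI_gain = 5.3,
      fI_saturation = 8,
      excitability_cv = 0.24,
      latency_median = 36.3, latency_cv = 0.35,
      isi_pattern = "broad",
      isi_median = 200, isi_cv = 0.30,
      isi_gamma = 0,
      rebound_mean = 0, rebound_cv = 0,        # Retzius cells never rebound
      sag_ratio_mean = 0.08, sag_ratio_sd = 0.03,
      excitability_trend = -0.585,
      excitability_trend_sd = 0.12,
      excitability_tau_trials = 3,
      rebound_trend = 0,
      latency_trend = 0.35,
      rmp_drift_stim = -5.72, rmp_drift_cont = -5.93,
      rmp_drift_sd = 1.8,
      count_noise_sd = 0.12,
      psp_rate_control = 0,
      copula_targets = list(
        c(pair = "exc:lat", rho = -0.63))))
  base$archetype <- archetype
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(base))
    if (length(unknown))
      stop("unknown cell_type_params field(s): ",
           paste(unknown, collapse = ", "))
    base[names(dots)] <- dots
  }
  stopifnot(base$rmp_mean >= -65, base$rmp_mean <= -35,
            base$latency_cv > 0, base$isi_cv > 0)
  if (base$archetype == "Rz") stopifnot(base$rebound_mean == 0)
  structure(base, class = "cell_type_params")
}

#' @export
print.cell_type_params <- function(x, ...) {
  cat(sprintf("<cell_type_params> archetype %s\n", x$archetype))
  cat(sprintf("  RMP %g +/- %g mV, Rin median %g MOhm, latency median %g ms\n",
              x$rmp_mean, x$rmp_sd, x$input_resistance_median,
              x$latency_median))
  cat(sprintf("  ISI pattern %s (median %g ms), excitability trend %+0.2f\n",
              x$isi_pattern, x$isi_median, x$excitability_trend))
  invisible(x)
}
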