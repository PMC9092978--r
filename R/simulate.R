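# Synthetic-cohort generator.
#
# The trace model is phenomenological: each trial's membrane potential is the
# trial's resting level, plus a first-order RC response to the injected
# current (with outward rectification above the spike threshold current),
# plus a slow sag component during hyperpolarizing pulses, plus stereotyped
# spike templates inserted at generated spike times, plus a rebound
# depolarization after the -2 nA pulse (mechanoreceptors only), plus an
# electrode-offset ramp, membrane noise and (optionally) synaptic bumps.
# Spike counts follow a saturating threshold-linear fI law scaled by a
# trial-dependent excitability factor; latency and inter-spike-interval
# structure are archetype-specific. All ground truth is retained.

#' Cohort configuration
#'
#' @param archetype one of "T3", "P1", "Rz".
#' @param protocol "stim" or "control".
#' @param n_cells number of cells (>= 0).
#' @param sample_rate Hz (>= 1000).
#' @param noise_sd membrane noise standard deviation, mV.
#' @param seed cohort seed; per-cell and per-trial streams are split from it
#'   deterministically, so increasing `n_cells` leaves earlier cells intact.
#' @param params a [cell_type_params()] object or a named list of overrides
#'   applied to the archetype defaults.
#' @param temperature_effect multiplicative temperature sensitivity of the
#'   spike-count drive per degree C away from 23 C (0 = confounder inert).
#' @param rmp_shift constant shift (mV) of the cohort's mean resting
#'   potential (exposes protocol-batch effects; 0 by default).
#' @param experimenter_mix probability that a cell is recorded by
#'   experimenter "IA" rather than "OR" (defaults to 0.65 for T3 under the
#'   stimulation protocol, 0 otherwise).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(archetype = c("T3", "P1", "Rz"),
                          protocol = c("stim", "control"),
                          n_cells = 10L,
                          sample_rate = 10000,
                          noise_sd = 1.5,
                          seed = 1L,
                          params = NULL,
                          temperature_effect = 0,
                          rmp_shift = 0,
                          experimenter_mix = NULL) {
  archetype <- match.arg(archetype)
  protocol <- match.arg(protocol)
  stopifnot(n_cells >= 0, noise_sd >= 0)
  check_sample_rate(sample_rate)
  if (is.null(params)) {
    params <- cell_type_params(archetype)
  } else if (!inherits(params, "cell_type_params")) {
    params <- do.call(cell_type_params, c(list(archetype = archetype), params))
  }
  if (is.null(experimenter_mix))
    experimenter_mix <- if (archetype == "T3" && protocol == "stim") 0.65 else 0
  structure(list(archetype = archetype, protocol = protocol,
                 n_cells = as.integer(n_cells), sample_rate = sample_rate,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 params = params, temperature_effect = temperature_effect,
                 rmp_shift = rmp_shift, experimenter_mix = experimenter_mix),
            class = "cohort_config")
}

child_seed <- function(seed, cell_index, trial = 0L) {
  (abs(seed) + 1000003 * cell_index + 9973 * trial) %% 2147483587L
}

# spike waveform: ~2 ms triangular rise / exponential decay, unit peak
spike_template <- function(sample_rate) {
  dt <- 1 / sample_rate
  n_rise <- max(1L, round(0.0005 * sample_rate))
  n_fall <- max(2L, ceiling(0.0025 * sample_rate))
  rise <- seq_len(n_rise) / n_rise
  fall <- exp(-(seq_len(n_fall) * dt) / 0.0006)
  list(offsets = c(-(n_rise:1), 0L, seq_len(n_fall)),
       shape = c(rise[-n_rise], 1, 1, fall)[seq_len(n_rise + 1L + n_fall)])
}

# in-pulse inter-spike intervals (ms) for a train of n spikes
plan_isis <- function(n, pattern, lat_ms, params, isi_pref) {
  if (n <= 1) return(numeric(0))
  k <- n - 1L
  usable <- max(500 - lat_ms - 2, 20)
  isis <- switch(pattern,
    decelerating = {
      sdlog <- sqrt(log(1 + params$isi_cv^2))
      base <- params$isi_median * (8 / n)^0.7 *
        exp(stats::rnorm(1, 0, sdlog))
      base * (1 + params$isi_gamma)^(0:(k - 1L)) *
        exp(stats::rnorm(k, 0, 0.12))
    },
    rhythmic = stats::rnorm(k, isi_pref, 3.5),
    broad = {
      sdlog <- sqrt(log(1 + params$isi_cv^2))
      base <- min(params$isi_median, usable / k)
      base * exp(stats::rnorm(k, 0, sdlog))
    },
    stop("unknown isi_pattern: ", pattern))
  pmax(isis, 6)
}

# spike times (ms from pulse onset) for one suprathreshold pulse
plan_pulse_spikes <- function(n, lat_ms, params, isi_pref) {
  if (n <= 0) return(numeric(0))
  tt <- lat_ms + cumsum(c(0, plan_isis(n, params$isi_pattern, lat_ms,
                                       params, isi_pref)))
  tt[tt <= 498]   # spikes scheduled past pulse end are truncated
}

rebound_spike_times <- function(n_reb) {
  if (n_reb <= 0) return(numeric(0))
  first <- 15 * exp(stats::rnorm(1, 0, 0.3))
  isis <- if (n_reb > 1)
    35 * 1.12^(seq_len(n_reb - 1L) - 1L) * exp(stats::rnorm(n_reb - 1L, 0, 0.2))
  else numeric(0)
  tt <- first + cumsum(c(0, pmax(isis, 6)))
  tt[tt <= 495]
}

#' Simulate one trial of one synthetic cell
#'
#' @param cell one-row data.frame of cell latents from
#'   [sample_cell_latents()], augmented with `isi_pref` and `rmp_shift`.
#' @param params a [cell_type_params()] object.
#' @param protocol an `ephys_protocol`.
#' @param trial_index trial number (1-based).
#' @param noise_sd membrane noise sd, mV.
#' @param waveform optional pre-rendered current waveform (from
#'   [render_waveform()]) to avoid re-rendering per trial.
#' @param exc_multiplier extra multiplicative factor on the spike-count
#'   drive (used for confounder-effect knobs).
#' @return list with elements `trace` (class `ephys_trace`: voltage mV,
#'   current nA, sample_rate, trial_index, t0, true spike times) and `truth`
#'   (true resting potential, spike times, intended counts).
#' @export
simulate_trial <- function(cell, params, protocol, trial_index,
                           noise_sd = 1.5, waveform = NULL,
                           exc_multiplier = 1) {
  stopifnot(trial_index >= 1, trial_index <= protocol$n_trials)
  fs <- protocol$sample_rate
  dt <- 1 / fs
  if (is.null(waveform)) waveform <- render_waveform(protocol)
  I <- waveform$current
  n <- length(I)
  t0 <- (trial_index - 1) * protocol$trial_spacing

  tau_s <- params$membrane_tau / 1000
  alpha <- exp(-dt / tau_s)

  # trial-dependent intrinsic state -------------------------------------
  trend_f <- 1 - exp(-(trial_index - 1) / params$excitability_tau_trials)
  e_trial <- max(cell$exc0 * (1 + cell$trend * trend_f), 0) * exc_multiplier
  drift_asym <- if (protocol$kind == "stim") params$rmp_drift_stim
                else params$rmp_drift_cont
  tau_drift <- if (protocol$kind == "stim") 5 else 0.7
  drift_f <- 1 - exp(-(trial_index - 1) / tau_drift)
  rmp_trial <- cell$rmp0 + cell$rmp_shift +
    (drift_asym + cell$drift_dev) * drift_f + stats::rnorm(1, 0, 0.4)
  lat_trial <- cell$lat0 * (1 + params$latency_trend * trend_f)

  # passive RC response; depolarizing steps engage outward conductances, so
  # the depolarizing branch saturates (~8 mV) instead of following R*I
  v_inf <- ifelse(I <= 0, cell$rin * I, 7 * tanh(cell$rin * I / 7))
  v <- rmp_trial +
    as.numeric(stats::filter((1 - alpha) * v_inf, alpha,
                             method = "recursive"))

  # sag during hyperpolarizing pulses. The sag component amplitude is
  # solved per pulse so that the *measured* definition (pulse minimum minus
  # plateau) recovers the cell's sag ratio on the noiseless trace -- the RC
  # rise is still short of plateau at the trough time and partially cancels
  # the dip, so a closed-form amplitude would under-deliver.
  tau_sag <- 0.120
  pul <- protocol$pulses
  for (i in seq_len(nrow(pul))) {
    A <- pul$amplitude[i]
    if (A >= 0) next
    i0 <- round(pul$t_start[i] * fs) + 1L
    i1 <- min(round(pul$t_end[i] * fs), n)
    if (i0 > n) next
    tp <- (seq.int(i0, i1) - i0) * dt
    rc <- 1 - exp(-tp / tau_s)
    sfun <- rc * exp(-tp / tau_sag)
    plateau <- cell$rin * A                      # mV, negative
    shortfall <- -plateau * exp(-tp / tau_s)     # RC deficit, positive
    target <- cell$sag_ratio * plateau           # desired trough depth
    amp <- stats::uniroot(
      function(a) min(shortfall + a * sfun) - target,
      c(20 * target - 1, 0))$root
    w <- amp * sfun
    v[i0:i1] <- v[i0:i1] + w
    # smooth post-pulse relaxation of the sag component
    if (i1 < n) {
      j1 <- min(i1 + round(0.1 * fs), n)
      tq <- (seq.int(i1 + 1L, j1) - i1) * dt
      v[(i1 + 1L):j1] <- v[(i1 + 1L):j1] + w[length(w)] * exp(-tq / tau_s)
    }
  }

  # rebound depolarization after the -2 nA pulse (mechanoreceptors) ------
  spike_times <- numeric(0)
  if (!is.null(protocol$rebound_window)) {
    rb0 <- protocol$rebound_window[1]
    if (params$archetype != "Rz") {
      i0 <- round(rb0 * fs) + 1L
      j1 <- min(i0 + round(0.4 * fs), n)
      tq <- (seq.int(i0, j1) - i0) * dt
      v[i0:j1] <- v[i0:j1] + 4 * (tq / 0.02) * exp(1 - tq / 0.02) *
        exp(-tq / 0.15) * 0.25 + 3 * (1 - exp(-tq / 0.01)) * exp(-tq / 0.15)
      n_reb <- round(max(cell$reb0 * params$rebound_mean *
                           (1 + params$rebound_trend * trend_f) *
                           exp(stats::rnorm(1, 0, 0.25)), 0))
      rb_times <- rb0 + rebound_spike_times(n_reb) / 1000
      spike_times <- c(spike_times, rb_times)
    }
  }

  # pulse-evoked spikes ---------------------------------------------------
  for (i in seq_len(nrow(pul))) {
    A <- pul$amplitude[i]
    drive <- e_trial * params$fI_gain * max(0, A - params$fI_threshold)
    if (drive <= 0) next
    drive <- drive * exp(stats::rnorm(1, 0, params$count_noise_sd))
    n_sp <- round(min(params$fI_saturation, drive))
    if (n_sp <= 0) next
    lat_ms <- lat_trial * exp(stats::rnorm(1, 0, 0.1)) *
      (0.7 / (A - params$fI_threshold))^0.3
    tt <- plan_pulse_spikes(n_sp, lat_ms, params, cell$isi_pref)
    spike_times <- c(spike_times, pul$t_start[i] + tt / 1000)
  }

  # synaptic bumps in quiet periods (control protocol, qualitative) ------
  if (protocol$kind == "control" && params$psp_rate_control > 0) {
    dur <- protocol$active_duration
    n_psp <- stats::rpois(1, params$psp_rate_control * dur)
    if (n_psp > 0) {
      for (tp in stats::runif(n_psp, 0, dur - 0.3)) {
        if (current_at(protocol, tp) != 0) next
        i0 <- round(tp * fs) + 1L
        j1 <- min(i0 + round(0.3 * fs), n)
        tq <- (seq.int(i0, j1) - i0) * dt
        amp <- stats::runif(1, -3, 3)
        v[i0:j1] <- v[i0:j1] + amp * (tq / 0.015) * exp(1 - tq / 0.015) *
          exp(-tq / 0.08)
      }
    }
  }

  # electrode offset ramp (before spike insertion: spikes peak near -10 mV
  # in the *measured* trace, which is what the height criterion sees) ----
  tt_abs <- t0 + (seq_len(n) - 1L) * dt
  v <- v + cell$offset_end * tt_abs / protocol$t_total

  # insert spike templates on the sample grid ----------------------------
  spike_times <- sort(spike_times)
  idx <- round(spike_times * fs) + 1L
  keep <- idx >= 1L & idx <= n
  idx <- idx[keep]
  spike_times <- (idx - 1L) / fs
  tmpl <- spike_template(fs)
  for (k in seq_along(idx)) {
    peak_level <- -10 + stats::rnorm(1, 0, 1)
    height <- peak_level - v[idx[k]]
    if (height <= 0) next
    at <- idx[k] + tmpl$offsets
    ok <- at >= 1L & at <= n
    v[at[ok]] <- v[at[ok]] + height * tmpl$shape[ok]
  }

  # membrane noise --------------------------------------------------------
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)

  trace <- structure(list(voltage = v, current = I, sample_rate = fs,
                          trial_index = trial_index, t0 = t0,
                          true_spikes = spike_times),
                     class = "ephys_trace")
  list(trace = trace,
       truth = list(rmp = rmp_trial, spike_times = spike_times,
                    e_trial = e_trial))
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> trial %d, %d samples @ %g Hz, t0 = %g s\n",
              x$trial_index, length(x$voltage), x$sample_rate, x$t0))
  invisible(x)
}

draw_confounders <- function(config) {
  n <- config$n_cells
  temperature <- round(stats::runif(n, 21.5, 24.6), 1)
  new_leech <- c(TRUE, stats::runif(max(n - 1L, 0)) < 1 / 3.5)[seq_len(n)]
  leech_id <- cumsum(new_leech)
  ganglion <- integer(n)
  prep <- integer(n)
  used <- list()
  for (i in seq_len(n)) {
    key <- as.character(leech_id[i])
    avail <- setdiff(7:16, used[[key]])
    if (!length(avail)) avail <- 7:16
    g <- avail[sample.int(length(avail), 1L)]
    used[[key]] <- c(used[[key]], g)
    ganglion[i] <- g
    prep[i] <- length(used[[key]])
  }
  experimenter <- ifelse(stats::runif(n) < config$experimenter_mix,
                         "IA", "OR")
  data.frame(temperature = temperature, leech_id = leech_id,
             ganglion = ganglion, preparation = prep,
             experimenter = experimenter,
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of synthetic cells
#'
#' Draws cell-level latents and confounders, then simulates every requested
#' trial of every cell under the configured protocol. Deterministic given
#' `config$seed`; cell i always sees the same random stream regardless of
#' `n_cells`, and trial t of cell i the same stream regardless of which
#' trials are requested.
#'
#' @param config a [cohort_config()].
#' @param trials integer vector of trial indices to simulate (default: all
#'   trials of the protocol).
#' @param keep_traces if FALSE, traces are dropped after each cell is
#'   simulated and only ground truth is kept (use
#'   [simulate_cohort_features()] for the memory-light simulate-and-extract
#'   path).
#' @return list of class `ephys_cohort`: config, protocol, latent table with
#'   confounders (`cells`), and per-cell list `recordings` with `traces`
#'   (or NULL) and `truth` per trial.
#' @export
simulate_cohort <- function(config, trials = NULL, keep_traces = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  protocol <- if (config$protocol == "stim")
    build_stim_protocol(config$sample_rate, seed = config$seed)
  else build_control_protocol(config$sample_rate)
  if (is.null(trials)) trials <- seq_len(protocol$n_trials)
  stopifnot(all(trials >= 1), all(trials <= protocol$n_trials))
  waveform <- render_waveform(protocol)

  set.seed(config$seed)
  conf <- draw_confounders(config)

  cells <- vector("list", config$n_cells)
  recordings <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    set.seed(child_seed(config$seed, i))
    lat <- sample_cell_latents(config$params, 1L)
    lat$isi_pref <- stats::rnorm(1, config$params$isi_median,
                                 config$params$isi_median *
                                   config$params$isi_cv)
    lat$rmp_shift <- config$rmp_shift
    lat$cell_id <- sprintf("%s_%s_%03d", config$archetype, config$protocol, i)
    cells[[i]] <- lat
    exc_mult <- exp(config$temperature_effect * (conf$temperature[i] - 23))
    tr_list <- vector("list", length(trials))
    names(tr_list) <- paste0("trial", trials)
    for (k in seq_along(trials)) {
      set.seed(child_seed(config$seed, i, trials[k]))
      sim <- simulate_trial(lat, config$params, protocol, trials[k],
                            noise_sd = config$noise_sd, waveform = waveform,
                            exc_multiplier = exc_mult)
      tr_list[[k]] <- if (keep_traces) sim else sim["truth"]
    }
    recordings[[i]] <- tr_list
  }
  cells <- if (config$n_cells > 0) do.call(rbind, cells) else
    data.frame()
  if (config$n_cells > 0) cells <- cbind(cells, conf)
  structure(list(config = config, protocol = protocol, trials = trials,
                 cells = cells, recordings = recordings),
            class = "ephys_cohort")
}

#' @export
print.ephys_cohort <- function(x, ...) {
  cat(sprintf("<ephys_cohort> %s / %s protocol: %d cell(s), trials %s\n",
              x$config$archetype, x$config$protocol, x$config$n_cells,
              paste(range(x$trials), collapse = "-")))
  invisible(x)
}
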