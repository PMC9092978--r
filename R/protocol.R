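# Stimulation and control current-injection protocols.
#
# Both protocols are represented as a queryable set of annotated pulse windows
# on a per-trial clock (seconds from trial start), plus trial bookkeeping
# (number of trials, spacing, measurement windows). Current is zero outside
# pulse windows; windows are half-open [t_start, t_end).

#' @keywords internal
amplitude_grid <- function() seq(-2, 1.5, by = 0.25)

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so protocol construction never perturbs a
# surrounding simulation stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

pulse_label <- function(amplitude) {
  sprintf("pulse_%+.2fnA", amplitude)
}

new_protocol <- function(kind, trial_duration, active_duration, pulses,
                         n_trials, trial_spacing, rmp_window, rebound_window,
                         sample_rate, seed = NA_integer_) {
  stopifnot(is.data.frame(pulses),
            all(c("label", "amplitude", "t_start", "t_end") %in% names(pulses)))
  ord <- order(pulses$t_start)
  pulses <- pulses[ord, , drop = FALSE]
  rownames(pulses) <- NULL
  if (nrow(pulses) > 1L &&
      any(pulses$t_start[-1L] < pulses$t_end[-nrow(pulses)]))
    stop("pulse windows overlap")
  structure(
    list(kind = kind, trial_duration = trial_duration,
         active_duration = active_duration, pulses = pulses,
         n_trials = n_trials, trial_spacing = trial_spacing,
         rmp_window = rmp_window, rebound_window = rebound_window,
         sample_rate = sample_rate, seed = seed,
         # total recording time: the electrode offset is measured at the end
         # of the last trial's rendered segment
         t_total = (n_trials - 1) * trial_spacing + active_duration),
    class = "ephys_protocol")
}

check_sample_rate <- function(sample_rate) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate < 1000)
    stop("sample_rate must be >= 1000 Hz (latency resolution <= 1 ms)")
  invisible(sample_rate)
}

#' Build the repeated-stimulation protocol
#'
#' One trial lasts 30 s and holds 15 slots of 2 s each; every slot carries a
#' 500 ms current pulse flanked by quiet gaps (1.0 s before, 0.5 s after), so
#' consecutive pulses are separated by 1,500 ms without current. The pulse
#' amplitudes are the 15-value grid from -2.0 to +1.5 nA in 0.25 nA steps,
#' each used exactly once per trial in a pseudo-random (seed-deterministic)
#' order, constrained so that the +1.0 nA pulse always occupies 19.0--19.5 s
#' (immediately after the 18.0--19.0 s resting-potential window) and the
#' -2.0 nA pulse ends at least 2 s before trial end, leaving a clean 500 ms
#' rebound window. The protocol is repeated for 20 trials (600 s total).
#'
#' @param sample_rate sampling rate in Hz used when the waveform is rendered;
#'   must be at least 1000 Hz.
#' @param seed integer seed controlling the pulse-order permutation.
#' @return An object of class `ephys_protocol`.
#' @seealso [build_control_protocol()], [current_at()], [render_waveform()]
#' @export
build_stim_protocol <- function(sample_rate = 10000, seed = 1L) {
  check_sample_rate(sample_rate)
  amps <- amplitude_grid()
  n_slots <- 15L
  plus1_slot <- 10L           # pulse at 19.0--19.5 s, forced by the RMP window
  slots <- setdiff(seq_len(n_slots), plus1_slot)
  other <- setdiff(amps, 1.0)
  assign_amp <- numeric(n_slots)
  assign_amp[plus1_slot] <- 1.0
  perm <- with_seed(seed, {
    p <- sample(other)
    # keep the -2 nA pulse out of the last slot so its 0.5 s rebound window
    # plus margin fits before trial end
    if (p[length(p)] == -2) {
      j <- sample(length(p) - 1L, 1L)
      tmp <- p[j]; p[j] <- p[length(p)]; p[length(p)] <- tmp
    }
    p
  })
  assign_amp[slots] <- perm
  t_start <- 2 * (seq_len(n_slots) - 1L) + 1.0
  pulses <- data.frame(
    label = vapply(assign_amp, pulse_label, character(1)),
    amplitude = assign_amp,
    t_start = t_start,
    t_end = t_start + 0.5)
  sag_end <- pulses$t_end[pulses$amplitude == -2]
  new_protocol(
    kind = "stim", trial_duration = 30, active_duration = 30,
    pulses = pulses, n_trials = 20L, trial_spacing = 30,
    rmp_window = c(18.0, 19.0),
    rebound_window = c(sag_end, sag_end + 0.5),
    sample_rate = sample_rate, seed = as.integer(seed))
}

#' Build the sparse control protocol
#'
#' One trial holds only two 500 ms test pulses -- -0.25 nA at 2.0--2.5 s and
#' +1.0 nA at 5.5--6.0 s (so the 4.5--5.5 s resting-potential window
#' immediately precedes it) -- followed by 5 min without stimulation. Three
#' trials start at 0, 300 and 600 s, so the final measurement is taken after
#' 10 min, matching the stimulation protocol. The quiet tail carries no
#' current; only the 10 s active segment is rendered by the simulator.
#'
#' @inheritParams build_stim_protocol
#' @return An object of class `ephys_protocol`.
#' @export
build_control_protocol <- function(sample_rate = 10000) {
  check_sample_rate(sample_rate)
  pulses <- data.frame(
    label = c(pulse_label(-0.25), pulse_label(1.0)),
    amplitude = c(-0.25, 1.0),
    t_start = c(2.0, 5.5),
    t_end = c(2.5, 6.0))
  new_protocol(
    kind = "control", trial_duration = 300, active_duration = 10,
    pulses = pulses, n_trials = 3L, trial_spacing = 300,
    rmp_window = c(4.5, 5.5),
    rebound_window = NULL,
    sample_rate = sample_rate)
}

#' Injected current at given times
#'
#' Returns the commanded current (nA) at each time `t` on the trial clock.
#' Pulse windows are half-open: a time equal to `t_end` is outside the pulse.
#'
#' @param protocol an `ephys_protocol`.
#' @param t numeric vector of times in seconds from trial start.
#' @return numeric vector of currents in nA.
#' @export
current_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "ephys_protocol"))
  if (any(t < 0 | t > protocol$trial_duration))
    stop("t outside [0, trial_duration]")
  out <- numeric(length(t))
  p <- protocol$pulses
  for (i in seq_len(nrow(p))) {
    inside <- t >= p$t_start[i] & t < p$t_end[i]
    out[inside] <- p$amplitude[i]
  }
  out
}

#' Render the protocol as a sampled waveform
#'
#' @param protocol an `ephys_protocol`.
#' @param sample_rate optional override of the protocol's sampling rate (Hz).
#' @param duration optional duration in seconds (defaults to the protocol's
#'   active segment).
#' @return data.frame with columns `time` (s) and `current` (nA); sample i
#'   sits at time (i-1)/sample_rate.
#' @export
render_waveform <- function(protocol, sample_rate = protocol$sample_rate,
                            duration = protocol$active_duration) {
  check_sample_rate(sample_rate)
  n <- round(duration * sample_rate)
  tt <- (seq_len(n) - 1L) / sample_rate
  data.frame(time = tt, current = current_at(protocol, tt))
}

#' @export
print.ephys_protocol <- function(x, ...) {
  cat(sprintf("<ephys_protocol> kind=%s, %d trial(s) of %g s (spacing %g s)\n",
              x$kind, x$n_trials, x$trial_duration, x$trial_spacing))
  cat(sprintf("  RMP window %g-%g s; %d pulse(s)\n",
              x$rmp_window[1], x$rmp_window[2], nrow(x$pulses)))
  if (!is.null(x$rebound_window))
    cat(sprintf("  rebound window %g-%g s\n",
                x$rebound_window[1], x$rebound_window[2]))
  invisible(x)
}

#' Serialize a protocol to a structured text config
#'
#' Only the defining parameters (kind, sample rate, seed) are written; the
#' waveform is reconstructed from them.
#'
#' @param protocol an `ephys_protocol`.
#' @param path file path for the YAML output.
#' @export
write_protocol_config <- function(protocol, path) {
  cfg <- list(kind = protocol$kind,
              sample_rate = protocol$sample_rate,
              seed = if (is.na(protocol$seed)) NULL else protocol$seed)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a protocol back from a YAML config
#' @param path file path written by [write_protocol_config()].
#' @return an `ephys_protocol`.
#' @export
read_protocol_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  switch(cfg$kind,
         stim = build_stim_protocol(cfg$sample_rate, cfg$seed),
         control = build_control_protocol(cfg$sample_rate),
         stop("unknown protocol kind: ", cfg$kind))
}

#' Write the rendered waveform to CSV for inspection
#' @inheritParams render_waveform
#' @param path output CSV path (columns: time s, current nA).
#' @export
write_waveform_csv <- function(protocol, path,
                               sample_rate = protocol$sample_rate) {
  utils::write.csv(render_waveform(protocol, sample_rate), path,
                   row.names = FALSE)
  invisible(path)
}
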