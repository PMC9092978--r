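# Response-feature extraction from (trace, protocol) pairs.
#
# Features follow the standard current-clamp definitions: windowed-median
# resting potential, peak-based spike detection (height/prominence/distance
# criteria), spike and rebound-spike counts in their 500 ms windows,
# first-spike latency to the peak of the first spike, inter-spike intervals,
# and the passive response / sag amplitude / sag ratio / input resistance
# from the -2 nA pulse. Undefined features are an explicit NA, never 0: the
# zero-vs-absent distinction drives downstream sample sizes.

window_idx <- function(trace, window) {
  fs <- trace$sample_rate
  i0 <- floor(window[1] * fs) + 1L
  i1 <- ceiling(window[2] * fs)          # half-open: sample at t_end excluded
  i1 <- min(i1, length(trace$voltage))
  seq.int(i0, i1)[(seq.int(i0, i1) - 1L) / fs >= window[1] &
                  (seq.int(i0, i1) - 1L) / fs < window[2]]
}

in_window <- function(t, window) t >= window[1] & t < window[2]

#' Detect spikes in a voltage trace
#'
#' Local maxima are kept when their absolute height reaches `min_height`,
#' their topographic prominence (height above the higher of the two lowest
#' points separating the peak from higher terrain on either side) reaches
#' `min_prominence`, and they are at least `min_distance_ms` apart; on a
#' distance conflict the higher peak wins. The distance criterion is
#' enforced in milliseconds (5 ms = 50 samples at the native 10 kHz) so
#' detection behaves identically at reduced sampling rates.
#'
#' @param trace an `ephys_trace` (or any list with `voltage` and
#'   `sample_rate`).
#' @param min_height minimum absolute peak height, mV.
#' @param min_prominence minimum topographic prominence, mV.
#' @param min_distance_ms minimum peak separation, ms.
#' @return list of class `spike_train`: `peak_times` (s, trial clock,
#'   strictly increasing) and `peak_amplitudes` (mV).
#' @export
detect_spikes <- function(trace, min_height = -20, min_prominence = 10,
                          min_distance_ms = 5) {
  v <- trace$voltage
  fs <- trace$sample_rate
  n <- length(v)
  empty <- structure(list(peak_times = numeric(0),
                          peak_amplitudes = numeric(0)),
                     class = "spike_train")
  if (n < 3L) return(empty)
  # candidate local maxima above the height floor (>= left, > right breaks
  # flat-top ties toward the first sample)
  core <- 2:(n - 1L)
  cand <- core[v[core] >= v[core - 1L] & v[core] > v[core + 1L] &
               v[core] >= min_height]
  if (!length(cand)) return(empty)
  h <- v[cand]
  k <- length(cand)
  # segment minima between consecutive candidates (and to the trace edges)
  bounds <- c(1L, cand, n)
  segmin <- vapply(seq_len(k + 1L), function(j)
    min(v[bounds[j]:bounds[j + 1L]]), numeric(1))
  prom <- numeric(k)
  for (j in seq_len(k)) {
    jj <- j
    left <- Inf
    lo <- segmin[j]
    while (jj >= 1L) {
      lo <- min(lo, segmin[jj])
      if (jj > 1L && h[jj - 1L] > h[j]) { left <- lo; break }
      jj <- jj - 1L
      if (jj == 0L) left <- lo
    }
    jj <- j
    right <- Inf
    lo <- segmin[j + 1L]
    while (jj <= k) {
      lo <- min(lo, segmin[jj + 1L])
      if (jj < k && h[jj + 1L] > h[j]) { right <- lo; break }
      jj <- jj + 1L
      if (jj == k + 1L) right <- lo
    }
    prom[j] <- h[j] - max(left, right)
  }
  keep <- prom >= min_prominence
  cand <- cand[keep]; h <- h[keep]
  if (!length(cand)) return(empty)
  # greedy min-distance: keep higher peaks first
  min_gap <- min_distance_ms / 1000 * fs
  ord <- order(h, decreasing = TRUE)
  taken <- logical(0)
  kept_pos <- integer(0)
  for (j in ord) {
    if (all(abs(cand[j] - kept_pos) >= min_gap))
      kept_pos <- c(kept_pos, cand[j])
  }
  kept_pos <- sort(kept_pos)
  structure(list(peak_times = (kept_pos - 1L) / fs,
                 peak_amplitudes = v[kept_pos]),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spike(s)\n", length(x$peak_times)))
  invisible(x)
}

plus1_window <- function(protocol) {
  p <- protocol$pulses
  i <- which(p$amplitude == 1.0)
  if (!length(i)) stop("protocol has no +1 nA pulse")
  c(p$t_start[i[1]], p$t_end[i[1]])
}

minus2_window <- function(protocol) {
  p <- protocol$pulses
  i <- which(p$amplitude == -2.0)
  if (!length(i)) stop("protocol has no -2 nA pulse")
  c(p$t_start[i[1]], p$t_end[i[1]])
}

#' Spike count during the +1 nA test pulse
#'
#' @param spikes a `spike_train`.
#' @param protocol an `ephys_protocol`.
#' @return integer count of spike peaks inside the half-open +1 nA window.
#' @export
spike_count <- function(spikes, protocol) {
  sum(in_window(spikes$peak_times, plus1_window(protocol)))
}

#' Rebound spike count after the -2 nA pulse
#'
#' Counts spike peaks in the 500 ms window immediately after the -2 nA
#' pulse. Rebound spikes cannot be determined for the control protocol,
#' which contains no strong hyperpolarization; calling this on a control
#' protocol is an error.
#'
#' @inheritParams spike_count
#' @return integer count.
#' @export
rebound_spike_count <- function(spikes, protocol) {
  if (is.null(protocol$rebound_window))
    stop("rebound spikes are undefined for the control protocol")
  sum(in_window(spikes$peak_times, protocol$rebound_window))
}

#' First-spike latency to the +1 nA pulse
#'
#' @inheritParams spike_count
#' @return latency in ms from pulse onset to the first spike peak, or `NA`
#'   when no spike falls inside the pulse window (cells with zero spikes
#'   have no latency by definition).
#' @export
first_spike_latency <- function(spikes, protocol) {
  w <- plus1_window(protocol)
  tt <- spikes$peak_times[in_window(spikes$peak_times, w)]
  if (!length(tt)) return(NA_real_)
  (min(tt) - w[1]) * 1000
}

#' Inter-spike intervals within the +1 nA pulse
#'
#' @inheritParams spike_count
#' @return numeric vector of successive peak-to-peak intervals (ms) within
#'   one trial's +1 nA window; empty when fewer than two spikes.
#' @export
interspike_intervals <- function(spikes, protocol) {
  tt <- spikes$peak_times[in_window(spikes$peak_times,
                                    plus1_window(protocol))]
  if (length(tt) < 2L) return(numeric(0))
  diff(sort(tt)) * 1000
}

#' Pool inter-spike intervals across trials and cells
#'
#' @param isi_list a list of numeric ISI vectors (one per trial or cell).
#' @return single numeric vector of pooled ISIs (ms).
#' @export
pool_isis <- function(isi_list) {
  as.numeric(unlist(isi_list, use.names = FALSE))
}

#' Resting membrane potential
#'
#' Median membrane potential over the 1 s window immediately before the
#' +1 nA pulse (18.0--19.0 s for the stimulation protocol, 4.5--5.5 s for
#' the control protocol). The median makes the estimate robust to spike or
#' synaptic transients within the window.
#'
#' @param trace an `ephys_trace`.
#' @param protocol an `ephys_protocol`.
#' @return RMP in mV.
#' @export
resting_membrane_potential <- function(trace, protocol) {
  stats::median(trace$voltage[window_idx(trace, protocol$rmp_window)])
}

#' Passive response, sag amplitude, sag ratio and input resistance
#'
#' From the -2 nA pulse of the stimulation protocol: the passive response is
#' the median over the last 50 ms of the pulse minus the median over the
#' 500 ms immediately before pulse onset; the sag amplitude is the in-pulse
#' voltage minimum (first 5 ms excluded as stimulus-onset transient) minus
#' the last-50 ms median; the sag ratio is their quotient (both negative, so
#' the ratio is positive); input resistance is |passive| / 2 nA.
#'
#' @inheritParams resting_membrane_potential
#' @return named list: `passive_response` (mV), `sag_amplitude` (mV),
#'   `sag_ratio`, `input_resistance` (MOhm).
#' @export
passive_and_sag <- function(trace, protocol) {
  if (protocol$kind != "stim")
    stop("sag and input resistance are undefined for the control protocol")
  w <- minus2_window(protocol)
  pre <- stats::median(trace$voltage[window_idx(trace, c(w[1] - 0.5, w[1]))])
  last50 <- stats::median(trace$voltage[window_idx(trace,
                                                   c(w[2] - 0.05, w[2]))])
  passive <- last50 - pre
  # trough estimate: smooth with a 5 ms moving average so the minimum
  # reflects the sag trajectory rather than the extreme noise sample
  vp <- trace$voltage[window_idx(trace, c(w[1] + 0.005, w[2]))]
  kk <- max(1L, round(0.005 * trace$sample_rate))
  vs <- as.numeric(stats::filter(vp, rep(1 / kk, kk), sides = 2))
  vmin <- min(vs, na.rm = TRUE)
  sag <- vmin - last50
  list(passive_response = passive,
       sag_amplitude = sag,
       sag_ratio = sag / passive,
       input_resistance = abs(passive) / 2)
}

#' Correct a final resting potential for linear electrode drift
#'
#' The electrode offset measured after the experiment is assumed to build up
#' linearly over the recording; the fraction accrued by time `t` is
#' subtracted from the raw value.
#'
#' @param raw_rmp raw measured RMP, mV.
#' @param offset_end electrode offset measured at the end, mV.
#' @param t measurement time, s from recording start.
#' @param t_total total recording duration, s.
#' @return corrected RMP, mV.
#' @export
correct_final_rmp <- function(raw_rmp, offset_end, t, t_total) {
  if (any(t_total == 0)) stop("t_total must be positive")
  stopifnot(all(t >= 0), all(t <= t_total))
  raw_rmp - offset_end * (t / t_total)
}

#' Extract all per-trial features from one trace
#'
#' @param trace an `ephys_trace`.
#' @param protocol an `ephys_protocol`.
#' @return one-row data.frame with trial index, RMP, spike count, rebound
#'   count (NA for control), latency (NA when no spikes), number of ISIs,
#'   passive/sag/input-resistance block (NA for control), plus the ISI
#'   vector as a list column `isis`.
#' @export
extract_trial_features <- function(trace, protocol) {
  spikes <- detect_spikes(trace)
  is_stim <- protocol$kind == "stim"
  ps <- if (is_stim) passive_and_sag(trace, protocol) else
    list(passive_response = NA_real_, sag_amplitude = NA_real_,
         sag_ratio = NA_real_, input_resistance = NA_real_)
  isis <- interspike_intervals(spikes, protocol)
  out <- data.frame(
    trial = trace$trial_index,
    rmp = resting_membrane_potential(trace, protocol),
    spike_count = spike_count(spikes, protocol),
    rebound_count = if (is_stim) rebound_spike_count(spikes, protocol)
                    else NA_integer_,
    latency = first_spike_latency(spikes, protocol),
    n_isis = length(isis),
    passive_response = ps$passive_response,
    sag_amplitude = ps$sag_amplitude,
    sag_ratio = ps$sag_ratio,
    input_resistance = ps$input_resistance)
  out$isis <- list(isis)
  out
}

final_trial_of <- function(protocol) protocol$n_trials

#' Initial/final/delta feature view for one cell
#'
#' Delta features are final minus initial (trial 20 vs trial 1 for the
#' stimulation protocol, trial 3 vs trial 1 for control). The final RMP is
#' corrected for electrode drift before differencing when `offset_end` is
#' supplied. Delta latency is NA when the latency is absent in either trial.
#'
#' @param trial_features per-trial feature table from
#'   [extract_trial_features()] rows (must contain trial 1 and the final
#'   trial).
#' @param protocol an `ephys_protocol`.
#' @param offset_end electrode offset at the end of the recording (mV), or
#'   NA to skip drift correction.
#' @return one-row data.frame with initial_*, final_* and delta_* columns.
#' @export
delta_features <- function(trial_features, protocol, offset_end = NA_real_) {
  fin <- final_trial_of(protocol)
  a <- trial_features[trial_features$trial == 1L, , drop = FALSE]
  b <- trial_features[trial_features$trial == fin, , drop = FALSE]
  if (nrow(a) != 1L || nrow(b) != 1L)
    stop("need exactly one row for trial 1 and the final trial")
  t_meas <- (fin - 1) * protocol$trial_spacing + mean(protocol$rmp_window)
  final_rmp_corr <- if (is.na(offset_end)) b$rmp else
    correct_final_rmp(b$rmp, offset_end, t_meas, protocol$t_total)
  data.frame(
    initial_rmp = a$rmp, final_rmp = final_rmp_corr,
    delta_rmp = final_rmp_corr - a$rmp,
    initial_count = a$spike_count, final_count = b$spike_count,
    delta_count = b$spike_count - a$spike_count,
    initial_rebound = a$rebound_count, final_rebound = b$rebound_count,
    delta_rebound = b$rebound_count - a$rebound_count,
    initial_latency = a$latency, final_latency = b$latency,
    delta_latency = ifelse(is.na(a$latency) | is.na(b$latency), NA_real_,
                           b$latency - a$latency),
    initial_sag_ratio = a$sag_ratio,
    initial_input_resistance = a$input_resistance)
}

#' Inclusion filter on extracted cells
#'
#' Keeps cells that spiked at least once in response to the +1 nA pulse in
#' the first or the final trial; excluded cells are reported via a message
#' and an `excluded` attribute.
#'
#' @param cell_table data.frame with columns `initial_count` and
#'   `final_count` (one row per cell).
#' @return the filtered data.frame, with attribute `excluded` holding the
#'   dropped rows.
#' @export
apply_inclusion_filter <- function(cell_table) {
  keep <- cell_table$initial_count >= 1L | cell_table$final_count >= 1L
  excluded <- cell_table[!keep, , drop = FALSE]
  if (nrow(excluded))
    message(sprintf("inclusion filter: excluded %d cell(s) with zero spikes in first and final trial",
                    nrow(excluded)))
  out <- cell_table[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}
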