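# Shared fixtures. Heavy cohorts are simulated once per test run and cached;
# tests run at 2 kHz (features are sample-rate robust, checked explicitly).

.fixture_cache <- new.env(parent = emptyenv())

fixture_arm <- function(archetype, n_cells, seed = 1L, trials = NULL,
                        sample_rate = 2000, protocol = "stim", ...) {
  key <- paste(archetype, protocol, n_cells, seed, sample_rate,
               paste(trials, collapse = "."), sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    cc <- cohort_config(archetype, protocol, n_cells = n_cells,
                        sample_rate = sample_rate, seed = seed, ...)
    .fixture_cache[[key]] <- simulate_cohort_features(cc, trials = trials)
  }
  .fixture_cache[[key]]
}

included_cells <- function(cf) {
  suppressMessages(apply_inclusion_filter(cf$cells))
}

# analytic trace with given constant segments; segments is a data.frame with
# columns t_start, t_end (s) and value (mV); baseline elsewhere
make_segment_trace <- function(baseline, segments, duration, sample_rate,
                               trial_index = 1L) {
  n <- round(duration * sample_rate)
  tt <- (seq_len(n) - 1L) / sample_rate
  v <- rep(baseline, n)
  for (i in seq_len(nrow(segments))) {
    sel <- tt >= segments$t_start[i] & tt < segments$t_end[i]
    v[sel] <- segments$value[i]
  }
  structure(list(voltage = v, current = numeric(n),
                 sample_rate = sample_rate, trial_index = trial_index,
                 t0 = 0, true_spikes = numeric(0)),
            class = "ephys_trace")
}

# add a triangular spike of given peak value and ~2 ms width at time t_peak
add_test_spike <- function(trace, t_peak, peak = -10) {
  fs <- trace$sample_rate
  j <- round(t_peak * fs) + 1L
  w <- max(1L, round(0.001 * fs))
  for (k in -w:w) {
    at <- j + k
    if (at < 1L || at > length(trace$voltage)) next
    frac <- 1 - abs(k) / (w + 1)
    lvl <- trace$voltage[at] + (peak - trace$voltage[at]) * frac
    trace$voltage[at] <- max(trace$voltage[at], lvl)
  }
  trace
}

fake_spike_train <- function(times, amps = rep(-10, length(times))) {
  structure(list(peak_times = times, peak_amplitudes = amps),
            class = "spike_train")
}
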