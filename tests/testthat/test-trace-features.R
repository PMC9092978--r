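test_that("detector finds template spikes and honors the height floor", {
  tr <- make_segment_trace(-50, data.frame(t_start = numeric(0),
                                           t_end = numeric(0),
                                           value = numeric(0)),
                           duration = 1, sample_rate = 10000)
  tr <- add_test_spike(tr, 0.400, peak = -10)
  tr <- add_test_spike(tr, 0.420, peak = -10)
  sp <- detect_spikes(tr)
  expect_equal(length(sp$peak_times), 2L)
  expect_equal(sp$peak_times, c(0.400, 0.420), tolerance = 1e-4)
  # a bump peaking below -20 mV is not a spike
  tr2 <- add_test_spike(make_segment_trace(-50, data.frame()[0, ],
                                           1, 10000), 0.5, peak = -25)
  expect_equal(length(detect_spikes(tr2)$peak_times), 0L)
})

test_that("detector enforces prominence", {
  # a -15 mV bump on a -22 mV shelf between two tall spikes: the paths to
  # higher terrain never drop below the shelf, so its prominence is 7 mV
  # and it is rejected while the flanking spikes are kept
  fs <- 10000
  n <- fs
  v <- rep(-50, n)
  v[2500:7500] <- -22
  bump <- function(v, j, peak, base) {
    w <- 10
    v[(j - w):(j + w)] <- pmax(v[(j - w):(j + w)],
                               base + (1 - abs(-w:w) / (w + 1)) *
                                 (peak - base))
    v
  }
  v <- bump(v, 3000, -5, -22)
  v <- bump(v, 7000, -5, -22)
  v <- bump(v, 5000, -15, -22)
  tr <- structure(list(voltage = v, current = numeric(n), sample_rate = fs,
                       trial_index = 1L, t0 = 0), class = "ephys_trace")
  expect_equal(length(detect_spikes(tr)$peak_times), 2L)
  # raising the bump to -11 lifts its prominence to 11 mV: now kept
  v2 <- bump(v, 5000, -11, -22)
  tr$voltage <- v2
  expect_equal(length(detect_spikes(tr)$peak_times), 3L)
})

test_that("min-distance keeps the higher of two close peaks", {
  tr <- make_segment_trace(-50, data.frame()[0, ], 1, 10000)
  tr <- add_test_spike(tr, 0.500, peak = -12)
  tr <- add_test_spike(tr, 0.503, peak = -10)   # 3 ms apart, higher
  sp <- detect_spikes(tr)
  expect_equal(length(sp$peak_times), 1L)
  expect_equal(sp$peak_times, 0.503, tolerance = 1e-4)
  # oracle cross-check: an exhaustive local-maxima scan finds both candidates
  v <- tr$voltage
  cand <- which(diff(sign(diff(v))) == -2) + 1L
  cand <- cand[v[cand] >= -20]
  expect_equal(length(cand), 2L)
  expect_equal((cand[which.max(v[cand])] - 1) / 10000, sp$peak_times,
               tolerance = 1e-4)
})

test_that("spike count respects the half-open +1 nA window", {
  p <- build_stim_protocol(2000, seed = 1)   # +1 nA at 19.0-19.5
  sp <- fake_spike_train(c(19.05, 19.20, 19.49))
  expect_equal(spike_count(sp, p), 3L)
  expect_equal(spike_count(fake_spike_train(c(19.5)), p), 0L)
  expect_equal(spike_count(fake_spike_train(c(19.0)), p), 1L)
  expect_equal(spike_count(fake_spike_train(numeric(0)), p), 0L)
})

test_that("rebound counting uses the post -2 nA window and rejects control", {
  p <- build_stim_protocol(2000, seed = 1)
  rb <- p$rebound_window
  expect_equal(rebound_spike_count(fake_spike_train(rb[1] + 0.1), p), 1L)
  # brute-force window boundary check
  for (dt in c(-0.01, 0, 0.25, 0.499, 0.501, 0.6)) {
    sp <- fake_spike_train(rb[1] + dt)
    expect_equal(rebound_spike_count(sp, p),
                 as.integer(dt >= 0 && dt < 0.5))
  }
  pc <- build_control_protocol(2000)
  expect_error(rebound_spike_count(fake_spike_train(1), pc),
               "control protocol")
  expect_error(passive_and_sag(make_segment_trace(-50, data.frame()[0, ],
                                                  1, 2000), pc),
               "control protocol")
})

test_that("first-spike latency is peak time minus pulse onset", {
  p <- build_stim_protocol(10000, seed = 1)
  expect_equal(first_spike_latency(fake_spike_train(c(19.0081, 19.05)), p),
               8.1, tolerance = 1e-9)
  expect_true(is.na(first_spike_latency(fake_spike_train(numeric(0)), p)))
  expect_true(is.na(first_spike_latency(fake_spike_train(18.9), p)))
})

test_that("inter-spike intervals come from the +1 nA window only", {
  p <- build_stim_protocol(2000, seed = 1)
  sp <- fake_spike_train(c(19.010, 19.033, 19.079))
  expect_equal(interspike_intervals(sp, p), c(23, 46), tolerance = 1e-9)
  expect_equal(interspike_intervals(fake_spike_train(19.2), p), numeric(0))
  expect_equal(pool_isis(list(c(23, 46), numeric(0), 10)), c(23, 46, 10))
})

test_that("RMP is the exact windowed median and robust to spike artifacts", {
  p <- build_stim_protocol(2000, seed = 1)
  tr <- make_segment_trace(-48, data.frame()[0, ], 30, 2000)
  expect_equal(resting_membrane_potential(tr, p), -48)
  # inject a 2 ms spike artifact inside the RMP window
  tr2 <- add_test_spike(tr, 18.5, peak = -10)
  expect_lt(abs(resting_membrane_potential(tr2, p) + 48), 0.1)
  # the mean is NOT robust: shifts visibly
  idx <- ephyscohort:::window_idx(tr2, p$rmp_window)
  expect_gt(abs(mean(tr2$voltage[idx]) + 48), 0.04)
  # order-statistic oracle: median equals the sorting definition
  set.seed(3)
  tr3 <- tr
  tr3$voltage <- tr3$voltage + rnorm(length(tr3$voltage))
  vals <- tr3$voltage[ephyscohort:::window_idx(tr3, p$rmp_window)]
  sv <- sort(vals)
  n <- length(sv)
  expect_equal(resting_membrane_potential(tr3, p),
               if (n %% 2) sv[(n + 1) / 2] else mean(sv[n / 2 + 0:1]))
})

test_that("sag arithmetic matches the analytic trace", {
  p <- build_stim_protocol(2000, seed = 1)
  w <- p$pulses[p$pulses$amplitude == -2, ]
  # baseline -50; pulse: dips to a flat -100 trough then settles at -90
  segs <- data.frame(
    t_start = c(w$t_start, w$t_start + 0.05, w$t_start + 0.10),
    t_end = c(w$t_start + 0.05, w$t_start + 0.10, w$t_end),
    value = c(-75, -100, -90))
  tr <- make_segment_trace(-50, segs, 30, 2000)
  ps <- passive_and_sag(tr, p)
  expect_equal(ps$passive_response, -40)
  expect_equal(ps$sag_amplitude, -10)
  expect_equal(ps$sag_ratio, 0.25)
  expect_equal(ps$input_resistance, 20)
})

test_that("a monotone step without sag yields sag ratio near zero", {
  p <- build_stim_protocol(2000, seed = 1)
  w <- p$pulses[p$pulses$amplitude == -2, ]
  fs <- 2000
  n <- 30 * fs
  tt <- (seq_len(n) - 1) / fs
  v <- rep(-50, n)
  inp <- tt >= w$t_start & tt < w$t_end
  v[inp] <- -50 - 40 * (1 - exp(-(tt[inp] - w$t_start) / 0.02))
  tr <- structure(list(voltage = v, current = numeric(n), sample_rate = fs,
                       trial_index = 1L, t0 = 0), class = "ephys_trace")
  ps <- passive_and_sag(tr, p)
  expect_lt(abs(ps$sag_amplitude), 0.2)
  expect_lt(abs(ps$sag_ratio), 0.01)
})

test_that("sag ratio is invariant to offsets and gain rescaling", {
  cc <- cohort_config("T3", "stim", n_cells = 1, sample_rate = 2000,
                      seed = 14)
  co <- simulate_cohort(cc, trials = 1)
  tr <- co$recordings[[1]][[1]]$trace
  r0 <- passive_and_sag(tr, co$protocol)$sag_ratio
  tr_off <- tr; tr_off$voltage <- tr$voltage + 7
  expect_equal(passive_and_sag(tr_off, co$protocol)$sag_ratio, r0)
  tr_gain <- tr; tr_gain$voltage <- tr$voltage * 1.3
  expect_equal(passive_and_sag(tr_gain, co$protocol)$sag_ratio, r0,
               tolerance = 1e-9)
})

test_that("generator sag ratio is recovered across cells", {
  cf <- fixture_arm("T3", 30, seed = 15, trials = 1)
  prm <- cell_type_params("T3")
  expect_lt(abs(median(cf$trial_features$sag_ratio) - prm$sag_ratio_mean),
            0.05)
})

test_that("electrode drift correction interpolates linearly", {
  expect_equal(correct_final_rmp(-55, -3, 600, 600), -52)
  expect_equal(correct_final_rmp(-55, 0, 300, 600), -55)
  expect_equal(correct_final_rmp(-50, -2.66, 300, 600), -48.67)
  expect_error(correct_final_rmp(-50, -3, 0, 0), "positive")
})

test_that("inclusion filter keeps cells spiking in first OR final trial", {
  tab <- data.frame(cell_id = c("a", "b", "c", "d"),
                    initial_count = c(0L, 0L, 1L, 2L),
                    final_count = c(3L, 0L, 0L, 5L))
  out <- suppressMessages(apply_inclusion_filter(tab))
  expect_equal(out$cell_id, c("a", "c", "d"))
  expect_equal(attr(out, "excluded")$cell_id, "b")
  expect_message(apply_inclusion_filter(tab), "excluded 1 cell")
})

test_that("delta features difference final minus initial with NA rules", {
  p <- build_stim_protocol(2000, seed = 1)
  tf <- data.frame(trial = c(1L, 20L), rmp = c(-50, -53),
                   spike_count = c(3L, 10L), rebound_count = c(2L, 1L),
                   latency = c(8, 12), n_isis = c(2L, 9L),
                   passive_response = NA_real_, sag_amplitude = NA_real_,
                   sag_ratio = c(0.2, 0.2), input_resistance = c(30, 30))
  d <- delta_features(tf, p, offset_end = 0)
  expect_equal(d$delta_count, 7L)
  expect_equal(d$delta_rmp, -3)
  expect_equal(d$delta_rebound, -1L)
  expect_equal(d$delta_latency, 4)
  # identical trials: all deltas zero
  tf0 <- tf; tf0[2, c("rmp", "spike_count", "rebound_count", "latency")] <-
    tf0[1, c("rmp", "spike_count", "rebound_count", "latency")]
  d0 <- delta_features(tf0, p, offset_end = 0)
  expect_equal(unlist(d0[c("delta_rmp", "delta_count", "delta_rebound",
                           "delta_latency")], use.names = FALSE),
               rep(0, 4))
  # latency absent in one trial: delta latency absent, count delta intact
  tf_na <- tf; tf_na$latency[1] <- NA
  d_na <- delta_features(tf_na, p, offset_end = 0)
  expect_true(is.na(d_na$delta_latency))
  expect_equal(d_na$delta_count, 7L)
  # electrode offset correction applied to the final RMP only
  d_off <- delta_features(tf, p, offset_end = -4)
  t_meas <- 19 * 30 + mean(p$rmp_window)
  expect_equal(d_off$delta_rmp, -3 + 4 * t_meas / 600)
})

test_that("features are sample-rate robust", {
  prm <- cell_type_params("T3")
  set.seed(31)
  lat <- sample_cell_latents(prm, 1)
  lat$isi_pref <- 20; lat$rmp_shift <- 0
  res <- lapply(c(2000, 10000), function(fs) {
    p <- build_stim_protocol(fs, seed = 1)
    set.seed(77)
    sim <- simulate_trial(lat, prm, p, 1, noise_sd = 0)
    extract_trial_features(sim$trace, p)
  })
  expect_equal(res[[1]]$spike_count, res[[2]]$spike_count)
  expect_equal(res[[1]]$rebound_count, res[[2]]$rebound_count)
  expect_lt(abs(res[[1]]$latency - res[[2]]$latency), 0.51)
  expect_lt(abs(res[[1]]$rmp - res[[2]]$rmp), 0.5)
  expect_lt(abs(res[[1]]$passive_response - res[[2]]$passive_response), 0.5)
})

test_that("trace CSV container round-trips traces and ground truth", {
  cc <- cohort_config("P1", "stim", n_cells = 1, sample_rate = 1000,
                      seed = 3)
  co <- simulate_cohort(cc, trials = 1)
  tr <- co$recordings[[1]][[1]]$trace
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f, archetype = "P1")
  back <- read_trace_csv(f)
  expect_equal(back$voltage, tr$voltage, tolerance = 1e-6)
  expect_equal(back$sample_rate, 1000)
  expect_equal(back$trial_index, 1L)
  expect_equal(back$true_spikes, tr$true_spikes, tolerance = 1e-6)
  d <- withr::local_tempdir()
  write_cohort_csv(co, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_equal(man$cell_id, co$cells$cell_id)
})
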