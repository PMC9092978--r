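test_that("Gaussian copula reproduces the requested rank correlations", {
  set.seed(11)
  lat <- sample_cell_latents(cell_type_params("T3"), 10000)
  tg <- cell_type_params("T3")$copula_targets
  rho <- function(a, b) cor(rank(a), rank(b))
  expect_equal(rho(lat$rmp0, lat$exc0),
               as.numeric(tg[[1]]["rho"]), tolerance = 0.03)
  expect_equal(rho(lat$exc0, lat$reb0),
               as.numeric(tg[[2]]["rho"]), tolerance = 0.03)
  expect_equal(rho(lat$exc0, lat$lat0),
               as.numeric(tg[[3]]["rho"]), tolerance = 0.03)
  # untargeted pair stays uncorrelated
  expect_lt(abs(rho(lat$rmp0, lat$lat0)), 0.05)
})

test_that("Rz copula leaves RMP and excitability independent", {
  set.seed(12)
  lat <- sample_cell_latents(cell_type_params("Rz"), 10000)
  expect_lt(abs(cor(rank(lat$rmp0), rank(lat$exc0))), 0.03)
})

test_that("degenerate and infeasible copula inputs behave", {
  set.seed(13)
  p0 <- cell_type_params("T3", rmp_sd = 1e-9)
  lat <- sample_cell_latents(p0, 50)
  expect_true(all(abs(lat$rmp0 - p0$rmp_mean) < 1e-6))
  bad <- cell_type_params("T3", copula_targets = list(
    c(pair = "rmp:exc", rho = 0.95),
    c(pair = "exc:lat", rho = 0.95),
    c(pair = "rmp:lat", rho = -0.95)))
  expect_error(sample_cell_latents(bad, 10), "positive-definite")
  expect_error(sample_cell_latents(
    cell_type_params("T3", copula_targets = list(
      c(pair = "rmp:exc", rho = 1))), 5), "< 1")
})

test_that("excitability follows a saturating trial law", {
  tau <- 3
  e <- excitability_at_trial(1, 1.95, 1:20, tau)
  expect_true(all(diff(e) > 0))
  # most of the change is completed within the first 10 trials
  e_inf <- 1 * (1 + 1.95)
  expect_lt(abs(e[10] - e_inf), 0.1 * abs(e[1] - e_inf))
  e_down <- excitability_at_trial(1, -0.585, 1:20, tau)
  expect_true(all(diff(e_down) < 0))
  expect_true(all(e_down > 0))
})

test_that("passive model is Ohmic at steady state for small currents", {
  cc <- cohort_config("Rz", "stim", n_cells = 3, sample_rate = 2000,
                      seed = 2, noise_sd = 0)
  co <- simulate_cohort(cc, trials = 1)
  w <- co$protocol$pulses[co$protocol$pulses$amplitude == -0.25, ]
  for (i in 1:3) {
    tr <- co$recordings[[i]][[1]]$trace
    truth <- co$recordings[[i]][[1]]$truth
    idx <- (round((w$t_end - 0.05) * tr$sample_rate) + 1):
      round(w$t_end * tr$sample_rate)
    offset <- co$cells$offset_end[i] * (tr$t0 + w$t_end) / 600
    deflection <- median(tr$voltage[idx]) - offset - truth$rmp
    expect_equal(deflection, -0.25 * co$cells$rin[i], tolerance = 0.01)
  }
})

test_that("ground-truth spikes are exactly recovered by the detector", {
  # the central oracle: sensitivity = specificity = 1 at default noise
  for (fs in c(2000, 10000)) {
    cc <- cohort_config("T3", "stim", n_cells = 4, sample_rate = fs,
                        seed = 5)
    co <- simulate_cohort(cc, trials = c(1, 20))
    n_spikes <- 0L
    for (i in seq_len(4)) for (k in 1:2) {
      tr <- co$recordings[[i]][[k]]$trace
      det <- detect_spikes(tr)$peak_times
      tru <- tr$true_spikes
      n_spikes <- n_spikes + length(tru)
      for (t in tru) expect_true(any(abs(det - t) <= 0.001 + 1e-9))
      for (t in det) expect_true(any(abs(tru - t) <= 0.001 + 1e-9))
    }
    expect_gt(n_spikes, 50L)
  }
})

test_that("Retzius cells never fire rebound spikes", {
  cf <- fixture_arm("Rz", 8, seed = 4, trials = c(1, 10, 20))
  expect_true(all(cf$trial_features$rebound_count == 0L))
})

test_that("cohorts are deterministic and stable under growth", {
  cc <- cohort_config("T3", "stim", n_cells = 3, sample_rate = 2000,
                      seed = 21)
  a <- simulate_cohort_features(cc, trials = c(1, 20))
  b <- simulate_cohort_features(cc, trials = c(1, 20))
  expect_identical(a$trial_features, b$trial_features)
  expect_identical(a$cells, b$cells)
  # growing the cohort leaves earlier cells untouched
  cc5 <- cohort_config("T3", "stim", n_cells = 5, sample_rate = 2000,
                       seed = 21)
  c5 <- simulate_cohort_features(cc5, trials = c(1, 20))
  expect_identical(a$trial_features,
                   c5$trial_features[c5$trial_features$cell_id %in%
                                     a$trial_features$cell_id, ])
  # trial subsets reuse the same per-trial streams
  full <- simulate_cohort_features(cc, trials = c(1, 2, 20))
  expect_equal(full$cells$delta_count, a$cells$delta_count)
})

test_that("an empty cohort yields empty tables", {
  cc <- cohort_config("T3", "stim", n_cells = 0, sample_rate = 2000,
                      seed = 1)
  cf <- simulate_cohort_features(cc, trials = 1)
  expect_equal(nrow(cf$trial_features), 0L)
  expect_equal(nrow(cf$cells), 0L)
})

test_that("zero-current slots evoke no spikes and flat traces", {
  cc <- cohort_config("T3", "stim", n_cells = 2, sample_rate = 2000,
                      seed = 8, noise_sd = 0)
  co <- simulate_cohort(cc, trials = 1)
  p <- co$protocol
  w0 <- p$pulses[p$pulses$amplitude == 0, ]
  for (i in 1:2) {
    tr <- co$recordings[[i]][[1]]$trace
    tru <- tr$true_spikes
    expect_false(any(tru >= w0$t_start & tru < w0$t_end))
    idx <- (round(w0$t_start * 2000) + 1):round(w0$t_end * 2000)
    truth <- co$recordings[[i]][[1]]$truth
    expect_lt(max(abs(tr$voltage[idx] - truth$rmp)), 1.5)  # offset ramp only
  }
})

test_that("excitability increase shows up as rising spike counts in T3", {
  cf <- fixture_arm("T3", 40, seed = 6, trials = c(1, 20))
  inc <- included_cells(cf)
  expect_gte(mean(inc$delta_count >= 0), 0.8)
})

test_that("extracted RMP tracks the generator ground truth", {
  cc <- cohort_config("P1", "stim", n_cells = 3, sample_rate = 2000,
                      seed = 9)
  co <- simulate_cohort(cc, trials = c(1, 20))
  for (i in 1:3) for (k in 1:2) {
    tr <- co$recordings[[i]][[k]]$trace
    truth <- co$recordings[[i]][[k]]$truth
    meas <- resting_membrane_potential(tr, co$protocol)
    t_mid <- tr$t0 + mean(co$protocol$rmp_window)
    offset <- co$cells$offset_end[i] * t_mid / 600
    expect_equal(meas - offset, truth$rmp, tolerance = 0.25)
  }
})

test_that("T3 initial spike counts span the observed range", {
  cf <- fixture_arm("T3", 67, seed = 1)
  counts <- cf$cells$initial_count
  expect_gte(max(counts), 15L)
  expect_equal(min(counts), 0L)
})
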