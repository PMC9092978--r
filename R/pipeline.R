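# End-to-end orchestration: simulate -> extract -> analyze.
#
# The memory-light path simulates one cell at a time, extracts its per-trial
# features and discards the traces, so study-scale cohorts (67 cells x 20
# trials) stay within a laptop's memory at any sampling rate.

features_from_cell <- function(tr_list, protocol, offset_end, cell_id,
                               archetype, kind) {
  rows <- lapply(tr_list, function(s) extract_trial_features(s$trace,
                                                             protocol))
  tf <- do.call(rbind, rows)
  tf <- cbind(data.frame(cell_id = cell_id, archetype = archetype,
                         protocol = kind, stringsAsFactors = FALSE), tf)
  fin <- final_trial_of(protocol)
  cf <- NULL
  if (all(c(1L, fin) %in% tf$trial))
    cf <- delta_features(tf, protocol, offset_end = offset_end)
  list(trial_features = tf, cell_features = cf)
}

#' Simulate a cohort and extract features in one streaming pass
#'
#' Equivalent to [simulate_cohort()] followed by feature extraction, but
#' traces are discarded cell by cell.
#'
#' @param config a [cohort_config()].
#' @param trials trial subset (default: all trials of the protocol).
#' @return list of class `cohort_features`: `trial_features` (one row per
#'   cell x trial, with an `isis` list column), `cells` (one row per cell:
#'   latents, confounders and initial/final/delta features when both end
#'   trials were simulated), `protocol`, `config`.
#' @export
simulate_cohort_features <- function(config, trials = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  protocol <- if (config$protocol == "stim")
    build_stim_protocol(config$sample_rate, seed = config$seed)
  else build_control_protocol(config$sample_rate)
  if (is.null(trials)) trials <- seq_len(protocol$n_trials)
  waveform <- render_waveform(protocol)

  set.seed(config$seed)
  conf <- draw_confounders(config)

  tf_all <- vector("list", config$n_cells)
  cf_all <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    set.seed(child_seed(config$seed, i))
    lat <- sample_cell_latents(config$params, 1L)
    lat$isi_pref <- stats::rnorm(1, config$params$isi_median,
                                 config$params$isi_median *
                                   config$params$isi_cv)
    lat$rmp_shift <- config$rmp_shift
    lat$cell_id <- sprintf("%s_%s_%03d", config$archetype, config$protocol, i)
    exc_mult <- exp(config$temperature_effect * (conf$temperature[i] - 23))
    tr_list <- vector("list", length(trials))
    for (k in seq_along(trials)) {
      set.seed(child_seed(config$seed, i, trials[k]))
      tr_list[[k]] <- simulate_trial(lat, config$params, protocol, trials[k],
                                     noise_sd = config$noise_sd,
                                     waveform = waveform,
                                     exc_multiplier = exc_mult)
    }
    fx <- features_from_cell(tr_list, protocol, lat$offset_end, lat$cell_id,
                             config$archetype, config$protocol)
    tf_all[[i]] <- fx$trial_features
    if (!is.null(fx$cell_features))
      cf_all[[i]] <- cbind(lat, conf[i, , drop = FALSE], fx$cell_features,
                           row.names = NULL)
    else
      cf_all[[i]] <- cbind(lat, conf[i, , drop = FALSE], row.names = NULL)
  }
  structure(list(
    trial_features = if (config$n_cells) do.call(rbind, tf_all) else
      data.frame(),
    cells = if (config$n_cells) do.call(rbind, cf_all) else data.frame(),
    protocol = protocol, config = config, trials = trials),
    class = "cohort_features")
}

#' Extract features from a simulated cohort with kept traces
#'
#' @param cohort an `ephys_cohort` from [simulate_cohort()] with
#'   `keep_traces = TRUE`.
#' @return a `cohort_features` list (see [simulate_cohort_features()]).
#' @export
extract_cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "ephys_cohort"))
  tf_all <- list(); cf_all <- list()
  for (i in seq_len(nrow(cohort$cells))) {
    lat <- cohort$cells[i, , drop = FALSE]
    fx <- features_from_cell(cohort$recordings[[i]], cohort$protocol,
                             lat$offset_end, lat$cell_id,
                             cohort$config$archetype, cohort$config$protocol)
    tf_all[[i]] <- fx$trial_features
    cf_all[[i]] <- if (!is.null(fx$cell_features))
      cbind(lat, fx$cell_features, row.names = NULL) else lat
  }
  structure(list(trial_features = do.call(rbind, tf_all),
                 cells = do.call(rbind, cf_all),
                 protocol = cohort$protocol, config = cohort$config,
                 trials = cohort$trials),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf("<cohort_features> %s/%s: %d cell(s), %d trial rows\n",
              x$config$archetype, x$config$protocol, nrow(x$cells),
              nrow(x$trial_features)))
  invisible(x)
}

#' Pooled inter-spike intervals of a cohort
#'
#' Concatenates the per-trial ISI lists over all trials and cells.
#'
#' @param cf a `cohort_features` object.
#' @param cells optional cell_id subset (e.g. after the inclusion filter).
#' @return numeric vector of ISIs (ms).
#' @export
cohort_pooled_isis <- function(cf, cells = NULL) {
  tf <- cf$trial_features
  if (!is.null(cells)) tf <- tf[tf$cell_id %in% cells, , drop = FALSE]
  pool_isis(tf$isis)
}

#' Full-analysis configuration
#'
#' @param n_stim named vector of stimulation-arm cohort sizes per archetype.
#' @param n_control named vector of control-arm cohort sizes per archetype.
#' @param sample_rate Hz.
#' @param noise_sd membrane noise sd, mV.
#' @param seed master seed; arm seeds are split deterministically from it.
#' @param alpha significance level for the correlation block.
#' @param alpha_comparisons Bonferroni-corrected level for the
#'   protocol-comparison block (alpha/5 by default).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(n_stim = c(T3 = 67, P1 = 29, Rz = 21),
                            n_control = c(T3 = 19, P1 = 22, Rz = 22),
                            sample_rate = 10000, noise_sd = 1.5, seed = 1L,
                            alpha = 0.05,
                            alpha_comparisons = bonferroni_alpha(alpha, 5)) {
  structure(list(n_stim = n_stim, n_control = n_control,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 seed = as.integer(seed), alpha = alpha,
                 alpha_comparisons = alpha_comparisons),
            class = "analysis_config")
}

arm_seed <- function(seed, archetype, kind) {
  offs <- match(archetype, c("T3", "P1", "Rz")) +
    3L * (kind == "control")
  (abs(seed) + 104729L * offs) %% 2147483587L
}

safe_spearman <- function(x, y, alpha, xl, yl) {
  ok <- !(is.na(x) | is.na(y))
  if (sum(ok) < 4L || length(unique(x[ok])) < 2L ||
      length(unique(y[ok])) < 2L)
    return(new_stat_result("spearman", xl, yl, sum(ok), NA_real_, NA_real_,
                           NA_real_, alpha, "not computable"))
  spearman_test(x, y, alpha = alpha, x_label = xl, y_label = yl)
}

spearman_block_rows <- function(cells, alpha) {
  list(
    safe_spearman(cells$temperature, cells$initial_count, alpha,
                  "temperature", "i spike count"),
    safe_spearman(cells$ganglion, cells$initial_count, alpha,
                  "ganglion", "i spike count"),
    safe_spearman(cells$initial_rmp, cells$initial_count, alpha,
                  "i RMP", "i spike count"),
    safe_spearman(cells$initial_rebound, cells$initial_count, alpha,
                  "i rebound spike count", "i spike count"),
    safe_spearman(cells$initial_latency, cells$initial_count, alpha,
                  "i latency", "i spike count"),
    safe_spearman(cells$delta_rmp, cells$delta_count, alpha,
                  "d RMP", "d spike count"),
    safe_spearman(cells$delta_rebound, cells$delta_count, alpha,
                  "d rebound spike count", "d spike count"),
    safe_spearman(cells$delta_latency, cells$delta_count, alpha,
                  "d latency", "d spike count"))
}

na_stat <- function(test, xl, yl, n, alpha) {
  new_stat_result(test, xl, yl, n, NA_real_, NA_real_, NA_real_, alpha,
                  "not computable")
}

wilcoxon_block_rows <- function(stim, cont, alpha, alpha_prime) {
  rows <- list()
  by_exp <- split(stim$initial_count, stim$experimenter)
  rows[[1]] <- if (length(by_exp) == 2L && all(lengths(by_exp) >= 2L))
    rank_sum_test(by_exp[["IA"]], by_exp[["OR"]], alpha = alpha,
                  x_label = "i spike count IA", y_label = "i spike count OR")
  else na_stat("rank_sum", "i spike count IA", "i spike count OR",
               nrow(stim), alpha)
  two <- function(xs, ys, xl, yl)
    if (length(xs[!is.na(xs)]) >= 2L && length(ys[!is.na(ys)]) >= 2L)
      rank_sum_test(xs, ys, alpha = alpha_prime, x_label = xl, y_label = yl)
    else na_stat("rank_sum", xl, yl, 0L, alpha_prime)
  one <- function(ds, xl)
    if (length(ds[!is.na(ds) & ds != 0]) >= 2L)
      signed_rank_test(ds, alpha = alpha_prime, x_label = xl)
    else na_stat("signed_rank", xl, "0", length(ds), alpha_prime)
  rows[[2]] <- two(stim$initial_count, cont$initial_count,
                   "Stim. i spike count", "Cont. i spike count")
  rows[[3]] <- two(stim$final_count, cont$final_count,
                   "Stim. f spike count", "Cont. f spike count")
  rows[[4]] <- two(stim$delta_count, cont$delta_count,
                   "Stim. d spike count", "Cont. d spike count")
  rows[[5]] <- one(stim$delta_count, "Stim. d spike count")
  rows[[6]] <- one(cont$delta_count, "Cont. d spike count")
  rows[[7]] <- two(stim$initial_rmp, cont$initial_rmp,
                   "Stim. i RMP", "Cont. i RMP")
  rows[[8]] <- two(stim$final_rmp, cont$final_rmp,
                   "Stim. f RMP", "Cont. f RMP")
  rows[[9]] <- two(stim$delta_rmp, cont$delta_rmp,
                   "Stim. d RMP", "Cont. d RMP")
  rows[[10]] <- one(stim$delta_rmp, "Stim. d RMP")
  rows[[11]] <- one(cont$delta_rmp, "Cont. d RMP")
  rows
}

#' Confounder analysis on a cell feature table
#'
#' Computes the rank correlation of the initial spike count with temperature
#' and with ganglion position, the rank-sum comparison between
#' experimenters, and the leech x preparation initial-count matrix restricted
#' to leeches contributing at least `min_preparations` preparations.
#'
#' @param cells cell feature table (after inclusion filtering) carrying
#'   `temperature`, `leech_id`, `ganglion`, `preparation`, `experimenter`
#'   and `initial_count`.
#' @param alpha significance level.
#' @param min_preparations minimum preparations per leech for the matrix.
#' @return list: `tests` (list of `stat_result`), `leech_matrix` (leeches x
#'   preparation order, NA-padded; zero rows when no leech qualifies).
#' @export
confounder_analysis <- function(cells, alpha = 0.05, min_preparations = 3L) {
  tests <- list()
  for (col in c("temperature", "ganglion")) {
    if (!col %in% names(cells)) {
      warning("missing confounder column: ", col, "; row skipped")
      next
    }
    tests[[col]] <- safe_spearman(cells[[col]], cells$initial_count, alpha,
                                  col, "i spike count")
  }
  if ("experimenter" %in% names(cells)) {
    by_exp <- split(cells$initial_count, cells$experimenter)
    tests[["experimenter"]] <-
      if (length(by_exp) == 2L && all(lengths(by_exp) >= 2L))
        rank_sum_test(by_exp[[1]], by_exp[[2]], alpha = alpha,
                      x_label = paste("i spike count", names(by_exp)[1]),
                      y_label = paste("i spike count", names(by_exp)[2]))
      else na_stat("rank_sum", "i spike count by experimenter", "",
                   nrow(cells), alpha)
  } else warning("missing confounder column: experimenter; row skipped")
  tab <- table(cells$leech_id)
  keep_leech <- names(tab)[tab >= min_preparations]
  if (!length(keep_leech)) {
    warning("no leech with >= ", min_preparations,
            " preparations; empty leech matrix")
    mat <- matrix(numeric(0), 0, 0)
  } else {
    sub <- cells[cells$leech_id %in% keep_leech, , drop = FALSE]
    ncol_max <- max(sub$preparation)
    mat <- matrix(NA_real_, length(keep_leech), ncol_max,
                  dimnames = list(paste0("leech_", keep_leech),
                                  paste0("prep_", seq_len(ncol_max))))
    for (j in seq_len(nrow(sub)))
      mat[paste0("leech_", sub$leech_id[j]),
          paste0("prep_", sub$preparation[j])] <- sub$initial_count[j]
  }
  list(tests = tests, leech_matrix = mat)
}

summarize_arm <- function(cells, cf) {
  pooled <- cohort_pooled_isis(cf, cells$cell_id)
  lat <- cells$initial_latency[!is.na(cells$initial_latency)]
  data.frame(
    archetype = cf$config$archetype,
    n = nrow(cells),
    median_initial_rmp = stats::median(cells$initial_rmp),
    median_initial_count = stats::median(cells$initial_count),
    cv_initial_count = coefficient_of_variation(cells$initial_count),
    median_initial_latency = stats::median(lat),
    cv_initial_latency = coefficient_of_variation(lat),
    median_pooled_isi = stats::median(pooled),
    cv_pooled_isi = coefficient_of_variation(pooled),
    median_input_resistance = stats::median(cells$initial_input_resistance),
    median_sag_ratio = stats::median(cells$initial_sag_ratio),
    median_delta_count = stats::median(cells$delta_count),
    median_delta_rmp = stats::median(cells$delta_rmp))
}

#' Run the full simulate-extract-analyze pipeline
#'
#' Simulates one stimulation and one control arm for each archetype, applies
#' the inclusion filter, extracts features, and assembles the
#' interdependency (Spearman, at `alpha`) and protocol-comparison (Wilcoxon,
#' at the Bonferroni-corrected `alpha_comparisons`) tables plus the
#' confounder analysis of the T3 stimulation arm. Deterministic given the
#' config seed.
#'
#' @param config an [analysis_config()].
#' @return list of class `analysis_report`: `summary`, `interdependency`,
#'   `comparison`, `confounders`, `arms` (the included cell tables),
#'   `exclusions`, `provenance`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  archetypes <- c("T3", "P1", "Rz")
  arms <- list()
  excl <- list()
  for (at in archetypes) {
    for (kind in c("stim", "control")) {
      n <- if (kind == "stim") config$n_stim[[at]] else config$n_control[[at]]
      cc <- cohort_config(at, kind, n_cells = n,
                          sample_rate = config$sample_rate,
                          noise_sd = config$noise_sd,
                          seed = arm_seed(config$seed, at, kind))
      cf <- simulate_cohort_features(cc)
      inc <- apply_inclusion_filter(cf$cells)
      excl[[paste(at, kind, sep = "_")]] <- attr(inc, "excluded")
      arms[[paste(at, kind, sep = "_")]] <- list(cells = inc, features = cf)
    }
  }
  inter <- list(); comp <- list(); summ <- list()
  for (at in archetypes) {
    stim <- arms[[paste0(at, "_stim")]]
    cont <- arms[[paste0(at, "_control")]]
    summ[[at]] <- summarize_arm(stim$cells, stim$features)
    rows <- if (nrow(stim$cells) >= 4L)
      spearman_block_rows(stim$cells, config$alpha)
    else replicate(8, na_stat("spearman", "", "", nrow(stim$cells),
                              config$alpha), simplify = FALSE)
    inter[[at]] <- cbind(archetype = at, stat_results_table(rows))
    comp[[at]] <- cbind(archetype = at,
                        stat_results_table(
                          wilcoxon_block_rows(stim$cells, cont$cells,
                                              config$alpha,
                                              config$alpha_comparisons)))
  }
  confounders <- confounder_analysis(arms[["T3_stim"]]$cells,
                                     alpha = config$alpha)
  structure(list(
    summary = do.call(rbind, summ),
    interdependency = do.call(rbind, inter),
    comparison = do.call(rbind, comp),
    confounders = confounders,
    arms = lapply(arms, `[[`, "cells"),
    exclusions = excl,
    provenance = list(seed = config$seed, sample_rate = config$sample_rate,
                      noise_sd = config$noise_sd,
                      package_version =
                        as.character(utils::packageVersion("ephyscohort")),
                      timestamp = NA)),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("=== Cohort summary (stimulation arms, after inclusion filter) ===\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat("\n=== Interdependencies (Spearman rank correlations) ===\n")
  it <- x$interdependency
  it$p <- NULL
  print(it, row.names = FALSE, digits = 3)
  cat("\n=== Protocol comparisons (Wilcoxon tests) ===\n")
  ct <- x$comparison
  ct$p <- NULL
  print(ct, row.names = FALSE, digits = 3)
  cat("\n=== Confounders (T3 stimulation arm) ===\n")
  for (s in x$confounders$tests) print(s)
  cat(sprintf("leech matrix: %d leech(es) with >= 3 preparations\n",
              nrow(x$confounders$leech_matrix)))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `table1.csv` (interdependency + comparison rows), `deltas.csv`
#' (per-cell initial/final/delta features of every arm), `confounders.csv`,
#' `summary.csv` and a plain-text `report.txt`. Re-running the pipeline with
#' the same config yields byte-identical files.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  tab1 <- rbind(cbind(block = "spearman", report$interdependency),
                cbind(block = "wilcoxon", report$comparison))
  utils::write.csv(tab1, file.path(dir, "table1.csv"), row.names = FALSE)
  keep <- c("cell_id", "archetype", "experimenter", "temperature",
            "leech_id", "ganglion", "preparation",
            "initial_rmp", "final_rmp", "delta_rmp",
            "initial_count", "final_count", "delta_count",
            "initial_rebound", "final_rebound", "delta_rebound",
            "initial_latency", "final_latency", "delta_latency",
            "initial_sag_ratio", "initial_input_resistance")
  deltas <- do.call(rbind, lapply(names(report$arms), function(nm) {
    d <- report$arms[[nm]]
    d <- d[, intersect(keep, names(d)), drop = FALSE]
    cbind(arm = nm, d)
  }))
  utils::write.csv(deltas, file.path(dir, "deltas.csv"), row.names = FALSE)
  conf <- stat_results_table(report$confounders$tests)
  utils::write.csv(conf, file.path(dir, "confounders.csv"),
                   row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
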