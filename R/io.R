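# Plain-text trace container: one CSV per trial (columns time s, voltage mV,
# current nA) with a commented header carrying the recording metadata and
# ground-truth spike times, plus a cohort manifest CSV. The same schema can
# hold externally recorded traces for re-analysis.

#' Write one trace to the CSV trace container
#'
#' @param trace an `ephys_trace`.
#' @param path output path.
#' @param archetype optional archetype tag stored in the header.
#' @export
write_trace_csv <- function(trace, path, archetype = NA_character_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_rate_hz: %g", trace$sample_rate),
    sprintf("# trial_index: %d", trace$trial_index),
    sprintf("# t0_s: %g", trace$t0),
    sprintf("# archetype: %s", archetype),
    sprintf("# true_spike_times_s: %s",
            paste(sprintf("%.6f", trace$true_spikes), collapse = ";"))),
    con)
  n <- length(trace$voltage)
  df <- data.frame(time = (seq_len(n) - 1L) / trace$sample_rate,
                   voltage_mV = trace$voltage,
                   current_nA = trace$current)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trace back from the CSV trace container
#'
#' @param path path written by [write_trace_csv()].
#' @return an `ephys_trace` (with `true_spikes` when present in the header).
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("# ", key, ":"), "", ln[1], fixed = TRUE))
  }
  df <- utils::read.csv(path, comment.char = "#")
  spikes_raw <- get("true_spike_times_s")
  spikes <- if (is.na(spikes_raw) || !nzchar(spikes_raw)) numeric(0) else
    as.numeric(strsplit(spikes_raw, ";", fixed = TRUE)[[1]])
  structure(list(voltage = df$voltage_mV, current = df$current_nA,
                 sample_rate = as.numeric(get("sample_rate_hz")),
                 trial_index = as.integer(get("trial_index")),
                 t0 = as.numeric(get("t0_s")),
                 true_spikes = spikes),
            class = "ephys_trace")
}

#' Write a simulated cohort (traces + manifest) to a directory
#'
#' One CSV per cell and trial (`<cell_id>_trial<k>.csv`) plus
#' `manifest.csv` with the cell metadata and confounders.
#'
#' @param cohort an `ephys_cohort` simulated with `keep_traces = TRUE`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ephys_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort$cells))) {
    id <- cohort$cells$cell_id[i]
    for (k in seq_along(cohort$trials)) {
      tr <- cohort$recordings[[i]][[k]]$trace
      if (is.null(tr))
        stop("cohort was simulated with keep_traces = FALSE")
      write_trace_csv(tr, file.path(dir, sprintf("%s_trial%02d.csv", id,
                                                 cohort$trials[k])),
                      archetype = cohort$config$archetype)
    }
  }
  manifest <- cohort$cells[, c("cell_id", "temperature", "leech_id",
                               "ganglion", "preparation", "experimenter")]
  manifest$archetype <- cohort$config$archetype
  manifest$protocol <- cohort$config$protocol
  manifest$seed <- cohort$config$seed
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
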