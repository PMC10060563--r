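#' Write one recording in the documented trace format
#'
#' Per cell, two files are written: `<cell_id>.json` with the metadata
#' (identifiers, sampling rate, epoch durations in ms, step currents in pA,
#' ground truth when present) and `<cell_id>.csv`, a matrix with one column
#' per sweep (in protocol order) and one row per sample, voltage in mV.
#'
#' @param rec a `recording`.
#' @param dir output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(cell_id = rec$cell_id, animal_id = rec$animal_id,
               sampling_rate_hz = rec$protocol$sampling_rate_hz,
               baseline_ms = rec$protocol$baseline_ms,
               step_ms = rec$protocol$step_ms,
               post_ms = rec$protocol$post_ms,
               currents_pA = rec$protocol$currents_pA)
  if (!is.null(rec$ground_truth)) {
    gt <- rec$ground_truth
    meta$ground_truth <- list(
      rheobase_pA = gt$rheobase_pA, tau_ms = gt$tau_ms,
      rm_mohm = gt$params$rm_mohm, cm_pf = gt$params$cm_pf,
      el_mv = gt$params$el_mv, vth_mv = gt$params$vth_mv,
      vreset_mv = gt$params$vreset_mv, tref_ms = gt$params$tref_ms,
      noise_sd_mv = gt$params$noise_sd_mv,
      spike_counts_step = gt$spike_counts_step)
  }
  jpath <- file.path(dir, paste0(rec$cell_id, ".json"))
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  m <- rec$sweeps
  colnames(m) <- sprintf("sweep_%d", seq_len(ncol(m)))
  write.csv(m, file.path(dir, paste0(rec$cell_id, ".csv")), row.names = FALSE)
  invisible(jpath)
}

#' Read a recording written by [write_recording()]
#'
#' @param json_path path to the `<cell_id>.json` metadata file; the sweep
#'   matrix is read from the CSV of the same stem.
#' @return A `recording`.
#' @export
read_recording <- function(json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  csv_path <- sub("\\.json$", ".csv", json_path)
  if (!file.exists(csv_path)) stop("sweep matrix not found: ", csv_path)
  sweeps <- as.matrix(read.csv(csv_path))
  dimnames(sweeps) <- NULL
  protocol <- step_protocol(currents_pA = meta$currents_pA,
                            baseline_ms = meta$baseline_ms,
                            step_ms = meta$step_ms, post_ms = meta$post_ms,
                            sampling_rate_hz = meta$sampling_rate_hz)
  if (ncol(sweeps) != length(protocol$currents_pA))
    stop("sweep count does not match protocol currents in ", csv_path)
  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    g <- meta$ground_truth
    params <- neuron_params(rm_mohm = g$rm_mohm, cm_pf = g$cm_pf,
                            el_mv = g$el_mv, vth_mv = g$vth_mv,
                            vreset_mv = g$vreset_mv, tref_ms = g$tref_ms,
                            noise_sd_mv = g$noise_sd_mv)
    gt <- list(params = params, rheobase_pA = g$rheobase_pA,
               tau_ms = g$tau_ms,
               spike_counts_step = as.integer(g$spike_counts_step))
  }
  structure(list(sweeps = sweeps, protocol = protocol,
                 cell_id = meta$cell_id, animal_id = meta$animal_id,
                 ground_truth = gt),
            class = "recording")
}

#' Write a synthetic cohort to disk
#'
#' Writes `behavior.csv` (final-timepoint behavioural table),
#' `pwt_timecourse.csv`, `ground_truth.json` and one JSON + CSV trace pair
#' per cell under `traces/`.
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_behavior_table(cohort$behavior, file.path(dir, "behavior.csv"))
  write.csv(cohort$pwt_timecourse, file.path(dir, "pwt_timecourse.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(per_animal = cohort$ground_truth$per_animal,
         true_r = cohort$ground_truth$true_r,
         seed = cohort$config$seed),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$recordings)) {
    tdir <- file.path(dir, "traces")
    for (rl in cohort$recordings)
      for (rec in rl) write_recording(rec, tdir)
  }
  invisible(dir)
}

#' Read all recordings from a trace directory
#'
#' @param dir directory holding `<cell_id>.json` / `<cell_id>.csv` pairs
#'   (a `traces/` directory written by [write_cohort()]).
#' @return A list of `recording` objects, sorted by file name.
#' @export
read_trace_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stop("no .json trace metadata found in ", dir)
  lapply(files, read_recording)
}
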