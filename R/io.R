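SCHEMA_VERSION <- "1.0"

#' Write a session to a directory of CSV files
#'
#' Writes `spikes.csv` (`neuron_id`, `spike_time_s`), `trials.csv`
#' (`onset_s`, `stimulus_id`, `role`, `period`, `block_id`, `running`),
#' `stimuli.csv` (the [stimulusSpec()] columns), optionally `motion.csv`
#' (`frame`, `motion_energy`), and `session.json` with the schema version
#' and frame rate. The round trip through [readSession()] is lossless at
#' the written numeric precision.
#'
#' @param session An [OddballSession-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- spikeTimes(session)
  spikes <- data.frame(
    neuron_id = rep(names(sp), lengths(sp)),
    spike_time_s = unlist(sp, use.names = FALSE))
  write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  write.csv(trialInfo(session)[TRIAL_COLUMNS], file.path(dir, "trials.csv"),
            row.names = FALSE)
  write.csv(stimulusInfo(session), file.path(dir, "stimuli.csv"),
            row.names = FALSE)
  meta <- list(schema_version = SCHEMA_VERSION,
               frame_rate_hz = session@frameRateHz,
               neuron_ids = names(sp))
  if (length(motionTrace(session)))
    write.csv(data.frame(frame = seq_along(motionTrace(session)),
                         motion_energy = motionTrace(session)),
              file.path(dir, "motion.csv"), row.names = FALSE)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

requireColumns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Read a session from a directory of CSV files
#'
#' Counterpart of [writeSession()]. Schema violations (missing columns,
#' unsorted onsets, unknown role or period labels) raise an error naming the
#' offending file and field. Neurons listed in `session.json` but absent
#' from `spikes.csv` are retained with zero spikes, with a warning.
#'
#' @param dir Directory holding `spikes.csv`, `trials.csv`, `stimuli.csv`
#'   and `session.json` (plus optional `motion.csv`).
#' @return An [OddballSession-class].
#' @export
readSession <- function(dir) {
  trials <- read.csv(file.path(dir, "trials.csv"),
                     stringsAsFactors = FALSE)
  requireColumns(trials, TRIAL_COLUMNS, "trials.csv")
  v <- validTrialTable(trials)
  if (!isTRUE(v)) stop(sprintf("trials.csv: %s", v), call. = FALSE)
  trials$running <- as.logical(trials$running)
  stimuli <- read.csv(file.path(dir, "stimuli.csv"),
                      stringsAsFactors = FALSE)
  requireColumns(stimuli, c("stimulus_id", "kind", "center_khz",
                            "duration_s"), "stimuli.csv")
  spikes <- read.csv(file.path(dir, "spikes.csv"), stringsAsFactors = FALSE)
  requireColumns(spikes, c("neuron_id", "spike_time_s"), "spikes.csv")
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  ids <- if (!is.null(meta$neuron_ids)) meta$neuron_ids
         else unique(spikes$neuron_id)
  spl <- split(spikes$spike_time_s, factor(spikes$neuron_id, levels = ids))
  empty <- names(spl)[lengths(spl) == 0]
  if (length(empty))
    warning(sprintf("neuron(s) with no spikes retained: %s",
                    paste(empty, collapse = ", ")))
  spl <- lapply(spl, sort)
  motionPath <- file.path(dir, "motion.csv")
  motion <- if (file.exists(motionPath))
    read.csv(motionPath)$motion_energy else numeric(0)
  oddballSession(spl, trials, stimuli, motion = motion,
                 frameRateHz = if (!is.null(meta$frame_rate_hz))
                   meta$frame_rate_hz else 30,
                 metadata = list(schema_version = meta$schema_version))
}
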