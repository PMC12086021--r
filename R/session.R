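#' Response-window definition
#'
#' The two counting windows used throughout the analysis, relative to each
#' stimulus onset: a baseline window of -200 ms to 0 ms, and an evoked
#' window from 15 ms after onset to 15 ms after offset (the latency shift
#' compensates ear-to-cortex transmission delay and applies to both edges,
#' so the evoked window length equals the stimulus duration).
#'
#' @param latencyS Evoked-window latency shift (s).
#' @param baselineS Length-2 baseline window relative to onset (s).
#' @return A list with class `ResponseWindows`.
#' @examples
#' responseWindows()
#' @export
responseWindows <- function(latencyS = 0.015, baselineS = c(-0.2, 0)) {
  stopifnot(length(baselineS) == 2, baselineS[1] < baselineS[2])
  structure(list(latencyS = latencyS, baselineS = baselineS),
            class = "ResponseWindows")
}

#' Align spikes to trials and extract windowed firing rates
#'
#' Counts each neuron's spikes in the baseline and evoked windows of every
#' trial (half-open intervals `[start, end)`) and converts counts to rates
#' by the window lengths. The evoked window runs from `onset + latency` to
#' `onset + duration + latency`, so its length is the stimulus duration.
#'
#' @param session An [OddballSession-class].
#' @param windows A [responseWindows()] definition.
#' @return A [SummarizedExperiment::SummarizedExperiment] with one row per
#'   neuron and one column per trial; assays `evoked_count`,
#'   `baseline_count`, `evoked_rate`, `baseline_rate` (spk/s); `colData`
#'   carries the trial table plus `duration_s`.
#' @examples
#' s <- simulateSession(simConfig(nNeurons = 2, tuningReps = 1,
#'                                minOddballs = 2, seed = 1))
#' se <- alignAndCount(s)
#' SummarizedExperiment::assayNames(se)
#' @export
alignAndCount <- function(session, windows = responseWindows()) {
  trials <- trialInfo(session)
  stimuli <- stimulusInfo(session)
  dur <- stimuli$duration_s[match(trials$stimulus_id, stimuli$stimulus_id)]
  evStart <- trials$onset_s + windows$latencyS
  evEnd <- evStart + dur
  blStart <- trials$onset_s + windows$baselineS[1]
  blEnd <- trials$onset_s + windows$baselineS[2]
  blLen <- diff(windows$baselineS)
  neurons <- names(spikeTimes(session))
  n <- length(neurons); m <- nrow(trials)
  ec <- bc <- matrix(0L, n, m, dimnames = list(neurons, NULL))
  for (i in seq_len(n)) {
    sp <- spikeTimes(session)[[i]]
    ec[i, ] <- countInWindows(sp, evStart, evEnd)
    bc[i, ] <- countInWindows(sp, blStart, blEnd)
  }
  cd <- S4Vectors::DataFrame(
    trials, duration_s = dur,
    center_khz = stimuli$center_khz[match(trials$stimulus_id,
                                          stimuli$stimulus_id)])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(evoked_count = ec, baseline_count = bc,
                  evoked_rate = sweep(ec, 2, dur, "/"),
                  baseline_rate = bc / blLen),
    colData = cd,
    rowData = S4Vectors::DataFrame(neuron_id = neurons),
    metadata = list(windows = windows))
}

#' Tidy per-trial responses
#'
#' Flattens an [alignAndCount()] SummarizedExperiment into a long
#' `data.frame` with one row per neuron x trial — the working format of the
#' filter, tuning, deviance and variability analyses.
#'
#' @param se SummarizedExperiment from [alignAndCount()].
#' @param neurons Optional subset of neuron ids.
#' @return `data.frame` with columns `neuron_id`, trial attributes
#'   (`onset_s`, `stimulus_id`, `role`, `period`, `block_id`, `running`,
#'   `duration_s`), `evoked_count`, `baseline_count`, `evoked_rate`,
#'   `baseline_rate`.
#' @export
trialResponses <- function(se, neurons = NULL) {
  ids <- SummarizedExperiment::rowData(se)$neuron_id
  if (is.null(neurons)) neurons <- ids
  keep <- match(neurons, ids)
  stopifnot(!anyNA(keep))
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  m <- nrow(cd)
  out <- cbind(
    data.frame(neuron_id = rep(neurons, each = m),
               stringsAsFactors = FALSE),
    cd[rep(seq_len(m), times = length(neurons)), , drop = FALSE])
  for (a in c("evoked_count", "baseline_count", "evoked_rate",
              "baseline_rate"))
    out[[a]] <- as.vector(t(SummarizedExperiment::assay(se, a)[keep, ,
                                                               drop = FALSE]))
  rownames(out) <- NULL
  out
}
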