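#' @import methods
NULL

TRIAL_COLUMNS <- c("onset_s", "stimulus_id", "role", "period", "block_id",
                   "running")

validTrialTable <- function(trials) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    return(sprintf("trial table lacks column(s): %s",
                   paste(missing, collapse = ", ")))
  if (nrow(trials) > 1 && any(diff(trials$onset_s) <= 0))
    return("trial onsets must be strictly increasing")
  if (!all(trials$role %in% ROLES))
    return(sprintf("unknown role label(s): %s",
                   paste(unique(setdiff(trials$role, ROLES)), collapse = ", ")))
  if (!all(trials$period %in% PERIODS))
    return(sprintf("unknown period label(s): %s",
                   paste(unique(setdiff(trials$period, PERIODS)),
                         collapse = ", ")))
  TRUE
}

#' OddballSession: one recording session
#'
#' Container for a trial-based extracellular recording session: spike
#' timestamps of isolated single units, the stimulus presentation (trial)
#' table, the stimulus dictionary, and an optional motion-energy trace used
#' for locomotion-state classification.
#'
#' @slot spikes Named list of sorted numeric spike-time vectors (seconds from
#'   session start), one element per neuron.
#' @slot trials `data.frame` with one row per stimulus presentation and
#'   columns `onset_s`, `stimulus_id`, `role` (standard/oddball/tuning),
#'   `period` (pre/saline/doi), `block_id`, `running` (logical, `NA` =
#'   unknown).
#' @slot stimuli Stimulus dictionary as returned by [stimulusSpec()], one row
#'   per distinct `stimulus_id`.
#' @slot motion Numeric motion-energy trace sampled at `frameRateHz`
#'   (length 0 when no video was recorded).
#' @slot frameRateHz Frame rate of the motion trace in Hz.
#' @slot metadata Free-form list (simulation ground truth, provenance, ...).
#' @export
setClass("OddballSession",
  representation(spikes = "list", trials = "data.frame",
                 stimuli = "data.frame", motion = "numeric",
                 frameRateHz = "numeric", metadata = "list"),
  prototype(motion = numeric(0), frameRateHz = 30, metadata = list()))

setValidity("OddballSession", function(object) {
  msgs <- character(0)
  v <- validTrialTable(object@trials)
  if (!isTRUE(v)) msgs <- c(msgs, v)
  if (length(object@spikes) && is.null(names(object@spikes)))
    msgs <- c(msgs, "spike list must be named by neuron id")
  bad <- vapply(object@spikes, function(s) is.unsorted(s) || any(s < 0),
                logical(1))
  if (any(bad))
    msgs <- c(msgs, sprintf("unsorted or negative spike times for: %s",
                            paste(names(object@spikes)[bad], collapse = ", ")))
  unknown <- setdiff(object@trials$stimulus_id, object@stimuli$stimulus_id)
  if (length(unknown))
    msgs <- c(msgs, sprintf("trials reference undescribed stimuli: %s",
                            paste(unique(unknown), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct an OddballSession
#'
#' @param spikes Named list of sorted spike-time vectors (seconds).
#' @param trials Trial table (see [OddballSession-class]).
#' @param stimuli Stimulus dictionary ([stimulusSpec()] rows).
#' @param motion Optional motion-energy trace.
#' @param frameRateHz Motion-trace frame rate (Hz).
#' @param metadata Optional list of session metadata.
#' @return A validated [OddballSession-class] object.
#' @export
oddballSession <- function(spikes, trials, stimuli, motion = numeric(0),
                           frameRateHz = 30, metadata = list()) {
  trials$stimulus_id <- as.character(trials$stimulus_id)
  trials$role <- as.character(trials$role)
  trials$period <- as.character(trials$period)
  new("OddballSession", spikes = spikes, trials = trials, stimuli = stimuli,
      motion = as.numeric(motion), frameRateHz = frameRateHz,
      metadata = metadata)
}

#' @describeIn OddballSession-class spike-time list accessor
#' @param object,x An `OddballSession`.
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname OddballSession-class
#' @export
setMethod("spikeTimes", "OddballSession", function(object) object@spikes)

#' @describeIn OddballSession-class trial-table accessor
#' @export
setGeneric("trialInfo", function(object) standardGeneric("trialInfo"))
#' @rdname OddballSession-class
#' @export
setMethod("trialInfo", "OddballSession", function(object) object@trials)

#' @describeIn OddballSession-class stimulus-dictionary accessor
#' @export
setGeneric("stimulusInfo", function(object) standardGeneric("stimulusInfo"))
#' @rdname OddballSession-class
#' @export
setMethod("stimulusInfo", "OddballSession", function(object) object@stimuli)

#' @describeIn OddballSession-class motion-energy trace accessor
#' @export
setGeneric("motionTrace", function(object) standardGeneric("motionTrace"))
#' @rdname OddballSession-class
#' @export
setMethod("motionTrace", "OddballSession", function(object) object@motion)

#' @describeIn OddballSession-class session metadata accessor
#' @importFrom S4Vectors metadata
#' @export
setMethod("metadata", "OddballSession", function(x, ...) x@metadata)

#' @rdname OddballSession-class
#' @export
setMethod("show", "OddballSession", function(object) {
  tr <- object@trials
  cat("OddballSession with", length(object@spikes), "neurons,",
      nrow(tr), "trials\n")
  cat("  periods:", paste(sprintf("%s (%d)", PERIODS,
      vapply(PERIODS, function(p) sum(tr$period == p), integer(1))),
      collapse = ", "), "\n")
  cat("  roles:  ", paste(sprintf("%s (%d)", ROLES,
      vapply(ROLES, function(r) sum(tr$role == r), integer(1))),
      collapse = ", "), "\n")
  cat("  stimuli:", paste(object@stimuli$stimulus_id, collapse = ", "), "\n")
  if (length(object@motion))
    cat("  motion trace:", length(object@motion), "frames @",
        object@frameRateHz, "Hz\n")
})

#' Gaussian frequency-tuning fit
#'
#' Result of fitting `r(x) = b + A exp(-(x - mu)^2 / (2 sigma^2))` to mean
#' evoked rates on `x = log2(frequency in kHz)`.
#'
#' @slot bfKhz Best frequency: Gaussian peak position, back on the kHz scale.
#' @slot sigmaLog2 Gaussian SD in octaves.
#' @slot amplitude Gaussian height `A` (spk/s), negative for suppressed cells.
#' @slot offset Fitted offset `b` (spk/s).
#' @slot baselineRate Reference baseline rate used for `maxDeltaFiring`
#'   (the fitted offset when no measured baseline is supplied).
#' @slot maxDeltaFiring Gaussian peak rate minus `baselineRate` (spk/s).
#' @slot rSquared Coefficient of determination against per-frequency means.
#' @slot converged Whether the optimizer converged from any start.
#' @export
setClass("TuningFit",
  representation(bfKhz = "numeric", sigmaLog2 = "numeric",
                 amplitude = "numeric", offset = "numeric",
                 baselineRate = "numeric", maxDeltaFiring = "numeric",
                 rSquared = "numeric", converged = "logical"))

setValidity("TuningFit", function(object) {
  if (length(object@sigmaLog2) && isTRUE(object@converged) &&
      object@sigmaLog2 <= 0)
    return("sigmaLog2 must be positive")
  if (length(object@rSquared) && is.finite(object@rSquared) &&
      object@rSquared > 1 + 1e-12)
    return("rSquared cannot exceed 1")
  TRUE
})

#' @describeIn TuningFit-class full width at half maximum in octaves
#'   (`2.355 * sigmaLog2`)
#' @param object A `TuningFit`.
#' @export
setGeneric("widthOctaves", function(object) standardGeneric("widthOctaves"))
#' @rdname TuningFit-class
#' @export
setMethod("widthOctaves", "TuningFit",
          function(object) 2.355 * object@sigmaLog2)

#' @rdname TuningFit-class
#' @export
setMethod("show", "TuningFit", function(object) {
  cat(sprintf(paste0("TuningFit: BF %.2f kHz, sigma %.3f oct ",
                     "(width %.3f oct), max Δ firing %.2f spk/s, ",
                     "R² %.3f%s\n"),
              object@bfKhz, object@sigmaLog2, widthOctaves(object),
              object@maxDeltaFiring, object@rSquared,
              if (object@converged) "" else " [not converged]"))
})
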