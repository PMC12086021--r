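#' Describe a stimulus
#'
#' Builds a one-row stimulus table describing a pure tone, a narrowband chord,
#' or a frequency-modulated (FM) sweep. Chords are composed of 12 simultaneous
#' pure tones logarithmically spaced between `f/1.2` and `f * 1.2` for center
#' frequency `f`; FM sweeps traverse `freqKhz[1]` to `freqKhz[2]`.
#'
#' The `center_khz` column carries the frequency at which a neuron's tuning
#' curve is evaluated when simulating responses: the tone frequency, the chord
#' center, or the geometric mean of the sweep range.
#'
#' @param id Stimulus label (character scalar).
#' @param kind One of `"pure_tone"`, `"chord"`, `"fm_sweep"`.
#' @param freqKhz Frequency in kHz: a scalar for tones and chords (the center
#'   frequency), a length-2 `c(start, end)` vector for sweeps.
#' @param durationS Duration in seconds (> 0).
#' @param levelDb Sound level in dB SPL.
#' @param nComponents Number of chord components; must be 12 for chords.
#' @return A one-row `data.frame` with columns `stimulus_id`, `kind`,
#'   `center_khz`, `freq_low_khz`, `freq_high_khz`, `duration_s`, `level_db`,
#'   `n_components`.
#' @examples
#' stimulusSpec("hi_chord", "chord", 13, 0.05, levelDb = 50)
#' stimulusSpec("upsweep", "fm_sweep", c(8, 13), 0.1)
#' @export
stimulusSpec <- function(id, kind = c("pure_tone", "chord", "fm_sweep"),
                         freqKhz, durationS, levelDb = 70, nComponents = 12L) {
  kind <- match.arg(kind)
  if (!is.numeric(durationS) || durationS <= 0)
    stop("durationS must be > 0")
  if (kind == "fm_sweep") {
    if (length(freqKhz) != 2 || freqKhz[1] == freqKhz[2])
      stop("fm_sweep needs distinct start and end frequencies")
    lo <- min(freqKhz); hi <- max(freqKhz)
    center <- sqrt(lo * hi)
    nComponents <- NA_integer_
  } else {
    if (length(freqKhz) != 1 || freqKhz <= 0)
      stop("freqKhz must be a positive scalar for tones and chords")
    center <- freqKhz
    if (kind == "chord") {
      if (nComponents != 12L)
        stop("chords are composed of 12 simultaneous pure tones")
      lo <- freqKhz / 1.2; hi <- freqKhz * 1.2
    } else {
      lo <- hi <- freqKhz
      nComponents <- 1L
    }
  }
  data.frame(stimulus_id = as.character(id), kind = kind,
             center_khz = center, freq_low_khz = lo, freq_high_khz = hi,
             duration_s = durationS, level_db = levelDb,
             n_components = as.integer(nComponents),
             stringsAsFactors = FALSE)
}

#' Component frequencies of a chord stimulus
#'
#' @param centerKhz Chord center frequency in kHz.
#' @param n Number of components (12 by convention).
#' @return Numeric vector of component frequencies, logarithmically spaced in
#'   `[centerKhz / 1.2, centerKhz * 1.2]`.
#' @examples
#' chordComponents(8)
#' @export
chordComponents <- function(centerKhz, n = 12L) {
  exp(seq(log(centerKhz / 1.2), log(centerKhz * 1.2), length.out = n))
}

#' Frequencies of the standard tuning ensemble
#'
#' @param n Number of frequencies.
#' @param rangeKhz Frequency range in kHz.
#' @return `n` logarithmically spaced frequencies spanning `rangeKhz`.
#' @examples
#' tuningFrequencies()
#' @export
tuningFrequencies <- function(n = 16L, rangeKhz = c(2, 40)) {
  2^seq(log2(rangeKhz[1]), log2(rangeKhz[2]), length.out = n)
}

#' Default stimulus ensembles
#'
#' The three paradigm ensembles: 16 pure tones logarithmically spaced from
#' 2 to 40 kHz (100 ms, 70 dB SPL), two 12-component chords centered at 8
#' and 13 kHz (50 ms, 50 dB SPL per component), and an 8-13 kHz FM up/down
#' sweep pair (100 ms, 70 dB SPL).
#'
#' @param durationS Stimulus duration in seconds.
#' @return A stimulus table ([stimulusSpec()] rows).
#' @examples
#' defaultChordStimuli()
#' @export
defaultTuningStimuli <- function(durationS = 0.1) {
  freqs <- tuningFrequencies()
  do.call(rbind, lapply(seq_along(freqs), function(i)
    stimulusSpec(sprintf("tone_%04.1fkHz", freqs[i]), "pure_tone",
                 freqs[i], durationS)))
}

#' @rdname defaultTuningStimuli
#' @export
defaultChordStimuli <- function(durationS = 0.05) {
  rbind(stimulusSpec("chord_8kHz", "chord", 8, durationS, levelDb = 50),
        stimulusSpec("chord_13kHz", "chord", 13, durationS, levelDb = 50))
}

#' @rdname defaultTuningStimuli
#' @export
defaultFmStimuli <- function(durationS = 0.1) {
  rbind(stimulusSpec("fm_up", "fm_sweep", c(8, 13), durationS),
        stimulusSpec("fm_down", "fm_sweep", c(13, 8), durationS))
}
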