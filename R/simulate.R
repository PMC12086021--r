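#' Build a frequency-tuning block
#'
#' One block of the tuning ensemble: each of the 16 logarithmically spaced
#' frequencies (2-40 kHz) presented `nReps` times in randomized order, with
#' silent inter-stimulus intervals drawn uniformly from `isiRangeS` (so
#' consecutive onsets are separated by the tone duration plus that interval).
#'
#' @param nReps Repetitions per frequency (>= 1).
#' @param period Period label (`pre`, `saline`, `doi`).
#' @param stimuli Stimulus dictionary for the block; defaults to the 16-tone
#'   ensemble.
#' @param isiRangeS Silent-interval range in seconds.
#' @param startS Session time of the first onset.
#' @param blockId Integer block label.
#' @param seed Optional seed (see [withSeed()]); `NULL` uses the current RNG
#'   stream.
#' @return List with elements `trials` (trial table rows) and `stimuli`.
#' @examples
#' blk <- tuningBlock(nReps = 2, seed = 1)
#' table(blk$trials$stimulus_id)
#' @export
tuningBlock <- function(nReps = 20, period = "pre",
                        stimuli = defaultTuningStimuli(),
                        isiRangeS = c(1, 1.4), startS = 0, blockId = 1L,
                        seed = NULL) {
  if (nReps < 1) stop("nReps must be >= 1")
  period <- match.arg(period, PERIODS)
  withSeed(seed, {
    ids <- sample(rep(stimuli$stimulus_id, nReps))
    dur <- stimuli$duration_s[match(ids, stimuli$stimulus_id)]
    gaps <- dur + runif(length(ids), isiRangeS[1], isiRangeS[2])
    onsets <- startS + c(0, cumsum(gaps[-length(gaps)]))
    list(trials = data.frame(onset_s = onsets, stimulus_id = ids,
                             role = "tuning", period = period,
                             block_id = as.integer(blockId), running = NA,
                             stringsAsFactors = FALSE),
         stimuli = stimuli)
  })
}

# Role sequence for one oddball block: runs of 9-11 standards (uniform),
# each followed by a single oddball, until minOddballs oddballs occurred.
oddballRoleSequence <- function(minOddballs) {
  runs <- sample(9:11, minOddballs, replace = TRUE)
  unlist(lapply(runs, function(r) c(rep("standard", r), "oddball")))
}

#' Build a role-swapped pair of oddball blocks
#'
#' Returns two concatenated blocks of an oddball sequence: in the first,
#' `stimA` is the repeated standard and `stimB` the rare oddball; in the
#' second the roles are exchanged. Within each block the standard is
#' repeated 9-11 times (uniform) before each single oddball, and the block
#' continues until at least `minOddballs` oddballs have occurred. Sounds are
#' presented at a fixed onset asynchrony of `duration + silentGapS`.
#'
#' @param stimA,stimB One-row stimulus tables from [stimulusSpec()]; must
#'   describe distinct stimuli of equal duration.
#' @param minOddballs Minimum oddballs per block (>= 1).
#' @param period Period label.
#' @param silentGapS Silent gap between sounds (s).
#' @param interBlockGapS Gap between the two blocks (s).
#' @param startS Session time of the first onset.
#' @param blockIdStart Block label of the first block (second gets + 1).
#' @param seed Optional seed.
#' @return List with `trials` and `stimuli`.
#' @examples
#' pair <- oddballBlock(stimulusSpec("a", "chord", 8, 0.05),
#'                      stimulusSpec("b", "chord", 13, 0.05),
#'                      minOddballs = 5, seed = 1)
#' table(pair$trials$role, pair$trials$block_id)
#' @export
oddballBlock <- function(stimA, stimB, minOddballs = 50, period = "pre",
                         silentGapS = 0.5, interBlockGapS = 5, startS = 0,
                         blockIdStart = 1L, seed = NULL) {
  if (identical(stimA$stimulus_id, stimB$stimulus_id))
    stop("standard and oddball stimuli must differ")
  if (minOddballs < 1) stop("minOddballs must be >= 1")
  period <- match.arg(period, PERIODS)
  soa <- stimA$duration_s + silentGapS
  withSeed(seed, {
    oneBlock <- function(std, odd, startS, blockId) {
      roles <- oddballRoleSequence(minOddballs)
      ids <- ifelse(roles == "standard", std$stimulus_id, odd$stimulus_id)
      data.frame(onset_s = startS + (seq_along(roles) - 1) * soa,
                 stimulus_id = ids, role = roles, period = period,
                 block_id = as.integer(blockId), running = NA,
                 stringsAsFactors = FALSE)
    }
    b1 <- oneBlock(stimA, stimB, startS, blockIdStart)
    b2 <- oneBlock(stimB, stimA, max(b1$onset_s) + soa + interBlockGapS,
                   blockIdStart + 1L)
    list(trials = rbind(b1, b2), stimuli = rbind(stimA, stimB))
  })
}

# Expected evoked-component rate (spk/s, excluding baseline) of a neuron for
# each trial, from its tuning curve, role gain and running gain.
evokedComponentRate <- function(neuron, trials, stimuli) {
  centers <- stimuli$center_khz[match(trials$stimulus_id,
                                      stimuli$stimulus_id)]
  tuned <- neuron@amplitude[trials$period] *
    exp(-(log2(centers) - neuron@bfLog2Khz)^2 / (2 * neuron@sigmaOctaves^2))
  gain <- ifelse(trials$role == "oddball",
                 neuron@oddballGain[trials$period], 1)
  run <- ifelse(!is.na(trials$running) & trials$running,
                neuron@runningGain, 1)
  unname(tuned * gain * run)
}

# Draw spike counts with mean mu and Fano-factor target ff: Poisson for
# ff <= 1, gamma-mixed Poisson (negative binomial, size = mu / (ff - 1))
# above. Vectorized over trials.
rcountFF <- function(mu, ff) {
  n <- length(mu)
  ff <- rep_len(ff, n)
  out <- integer(n)
  pois <- ff <= 1 + 1e-9 | mu <= 0
  out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois))
    out[!pois] <- rnbinom(sum(!pois), size = mu[!pois] / (ff[!pois] - 1),
                          mu = mu[!pois])
  out
}

#' Simulate per-trial spike counts for one neuron
#'
#' The count-level core of the generator: for each trial the evoked-window
#' count is drawn from a count distribution with mean
#' `(baseline + tuned evoked rate x oddball gain x running gain) x window`
#' and variance `dispersion x mean` (Poisson at dispersion 1, negative
#' binomial above), and the baseline-window count from the baseline rate
#' with the same dispersion. Negative computed rates are clamped to zero
#' with a warning.
#'
#' @param neuron A [SimNeuron-class].
#' @param trials Trial table.
#' @param stimuli Stimulus dictionary covering `trials$stimulus_id`.
#' @param baselineWindowS Baseline-window length (s).
#' @param seed Optional seed.
#' @return `data.frame` with one row per trial: `evoked_count`,
#'   `baseline_count`, `evoked_rate`, `baseline_rate`, `duration_s`, plus the
#'   trial columns.
#' @export
simulateCounts <- function(neuron, trials, stimuli, baselineWindowS = 0.2,
                           seed = NULL) {
  if (!nrow(trials)) stop("trial table is empty")
  withSeed(seed, {
    dur <- stimuli$duration_s[match(trials$stimulus_id,
                                    stimuli$stimulus_id)]
    rate <- neuron@baselineRate[trials$period] +
      evokedComponentRate(neuron, trials, stimuli)
    if (any(rate < 0)) {
      warning("negative computed rate clamped to 0")
      rate <- pmax(rate, 0)
    }
    state <- ifelse(!is.na(trials$running) & trials$running,
                    "running", "stationary")
    ff <- neuron@dispersion[cbind(trials$period, state)]
    ec <- rcountFF(rate * dur, ff)
    bc <- rcountFF(neuron@baselineRate[trials$period] * baselineWindowS, ff)
    cbind(trials,
          data.frame(duration_s = dur, evoked_count = ec,
                     baseline_count = bc, evoked_rate = ec / dur,
                     baseline_rate = bc / baselineWindowS))
  })
}

#' Simulate a spike train for one neuron
#'
#' Draws per-trial counts with [simulateCounts()] and places the spikes
#' uniformly within the corresponding windows: evoked spikes in
#' `[onset + latency, onset + latency + duration)` and baseline spikes in
#' `[onset - baselineWindowS, onset)`. Spiking between counted windows is not
#' modeled, since no implemented statistic reads it.
#'
#' @inheritParams simulateCounts
#' @param latencyS Ear-to-cortex transmission latency applied to the evoked
#'   window (s).
#' @return Sorted numeric vector of spike times (s).
#' @export
simulateSpikes <- function(neuron, trials, stimuli, latencyS = 0.015,
                           baselineWindowS = 0.2, seed = NULL) {
  withSeed(seed, {
    cnt <- simulateCounts(neuron, trials, stimuli,
                          baselineWindowS = baselineWindowS)
    evStart <- cnt$onset_s + latencyS
    ev <- rep(evStart, cnt$evoked_count) +
      runif(sum(cnt$evoked_count)) * rep(cnt$duration_s, cnt$evoked_count)
    bl <- rep(cnt$onset_s - baselineWindowS, cnt$baseline_count) +
      runif(sum(cnt$baseline_count)) * baselineWindowS
    sort(c(ev, bl))
  })
}

#' Simulate a motion-energy trace consistent with trial running labels
#'
#' Produces a frame-indexed nonnegative motion-energy series (arbitrary
#' units) in which frames around running-trial onsets sit at a high level
#' and all other frames at a low level, with additive noise. After 10-frame
#' boxcar smoothing the values at running-trial onsets exceed any threshold
#' separating the two levels, so [classifyLocomotion()] recovers the labels.
#'
#' @param trials Trial table with a logical `running` column (`NA` treated as
#'   not running).
#' @param frameRateHz Frame rate (Hz).
#' @param runLevel,quietLevel Motion-energy levels for running and quiet
#'   frames.
#' @param noiseSd SD of additive Gaussian noise (clipped at zero).
#' @param seed Optional seed.
#' @return Numeric vector, one value per frame from session time 0.
#' @export
simulateMotionTrace <- function(trials, frameRateHz = 30, runLevel = 1,
                                quietLevel = 0.05, noiseSd = 0.02,
                                seed = NULL) {
  if (frameRateHz <= 0) stop("frameRateHz must be > 0")
  withSeed(seed, {
    nFrames <- ceiling((max(trials$onset_s) + 1) * frameRateHz) + 1
    # each frame takes the state of the nearest trial onset, so bouts end
    # halfway to a neighboring trial of the opposite state
    tFrames <- (seq_len(nFrames) - 1) / frameRateHz
    nearest <- findInterval(tFrames,
                            c(-Inf, trials$onset_s[-1] -
                                diff(trials$onset_s) / 2)) |>
      pmin(nrow(trials)) |> pmax(1L)
    running <- !is.na(trials$running[nearest]) & trials$running[nearest]
    level <- ifelse(running, runLevel, quietLevel)
    pmax(level + rnorm(nFrames, 0, noiseSd), 0)
  })
}

# Trial layout of one period: tuning block, chord oddball pair, FM pair.
periodTrials <- function(config, period, startS, blockIdStart,
                         interBlockGapS = 10) {
  tun <- tuningBlock(config@tuningReps, period, isiRangeS = config@isiRangeS,
                     startS = startS, blockId = blockIdStart)
  chords <- defaultChordStimuli()
  t0 <- max(tun$trials$onset_s) + interBlockGapS
  ch <- oddballBlock(chords[1, ], chords[2, ], config@minOddballs, period,
                     silentGapS = config@silentGapS, startS = t0,
                     blockIdStart = blockIdStart + 1L)
  fms <- defaultFmStimuli()
  t1 <- max(ch$trials$onset_s) + interBlockGapS
  fm <- oddballBlock(fms[1, ], fms[2, ], config@minOddballs, period,
                     silentGapS = config@silentGapS, startS = t1,
                     blockIdStart = blockIdStart + 3L)
  list(trials = rbind(tun$trials, ch$trials, fm$trials),
       stimuli = rbind(tun$stimuli, ch$stimuli, fm$stimuli))
}

#' Simulate a full session
#'
#' Generates one session with the paradigm structure the pipeline analyzes:
#' three periods (pre, saline, doi) each containing a tuning block, a
#' role-swapped chord oddball pair and a role-swapped FM oddball pair; a
#' population of neurons drawn from the configured distributions; per-trial
#' running labels drawn with the per-period running probability; spike
#' trains for every neuron; and a motion-energy trace consistent with the
#' running labels. All draws flow from the master seed through per-neuron
#' substreams, so the session is fully reproducible.
#'
#' @param config A [SimConfig-class].
#' @param neurons Optional list of [SimNeuron-class] objects to use instead
#'   of sampling from `config` (e.g. a constructed toy population).
#' @return An [OddballSession-class]; `metadata(session)$neurons` holds the
#'   ground-truth parameters and `metadata$config` the configuration.
#' @examples
#' s <- simulateSession(simConfig(nNeurons = 2, tuningReps = 2,
#'                                minOddballs = 3, seed = 7))
#' s
#' @export
simulateSession <- function(config, neurons = NULL) {
  withSeed(config@seed, {
    parts <- list()
    startS <- 1  # leaves room for the first trial's baseline window
    blockId <- 1L
    for (p in PERIODS) {
      pt <- periodTrials(config, p, startS, blockId)
      parts[[p]] <- pt
      startS <- max(pt$trials$onset_s) + 30
      blockId <- blockId + 5L
    }
    trials <- do.call(rbind, lapply(parts, `[[`, "trials"))
    rownames(trials) <- NULL
    stimuli <- unique(do.call(rbind, lapply(parts, `[[`, "stimuli")))
    trials$running <- runif(nrow(trials)) <
      config@runningProb[trials$period]
    if (is.null(neurons)) neurons <- sampleNeurons(config)
    if (is.null(names(neurons)))
      names(neurons) <- sprintf("n%03d", seq_along(neurons))
    spikes <- lapply(seq_along(neurons), function(i)
      simulateSpikes(neurons[[i]], trials, stimuli,
                     seed = substreamSeed(config@seed, 100000 + i)))
    names(spikes) <- names(neurons)
    motion <- simulateMotionTrace(trials,
                                  seed = substreamSeed(config@seed, 99999))
    oddballSession(spikes, trials, stimuli, motion = motion,
                   metadata = list(config = config, neurons = neurons))
  })
}
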