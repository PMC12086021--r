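#' Generative model of one simulated neuron
#'
#' Parameters of the count-process model used by the synthetic-data
#' generator. A neuron has a per-period baseline rate, a Gaussian tuning
#' curve on log2 frequency (peak position, width, height), a multiplicative
#' oddball gain applied to the evoked (tuned) component on oddball trials, a
#' per-period / per-locomotion-state Fano-factor target for the spike-count
#' distribution, and a multiplicative evoked-rate gain during running.
#'
#' @slot baselineRate Named numeric, baseline rate (spk/s) per period
#'   (`pre`, `saline`, `doi`).
#' @slot bfLog2Khz Tuning peak position, log2(kHz).
#' @slot sigmaOctaves Tuning SD in octaves.
#' @slot amplitude Named numeric, tuning peak height (spk/s) per period.
#' @slot oddballGain Named numeric (>= 0), evoked-rate factor on oddball
#'   trials, per period.
#' @slot dispersion Numeric matrix (periods x `stationary`/`running`),
#'   target Fano factor of the spike-count process (> 0; 1 = Poisson).
#' @slot runningGain Evoked-rate factor applied on running trials.
#' @export
setClass("SimNeuron",
  representation(baselineRate = "numeric", bfLog2Khz = "numeric",
                 sigmaOctaves = "numeric", amplitude = "numeric",
                 oddballGain = "numeric", dispersion = "matrix",
                 runningGain = "numeric"))

setValidity("SimNeuron", function(object) {
  msgs <- character(0)
  perPeriod <- function(x, what)
    if (!identical(names(x), PERIODS))
      sprintf("%s must be named by period (pre, saline, doi)", what)
  msgs <- c(msgs, perPeriod(object@baselineRate, "baselineRate"),
            perPeriod(object@amplitude, "amplitude"),
            perPeriod(object@oddballGain, "oddballGain"))
  if (any(object@baselineRate < 0) || any(object@oddballGain < 0))
    msgs <- c(msgs, "rates and gains must be >= 0")
  if (any(object@dispersion <= 0))
    msgs <- c(msgs, "dispersion (Fano target) must be > 0")
  if (!identical(rownames(object@dispersion), PERIODS) ||
      !identical(colnames(object@dispersion), c("stationary", "running")))
    msgs <- c(msgs, "dispersion must be a periods x (stationary, running) matrix")
  if (object@sigmaOctaves <= 0)
    msgs <- c(msgs, "sigmaOctaves must be > 0")
  msgs <- msgs[!vapply(msgs, is.null, logical(1))]
  if (length(msgs)) unlist(msgs) else TRUE
})

expandPerPeriod <- function(x) {
  if (length(x) == 1) x <- rep(x, 3)
  if (is.null(names(x))) names(x) <- PERIODS
  x[PERIODS]
}

#' Construct a SimNeuron
#'
#' Scalars are recycled across periods; `dispersion` may be a scalar, a
#' per-period vector, or a full periods x (stationary, running) matrix.
#'
#' @param baselineRate Baseline rate (spk/s), scalar or per-period.
#' @param bfLog2Khz Tuning peak position in log2(kHz).
#' @param sigmaOctaves Tuning SD (octaves).
#' @param amplitude Tuning peak height (spk/s), scalar or per-period.
#' @param oddballGain Oddball evoked-rate factor, scalar or per-period.
#' @param dispersion Fano-factor target of the count process.
#' @param runningGain Evoked-rate factor on running trials.
#' @return A validated [SimNeuron-class].
#' @examples
#' simNeuron(baselineRate = 5, amplitude = 20, oddballGain = c(1.5, 1.5, 1.1))
#' @export
simNeuron <- function(baselineRate = 5, bfLog2Khz = log2(10),
                      sigmaOctaves = 1, amplitude = 20, oddballGain = 1.5,
                      dispersion = 1, runningGain = 1) {
  if (!is.matrix(dispersion)) {
    d <- expandPerPeriod(dispersion)
    dispersion <- cbind(stationary = d, running = d)
    rownames(dispersion) <- PERIODS
  }
  new("SimNeuron", baselineRate = expandPerPeriod(baselineRate),
      bfLog2Khz = bfLog2Khz, sigmaOctaves = sigmaOctaves,
      amplitude = expandPerPeriod(amplitude),
      oddballGain = expandPerPeriod(oddballGain),
      dispersion = dispersion, runningGain = runningGain)
}

#' Simulation configuration
#'
#' Full parameterization of a simulated session: paradigm layout (trial
#' counts, inter-stimulus timing), per-period running probability, the
#' population distributions from which neurons are drawn, and the master
#' seed. A fixed seed yields identical sessions.
#'
#' @slot nNeurons Number of simultaneously recorded units.
#' @slot tuningReps Repetitions per tuning frequency.
#' @slot minOddballs Minimum oddball presentations per oddball block.
#' @slot isiRangeS Silent-interval range (s) between tuning tones.
#' @slot silentGapS Silent gap (s) between oddball-sequence sounds, so the
#'   stimulus-onset asynchrony is `duration + silentGapS`.
#' @slot runningProb Named per-period probability that a trial is a running
#'   trial.
#' @slot population List of population-distribution parameters (see
#'   [simConfig()]).
#' @slot seed Master RNG seed.
#' @export
setClass("SimConfig",
  representation(nNeurons = "integer", tuningReps = "integer",
                 minOddballs = "integer", isiRangeS = "numeric",
                 silentGapS = "numeric", runningProb = "numeric",
                 population = "list", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@nNeurons < 1 || object@tuningReps < 1 || object@minOddballs < 1)
    msgs <- c(msgs, "nNeurons, tuningReps and minOddballs must be >= 1")
  if (any(object@runningProb < 0) || any(object@runningProb > 1))
    msgs <- c(msgs, "runningProb must lie in [0, 1]")
  if (!identical(names(object@runningProb), PERIODS))
    msgs <- c(msgs, "runningProb must be named by period")
  if (length(object@isiRangeS) != 2 || diff(object@isiRangeS) < 0)
    msgs <- c(msgs, "isiRangeS must be an increasing length-2 range")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: sessions of
#' three periods (pre, saline, doi) each holding a 16-frequency tuning block
#' (>= 20 repetitions, 1-1.4 s inter-stimulus intervals), a role-swapped
#' chord oddball pair (8 and 13 kHz centers, 50 ms sounds, 500 ms gaps) and a
#' role-swapped FM oddball pair (8-13 kHz up/down sweeps, 100 ms sounds),
#' with at least 50 oddballs per block and 9-11 standards per oddball.
#' Population defaults place the drug effect entirely in the doi period:
#' oddball gain 1.5 -> 1.1, evoked amplitude and baseline scaled by 0.8,
#' count dispersion (Fano target) 1.0 -> 1.3, and running probabilities
#' 0.44 / 0.20 / 0.72 across pre / saline / doi.
#'
#' @param nNeurons,tuningReps,minOddballs Paradigm sizes.
#' @param isiRangeS Tuning-block silent-interval range (s).
#' @param silentGapS Oddball-sequence silent gap (s).
#' @param runningProb Named per-period running probability.
#' @param population Named list overriding entries of the default population
#'   distribution: `baselineMeanLog`, `baselineSdLog`, `amplitudeMeanLog`,
#'   `amplitudeSdLog`, `bfRangeLog2`, `sigmaRange`, `gain` (per-period mean
#'   oddball gain), `gainSdLog` (per-neuron lognormal jitter),
#'   `evokedFactor`, `baselineFactor`, `dispersion` (all per-period),
#'   `dispersionRunningFactor`, `runningGainMeanLog`, `runningGainSdLog`.
#' @param seed Master seed (integer).
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nNeurons = 4, tuningReps = 2, minOddballs = 3, seed = 1)
#' @export
simConfig <- function(nNeurons = 100, tuningReps = 20, minOddballs = 50,
                      isiRangeS = c(1, 1.4), silentGapS = 0.5,
                      runningProb = c(pre = 0.44, saline = 0.20, doi = 0.72),
                      population = list(), seed = 1L) {
  pop <- list(
    baselineMeanLog = log(5), baselineSdLog = 0.5,
    amplitudeMeanLog = log(20), amplitudeSdLog = 0.4,
    bfRangeLog2 = log2(c(4, 26)),
    sigmaRange = c(0.7, 1.8),
    gain = c(pre = 1.5, saline = 1.5, doi = 1.1),
    gainSdLog = 0.1,
    evokedFactor = c(pre = 1, saline = 1, doi = 0.8),
    baselineFactor = c(pre = 1, saline = 1, doi = 0.8),
    dispersion = c(pre = 1, saline = 1, doi = 1.3),
    dispersionRunningFactor = 1,
    runningGainMeanLog = log(1.2), runningGainSdLog = 0.1)
  stopifnot(all(names(population) %in% names(pop)))
  pop[names(population)] <- population
  new("SimConfig", nNeurons = as.integer(nNeurons),
      tuningReps = as.integer(tuningReps),
      minOddballs = as.integer(minOddballs),
      isiRangeS = isiRangeS, silentGapS = silentGapS,
      runningProb = expandPerPeriod(runningProb), population = pop,
      seed = as.integer(seed))
}

#' Draw a population of simulated neurons
#'
#' Samples `nNeurons` [SimNeuron-class] objects from the population
#' distributions of a [SimConfig-class]. Baseline rates, tuning amplitudes,
#' per-neuron gain jitter and running gains are lognormal; tuning peak
#' positions and widths are uniform over their configured ranges. Each
#' neuron is drawn from its own substream of the master seed, so neuron `i`
#' is identical regardless of population size.
#'
#' @param config A [SimConfig-class].
#' @return List of [SimNeuron-class] objects named `n001`, `n002`, ...
#' @export
sampleNeurons <- function(config) {
  pop <- config@population
  lapply(seq_len(config@nNeurons), function(i) {
    withSeed(substreamSeed(config@seed, i), {
      base <- exp(rnorm(1, pop$baselineMeanLog, pop$baselineSdLog))
      amp <- exp(rnorm(1, pop$amplitudeMeanLog, pop$amplitudeSdLog))
      gainJitter <- exp(rnorm(1, 0, pop$gainSdLog))
      disp <- expandPerPeriod(pop$dispersion)
      simNeuron(
        baselineRate = base * expandPerPeriod(pop$baselineFactor),
        bfLog2Khz = runif(1, pop$bfRangeLog2[1], pop$bfRangeLog2[2]),
        sigmaOctaves = runif(1, pop$sigmaRange[1], pop$sigmaRange[2]),
        amplitude = amp * expandPerPeriod(pop$evokedFactor),
        oddballGain = expandPerPeriod(pop$gain) * gainJitter,
        dispersion = cbind(stationary = disp,
                           running = disp * pop$dispersionRunningFactor),
        runningGain = exp(rnorm(1, pop$runningGainMeanLog,
                                pop$runningGainSdLog)))
    })
  }) |> stats::setNames(sprintf("n%03d", seq_len(config@nNeurons)))
}

#' Read / write a simulation configuration as YAML
#'
#' Serializes every [SimConfig-class] field, including the population
#' distributions; the round trip reproduces the configuration (and hence,
#' with the stored seed, the identical session).
#'
#' @param config A [SimConfig-class].
#' @param path YAML file path.
#' @return `writeSimConfig` returns `path` invisibly; `readSimConfig`
#'   returns a [SimConfig-class].
#' @export
writeSimConfig <- function(config, path) {
  yaml::write_yaml(list(
    nNeurons = config@nNeurons, tuningReps = config@tuningReps,
    minOddballs = config@minOddballs, isiRangeS = config@isiRangeS,
    silentGapS = config@silentGapS,
    runningProb = as.list(config@runningProb),
    population = lapply(config@population, function(x)
      if (!is.null(names(x))) as.list(x) else x),
    seed = config@seed), path, precision = 15)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  v <- yaml::read_yaml(path)
  v$runningProb <- unlist(v$runningProb)
  v$population <- lapply(v$population, function(x)
    if (is.list(x)) unlist(x) else x)
  do.call(simConfig, v)
}

#' @rdname SimConfig-class
#' @param object A `SimConfig`.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nNeurons, "neurons, tuningReps",
      object@tuningReps, ", minOddballs", object@minOddballs,
      ", seed", object@seed, "\n")
  cat("  running prob:", paste(sprintf("%s %.2f", PERIODS,
      object@runningProb), collapse = ", "), "\n")
  cat("  doi effects: gain", object@population$gain[["doi"]],
      "evoked x", object@population$evokedFactor[["doi"]],
      "dispersion", object@population$dispersion[["doi"]], "\n")
})
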