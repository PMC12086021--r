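assay <- SummarizedExperiment::assay

# Shared fixtures, built in code. The small session is computed once per
# test run and reused by the session/pipeline tests.

tinyConfig <- function(seed = 11, ...)
  simConfig(nNeurons = 4, tuningReps = 3, minOddballs = 5, seed = seed, ...)

.fixtureEnv <- new.env()

sharedSession <- function() {
  if (is.null(.fixtureEnv$session))
    .fixtureEnv$session <- simulateSession(tinyConfig())
  .fixtureEnv$session
}

# A session whose spike trains are fully deterministic: each neuron fires a
# fixed number of evenly spaced spikes in every evoked and baseline window,
# so filter decisions can be computed by hand. `rates` is a data.frame with
# one row per neuron: evoked_pre/sal/doi and baseline_pre/sal/doi in spk/s.
deterministicSession <- function(rates, nReps = 20, durS = 0.1) {
  stim <- rbind(stimulusSpec("tone_A", "pure_tone", 8, durS),
                stimulusSpec("tone_B", "pure_tone", 16, durS))
  trials <- do.call(rbind, lapply(seq_along(PERIODS <- c("pre", "saline",
                                                         "doi")),
    function(pi) {
      n <- 2 * nReps
      data.frame(onset_s = (pi - 1) * 1000 + seq_len(n) * 2,
                 stimulus_id = rep(stim$stimulus_id, nReps),
                 role = "tuning", period = PERIODS[pi],
                 block_id = pi, running = NA)
    }))
  evenSpikes <- function(k, a, b)
    if (k <= 0) numeric(0) else a + (seq_len(k) - 0.5) / k * (b - a)
  spikes <- lapply(seq_len(nrow(rates)), function(i) {
    r <- rates[i, ]
    ev <- mapply(function(onset, period) {
      k <- round(r[[paste0("evoked_", period)]] * durS)
      evenSpikes(k, onset + 0.015, onset + 0.015 + durS)
    }, trials$onset_s, trials$period, SIMPLIFY = FALSE)
    bl <- mapply(function(onset, period) {
      k <- round(r[[paste0("baseline_", period)]] * 0.2)
      evenSpikes(k, onset - 0.2, onset)
    }, trials$onset_s, trials$period, SIMPLIFY = FALSE)
    sort(unlist(c(ev, bl)))
  })
  names(spikes) <- rates$neuron_id
  oddballSession(spikes, trials, stim)
}

# Tidy per-trial responses for one neuron built directly (filter unit tests).
respFrame <- function(evoked, baseline = 0, stimulus = "s1",
                      period = "saline", neuron = "n1") {
  n <- max(length(evoked), length(baseline))
  data.frame(neuron_id = neuron, stimulus_id = stimulus, period = period,
             role = "tuning", block_id = 1L, running = NA,
             onset_s = seq_len(n), duration_s = 0.1,
             evoked_rate = rep_len(evoked, n),
             baseline_rate = rep_len(baseline, n),
             evoked_count = rep_len(evoked, n) * 0.1,
             baseline_count = rep_len(baseline, n) * 0.2)
}
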