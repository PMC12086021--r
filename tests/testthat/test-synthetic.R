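test_that("tuning blocks have the right size, ensemble and spacing", {
  blk <- tuningBlock(nReps = 20, seed = 1)
  expect_equal(nrow(blk$trials), 320)
  tab <- table(blk$trials$stimulus_id)
  expect_length(tab, 16)
  expect_true(all(tab == 20))
  f <- sort(blk$stimuli$center_khz)
  expect_equal(range(f), c(2, 40))
  expect_equal(diff(log2(f)), rep(log2(40 / 2) / 15, 15), tolerance = 1e-10)
  gaps <- diff(blk$trials$onset_s)
  expect_true(all(gaps >= 0.1 + 1 - 1e-9 & gaps <= 0.1 + 1.4 + 1e-9))

  one <- tuningBlock(nReps = 1, seed = 2)
  expect_equal(nrow(one$trials), 16)
  expect_equal(anyDuplicated(one$trials$stimulus_id), 0)
  expect_error(tuningBlock(nReps = 0), "nReps")
  expect_identical(tuningBlock(nReps = 5, seed = 9),
                   tuningBlock(nReps = 5, seed = 9))
})

test_that("oddball blocks obey run-length and count constraints and swap roles", {
  a <- stimulusSpec("a", "chord", 8, 0.05, levelDb = 50)
  b <- stimulusSpec("b", "chord", 13, 0.05, levelDb = 50)
  pair <- oddballBlock(a, b, minOddballs = 50, seed = 3)
  tr <- pair$trials
  for (blk in unique(tr$block_id)) {
    d <- tr[tr$block_id == blk, ]
    expect_gte(sum(d$role == "oddball"), 50)
    odd <- which(d$role == "oddball")
    runs <- diff(c(0, odd)) - 1
    expect_true(all(runs %in% 9:11))
  }
  # role swap: the standard of block 1 is the oddball of block 2
  std1 <- unique(tr$stimulus_id[tr$block_id == 1 & tr$role == "standard"])
  odd2 <- unique(tr$stimulus_id[tr$block_id == 2 & tr$role == "oddball"])
  expect_identical(std1, odd2)

  minimal <- oddballBlock(a, b, minOddballs = 1, seed = 4)
  expect_gte(sum(minimal$trials$block_id == 1), 10)
  expect_error(oddballBlock(a, a), "differ")
})

test_that("run lengths are uniform over 9-11", {
  pair <- oddballBlock(stimulusSpec("a", "pure_tone", 8, 0.05),
                       stimulusSpec("b", "pure_tone", 13, 0.05),
                       minOddballs = 5000, seed = 5)
  tr <- pair$trials
  runs <- unlist(lapply(split(tr, tr$block_id), function(d) {
    odd <- which(d$role == "oddball")
    diff(c(0, odd)) - 1
  }))
  expect_gte(length(runs), 10000)
  expect_gt(stats::chisq.test(table(runs))$p.value, 0.01)
})

test_that("dispersion-1 counts are Poisson and NB dispersion hits its target", {
  stim <- stimulusSpec("t", "pure_tone", 10, 0.1)
  trials <- data.frame(onset_s = seq_len(10000) * 2, stimulus_id = "t",
                       role = "tuning", period = "saline", block_id = 1L,
                       running = FALSE)
  nrn <- simNeuron(baselineRate = 5, bfLog2Khz = log2(10), amplitude = 20,
                   dispersion = 1)
  cnt <- simulateCounts(nrn, trials, stim, seed = 6)
  ff <- var(cnt$evoked_count) / mean(cnt$evoked_count)
  expect_lt(abs(ff - 1), 0.05)
  # mean matches the configured rate: (5 + 20) spk/s x 0.1 s
  expect_lt(abs(mean(cnt$evoked_count) - 2.5), 3 * sqrt(2.5 / 10000) * 2)

  for (phi in c(1.3, 2)) {
    nrnD <- simNeuron(baselineRate = 5, bfLog2Khz = log2(10),
                      amplitude = 20, dispersion = phi)
    cntD <- simulateCounts(nrnD, trials, stim, seed = 7)
    ffD <- var(cntD$evoked_count) / mean(cntD$evoked_count)
    expect_lt(abs(ffD - phi) / phi, 0.05)
  }
})

test_that("spike placement respects the counting windows", {
  stim <- stimulusSpec("t", "pure_tone", 10, 0.1)
  trials <- data.frame(onset_s = seq_len(500) * 2, stimulus_id = "t",
                       role = "tuning", period = "pre", block_id = 1L,
                       running = FALSE)
  nrn <- simNeuron(baselineRate = 10, amplitude = 30,
                   bfLog2Khz = log2(10), sigmaOctaves = 1)
  sp <- simulateSpikes(nrn, trials, stim, seed = 8)
  expect_false(is.unsorted(sp))
  rel <- sp - trials$onset_s[findInterval(sp, trials$onset_s - 0.2)]
  # spikes are only placed in [-0.2, 0) or [0.015, 0.115)
  expect_true(all((rel >= -0.2 & rel < 0) | (rel >= 0.015 & rel < 0.115)))
})

test_that("zero tuning amplitude leaves evoked at baseline, gain 1 gives OEI 0", {
  stim <- defaultChordStimuli()
  pair <- oddballBlock(stim[1, ], stim[2, ], minOddballs = 200,
                       period = "saline", seed = 9)
  flat <- simNeuron(baselineRate = 20, amplitude = 0, oddballGain = 1.7)
  cnt <- simulateCounts(flat, pair$trials, pair$stimuli, seed = 10)
  expect_lt(abs(mean(cnt$evoked_rate) - 20) / 20, 0.05)

  sym <- simNeuron(baselineRate = 0, amplitude = 25,
                   bfLog2Khz = log2(10), sigmaOctaves = 2, oddballGain = 1)
  cnt2 <- simulateCounts(sym, pair$trials, pair$stimuli, seed = 11)
  odd <- oddballResponses(cnt2)
  expect_lt(max(abs(odd$oei)), 0.1)
  # role symmetry: a stimulus responds alike as standard and as oddball
  s1 <- cnt2$evoked_count[cnt2$stimulus_id == "chord_8kHz" &
                            cnt2$role == "standard"]
  s2 <- cnt2$evoked_count[cnt2$stimulus_id == "chord_8kHz" &
                            cnt2$role == "oddball"]
  expect_gt(suppressWarnings(wilcox.test(s1, s2))$p.value, 0.01)
})

test_that("sessions are reproducible from the seed", {
  s1 <- simulateSession(tinyConfig(seed = 123))
  s2 <- simulateSession(tinyConfig(seed = 123))
  expect_identical(spikeTimes(s1), spikeTimes(s2))
  expect_identical(trialInfo(s1), trialInfo(s2))
  expect_identical(motionTrace(s1), motionTrace(s2))
  s3 <- simulateSession(tinyConfig(seed = 124))
  expect_false(identical(spikeTimes(s1), spikeTimes(s3)))
})

test_that("motion traces round-trip through locomotion classification", {
  trials <- data.frame(onset_s = seq_len(200) * 3, stimulus_id = "t",
                       role = "tuning", period = "pre", block_id = 1L,
                       running = rep(c(TRUE, FALSE, FALSE, TRUE), 50))
  tr1 <- simulateMotionTrace(trials, seed = 12)
  expect_identical(tr1, simulateMotionTrace(trials, seed = 12))
  expect_true(all(tr1 >= 0))
  got <- classifyLocomotion(tr1, trials$onset_s)
  expect_gte(mean(got == trials$running), 0.99)

  quiet <- trials; quiet$running <- FALSE
  trQ <- simulateMotionTrace(quiet, seed = 13)
  gotQ <- classifyLocomotion(trQ, quiet$onset_s, threshold = 0.5)
  expect_false(any(gotQ))
})
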