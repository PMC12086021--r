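oneTrialSession <- function(spikes, onset = 1, durS = 0.1) {
  oddballSession(list(n1 = spikes),
                 data.frame(onset_s = onset, stimulus_id = "t",
                            role = "tuning", period = "pre", block_id = 1L,
                            running = NA),
                 stimulusSpec("t", "pure_tone", 8, durS))
}

test_that("windowed counting matches direct counts and uses half-open windows", {
  s <- oneTrialSession(c(1.020, 1.050))
  se <- alignAndCount(s)
  expect_equal(as.numeric(assay(se, "evoked_count")), 2)
  expect_equal(as.numeric(assay(se, "evoked_rate")), 20)

  empty <- alignAndCount(oneTrialSession(numeric(0)))
  expect_equal(as.numeric(assay(empty, "evoked_rate")), 0)
  expect_equal(as.numeric(assay(empty, "baseline_rate")), 0)

  # boundaries: evoked window is [onset + 0.015, onset + 0.115)
  atStart <- alignAndCount(oneTrialSession(1.015))
  expect_equal(as.numeric(assay(atStart, "evoked_count")), 1)
  atEnd <- alignAndCount(oneTrialSession(1.115))
  expect_equal(as.numeric(assay(atEnd, "evoked_count")), 0)
  justBefore <- alignAndCount(oneTrialSession(1.115 - 1e-9))
  expect_equal(as.numeric(assay(justBefore, "evoked_count")), 1)
  # baseline window is [onset - 0.2, onset)
  blEdge <- alignAndCount(oneTrialSession(c(0.8, 1 - 1e-9, 1.0)))
  expect_equal(as.numeric(assay(blEdge, "baseline_count")), 2)
})

test_that("alignment is translation invariant", {
  s0 <- simulateSession(tinyConfig(seed = 21))
  shift <- 12.5
  trials <- trialInfo(s0)
  trials$onset_s <- trials$onset_s + shift
  s1 <- oddballSession(lapply(spikeTimes(s0), `+`, shift), trials,
                       stimulusInfo(s0))
  expect_equal(assay(alignAndCount(s0), "evoked_count"),
               assay(alignAndCount(s1), "evoked_count"))
})

test_that("mean evoked rate converges to the generating rate", {
  stim <- stimulusSpec("t", "pure_tone", 10, 0.1)
  trials <- data.frame(onset_s = seq_len(4000) * 2, stimulus_id = "t",
                       role = "tuning", period = "pre", block_id = 1L,
                       running = FALSE)
  nrn <- simNeuron(baselineRate = 0, amplitude = 10, bfLog2Khz = log2(10))
  sp <- simulateSpikes(nrn, trials, stim, seed = 22)
  se <- alignAndCount(oddballSession(list(n1 = sp), trials, stim))
  expect_lt(abs(mean(assay(se, "evoked_rate")) - 10), 0.5)
})

test_that("sessions round-trip through CSV and schema errors are named", {
  s <- sharedSession()
  dir <- withr::local_tempdir()
  writeSession(s, dir)
  r <- readSession(dir)
  expect_equal(spikeTimes(r), spikeTimes(s), tolerance = 1e-12)
  expect_equal(trialInfo(r)$onset_s, trialInfo(s)$onset_s,
               tolerance = 1e-12)
  expect_identical(trialInfo(r)$role, trialInfo(s)$role)
  expect_identical(trialInfo(r)$running, trialInfo(s)$running)
  expect_equal(motionTrace(r), motionTrace(s), tolerance = 1e-12)
  expect_equal(assay(alignAndCount(r), "evoked_count"),
               assay(alignAndCount(s), "evoked_count"))

  # misspelled role column is reported by name
  tr <- read.csv(file.path(dir, "trials.csv"))
  names(tr)[names(tr) == "role"] <- "rolle"
  write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  expect_error(readSession(dir), "trials.csv.*role")
})

test_that("neurons with no spikes are retained with a warning", {
  s <- sharedSession()
  dir <- withr::local_tempdir()
  writeSession(s, dir)
  sp <- read.csv(file.path(dir, "spikes.csv"))
  drop1 <- names(spikeTimes(s))[1]
  write.csv(sp[sp$neuron_id != drop1, ], file.path(dir, "spikes.csv"),
            row.names = FALSE)
  expect_warning(r <- readSession(dir), drop1)
  expect_length(spikeTimes(r), length(spikeTimes(s)))
  expect_length(spikeTimes(r)[[drop1]], 0)
})
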