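test_that("OEI and MI follow their definitions and symmetries", {
  expect_equal(computeOEI(10, 5), 1 / 3)
  expect_equal(computeOEI(7, 7), 0)
  expect_true(is.na(computeOEI(0, 0)))
  expect_equal(computeMI(10, 5), -1 / 3)
  expect_equal(computeMI(4, 4), 0)
  expect_true(is.na(computeMI(0, 0)))

  withr::with_seed(41, {
    o <- runif(500, 0, 50); s <- runif(500, 0, 50)
    expect_equal(computeOEI(o, s), -computeOEI(s, o))  # antisymmetry
    expect_true(all(abs(computeOEI(o, s)) <= 1, na.rm = TRUE))
    expect_true(all(abs(computeMI(o, s)) <= 1, na.rm = TRUE))
  })
})

test_that("empirical OEI converges to (g - 1) / (g + 1)", {
  g <- 1.5
  stim <- defaultChordStimuli()
  pair <- oddballBlock(stim[1, ], stim[2, ], minOddballs = 300,
                       period = "saline", seed = 42)
  oeis <- unlist(lapply(1:10, function(i) {
    nrn <- simNeuron(baselineRate = 0, amplitude = 30,
                     bfLog2Khz = log2(10), sigmaOctaves = 2,
                     oddballGain = g)
    odd <- oddballResponses(simulateCounts(nrn, pair$trials, pair$stimuli,
                                           seed = 430 + i))
    odd$oei
  }))
  expect_equal(mean(oeis), (g - 1) / (g + 1), tolerance = 0.02)
})

test_that("population tests handle identity and degenerate sizes", {
  odd <- data.frame(neuron_id = rep(sprintf("n%02d", 1:10), 2),
                    stimulus_id = "chord_8kHz",
                    period = rep(c("saline", "doi"), each = 10),
                    o = 10, s = 5, n_oddball = 50, n_standard = 500,
                    oei = rep(seq(0.1, 0.4, length.out = 10), 2))
  ident <- populationTests(odd)
  expect_equal(ident$p, 1)
  expect_equal(ident$median_ref, ident$median_cmp)
  small <- populationTests(odd[c(1:3, 11:13), ])
  expect_true(is.na(small$p))
  expect_equal(small$n, 3)
})

test_that("excluding the first standard after each oddball shrinks the average set", {
  s <- sharedSession()
  resp <- trialResponses(alignAndCount(s),
                         neurons = names(spikeTimes(s))[1])
  all <- oddballResponses(resp)
  trimmed <- oddballResponses(resp, excludeFirstStandard = TRUE)
  expect_true(all(trimmed$n_standard <= all$n_standard))
  expect_identical(trimmed$n_oddball, all$n_oddball)
  # one standard removed per oddball, except after the block-final oddball
  expect_equal(all$n_standard - trimmed$n_standard, all$n_oddball - 1)
})

test_that("the adaptation control separates drug effects from drift", {
  stim <- defaultChordStimuli()
  simPop <- function(gains, amps, seed, n = 60) {
    pair <- lapply(c(pre = "pre", saline = "saline", doi = "doi"),
                   function(p) oddballBlock(stim[1, ], stim[2, ],
                                            minOddballs = 30, period = p,
                                            seed = seed))
    resp <- do.call(rbind, lapply(seq_len(n), function(i) {
      nrn <- simNeuron(baselineRate = 0, amplitude = amps,
                       bfLog2Khz = log2(10), sigmaOctaves = 2,
                       oddballGain = gains)
      d <- do.call(rbind, lapply(pair, function(b)
        simulateCounts(nrn, b$trials, b$stimuli,
                       seed = substreamSeed(seed, i))))
      d$neuron_id <- sprintf("n%03d", i)
      d
    }))
    adaptationControl(oddballResponses(resp))
  }
  # stationary population: neither step shows a shift
  still <- simPop(gains = 1.5, amps = 25, seed = 51)
  expect_true(all(still$p_pre_sal > 0.01))
  expect_true(all(abs(still$median_mi_pre_sal) < 0.05))
  # drift only: both steps shrink alike, paired comparison is null
  drift <- simPop(gains = 1.5, amps = c(pre = 25, saline = 20, doi = 16),
                  seed = 52)
  expect_lt(max(abs(drift$median_mi_pre_sal - drift$median_mi_sal_doi)),
            0.05)
  expect_true(all(drift$p_mi_paired > 0.05))
  # drug only: the saline-to-doi step is the larger, negative one
  drug <- simPop(gains = c(pre = 1.5, saline = 1.5, doi = 1.1),
                 amps = c(pre = 25, saline = 25, doi = 20), seed = 53)
  expect_true(all(drug$median_mi_sal_doi < drug$median_mi_pre_sal))
  expect_true(all(drug$p_sal_doi < 0.05))
})

test_that("matched resampling matches the target mean deterministically", {
  withr::with_seed(61, {
    early <- rnorm(60, 0.18, 0.05)
    lateSal <- rnorm(150, 0.15, 0.05)
    lateDoi <- lateSal - 0.1 + rnorm(150, 0, 0.02)
  })
  res <- matchedResampling(early, lateSal, lateDoi, nResamples = 20,
                           seed = 62)
  expect_true(all(abs(res$resamples$mean_sal - res$target_mean) <= 0.01))
  expect_equal(res$subset_size, 60)
  res2 <- matchedResampling(early, lateSal, lateDoi, nResamples = 20,
                            seed = 62)
  expect_identical(res, res2)  # seed pins the subsets

  # identical sets: the full-size subset matches trivially
  triv <- matchedResampling(lateSal, lateSal, lateDoi, nResamples = 3,
                            seed = 63)
  expect_equal(triv$subset_size, length(lateSal))
  expect_equal(triv$resamples$mean_sal, rep(mean(lateSal), 3))

  # impossible target: whole late set cannot move its mean
  expect_error(matchedResampling(early + 2, lateSal, lateDoi,
                                 nResamples = 1, seed = 64),
               "tol|target")
  expect_error(matchedResampling(early, lateSal[1:10], lateDoi[1:10],
                                 subsetSize = 50), "smaller")
})

test_that("early/late splitting and effect comparison behave", {
  expect_identical(earlyLateSplit(c(1, 2, 3, 5)),
                   c("early", "early", "late", "late"))
  withr::with_seed(65, {
    a <- rnorm(40, 0.1, 0.05); b <- rnorm(40, 0.1, 0.05)
  })
  cmp <- effectComparison(a, b)
  expect_gt(cmp$p, 0.05)
  expect_equal(cmp$n_early, 40)
})
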