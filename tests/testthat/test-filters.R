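test_that("stability filter uses relative change with a closed 30% boundary", {
  pre <- respFrame(evoked = rep(10, 10), baseline = rep(4, 10),
                   period = "pre")
  cases <- list(list(sal = 12, stable = TRUE),   # 20% change
                list(sal = 14, stable = FALSE),  # 40% change
                list(sal = 13, stable = TRUE))   # exactly 30%
  for (cs in cases) {
    sal <- respFrame(evoked = rep(cs$sal, 10), baseline = rep(4, 10))
    got <- stabilityFilter(pre, sal)
    expect_identical(got$stable, cs$stable)
  }
  expect_equal(stabilityFilter(pre, respFrame(rep(12, 10),
                                              rep(4, 10)))$change_evoked,
               0.2)
  # zero pre-period rate: stable only when saline is also silent
  silent <- respFrame(evoked = rep(0, 10), baseline = rep(0, 10),
                      period = "pre")
  expect_true(stabilityFilter(silent, respFrame(rep(0, 10),
                                                rep(0, 10)))$stable)
  unstable <- stabilityFilter(silent, respFrame(rep(3, 10), rep(0, 10)))
  expect_false(unstable$stable)
  expect_match(unstable$diagnostic, "division by zero")
})

test_that("responsiveness needs a corrected signed-rank difference", {
  flat <- respFrame(evoked = rep(7, 20), baseline = rep(7, 20))
  expect_false(responsivenessTest(flat)$responsive)

  # strong response: power > 0.99 across seeded replicates
  hits <- vapply(1:50, function(i) {
    withr::with_seed(i, {
      d <- respFrame(evoked = rpois(20, 30) / 0.1 * 0.1,
                     baseline = rpois(20, 10) / 0.1 * 0.1)
      responsivenessTest(d)$responsive
    })
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  # Bonferroni correction scales the minimum p by the family size
  withr::with_seed(1, {
    one <- respFrame(evoked = rpois(30, 20), baseline = rpois(30, 10))
    many <- rbind(one, do.call(rbind, lapply(2:16, function(k)
      respFrame(evoked = rpois(30, 10), baseline = rpois(30, 10),
                stimulus = paste0("s", k)))))
  })
  p1 <- responsivenessTest(one)$min_p_corrected
  p16 <- responsivenessTest(many)$min_p_corrected
  expect_equal(p16, min(p1 * 16, 1), tolerance = 1e-10)
  # adding stimuli can never create responsiveness (Bonferroni monotone)
  expect_true(responsivenessTest(many)$responsive <=
                responsivenessTest(one)$responsive)
})

test_that("evoked floor requires > 5 spk/s in every period", {
  mk <- function(rates) do.call(rbind, Map(function(r, p)
    respFrame(evoked = rep(r, 8), baseline = 0, period = p),
    rates, c("pre", "saline", "doi")))
  expect_true(evokedFloor(mk(c(8, 6, 5.5)))$ok)
  expect_false(evokedFloor(mk(c(8, 6, 4)))$ok)
  expect_false(evokedFloor(mk(c(8, 6, 5.0)))$ok)  # exactly 5 fails
  missing <- evokedFloor(mk(c(8, 6, 7))[-(17:24), ])
  expect_false(missing$ok)
  expect_match(missing$diagnostic, "doi")
})

test_that("locomotion classification smooths with a 10-frame boxcar", {
  # unit impulse: the smoothed plateau has value 1/10 over 10 frames
  trace <- c(rep(0, 100), 1, rep(0, 100))
  onsets <- (0:200) / 30
  got <- classifyLocomotion(trace, onsets, threshold = 1 / 10 - 1e-6)
  expect_equal(sum(got, na.rm = TRUE), 10)
  none <- classifyLocomotion(trace, onsets, threshold = 1 / 10 + 1e-6)
  expect_false(any(none, na.rm = TRUE))

  # onsets outside the trace span are unknown
  out <- classifyLocomotion(rep(0.2, 50), c(1, 100), threshold = 0.1)
  expect_identical(out[1], TRUE)
  expect_true(is.na(out[2]))
})

test_that("OEI stability uses a strict 30% boundary", {
  expect_true(oeiStabilityFilter(0.40, 0.45))   # 12.5% change
  expect_false(oeiStabilityFilter(0.40, 0.20))  # 50% change
  expect_false(oeiStabilityFilter(0.40, 0.52))  # exactly 30%
  expect_true(oeiStabilityFilter(0, 0))
  expect_false(oeiStabilityFilter(0, 0.1))
  expect_identical(oeiStabilityFilter(c(0.4, 0.4), c(0.45, 0.2)),
                   c(TRUE, FALSE))
})

test_that("the inclusion report reproduces hand-computed decisions", {
  rates <- data.frame(
    neuron_id = sprintf("n%02d", 1:6),
    evoked_pre =    c(20, 20, 20, 20, 10, 20),
    evoked_saline = c(24, 30, 24, 24, 10, 24),  # n2: 50% evoked change
    evoked_doi =    c(22, 20, 4,  22, 10, 22),  # n3: below the 5 spk/s floor
    baseline_pre =    c(5, 5, 5, 5, 10, 5),
    baseline_saline = c(6, 5, 6, 8, 10, 6),     # n4: 60% spontaneous change
    baseline_doi =    c(5, 5, 5, 5, 10, 5))     # n5: evoked == baseline
  # n6 duplicates n1 (stable, responsive, above floor)
  s <- deterministicSession(rates)
  rep <- inclusionReport(alignAndCount(s))
  expect_identical(rep$included,
                   c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(rep$stable, c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(rep$evoked_floor_ok, c(TRUE, TRUE, FALSE, TRUE, TRUE,
                                          TRUE))
  expect_identical(rep$responsive, c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  # filters are idempotent: re-running reproduces the same report
  expect_identical(rep, inclusionReport(alignAndCount(s)))
})

test_that("stability pass rate approaches 1 without drift as trials grow", {
  hit <- function(n, seed) withr::with_seed(seed, {
    pre <- respFrame(evoked = rpois(n, 20), baseline = rpois(n, 5),
                     period = "pre")
    sal <- respFrame(evoked = rpois(n, 20), baseline = rpois(n, 5))
    stabilityFilter(pre, sal)$stable
  })
  few <- mean(vapply(1:40, function(i) hit(5, i), logical(1)))
  many <- mean(vapply(1:40, function(i) hit(200, i), logical(1)))
  expect_gte(many, few)
  expect_gte(many, 0.975)
})
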