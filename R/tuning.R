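gaussOnLog2 <- function(x, b, A, mu, sigma)
  b + A * exp(-(x - mu)^2 / (2 * sigma^2))

#' Fit a Gaussian frequency-tuning curve
#'
#' Least-squares fit of `r(x) = b + A exp(-(x - mu)^2 / (2 sigma^2))` to the
#' mean evoked rate per frequency, with `x = log2(frequency in kHz)` so that
#' `sigma` is in octaves and the full width at half maximum is
#' `2.355 sigma`. The fit is bounded (`mu` within the presented frequency
#' span, `sigma` in `[0.05, 5]` octaves) and multi-started from a grid of
#' peak positions (every presented frequency) crossed with
#' `sigma` in {0.25, 0.5, 1, 2}; the start with the best converged
#' sum-of-squares wins, ties broken by the first grid point.
#'
#' The best frequency is the fitted peak position; `maxDeltaFiring` is the
#' Gaussian peak rate minus the baseline rate (the measured baseline when
#' supplied, otherwise the fitted offset `b`, in which case it equals `A`).
#' R-squared is computed against the per-frequency means and set to 0 when
#' those means are constant (no variance to explain).
#'
#' @param meanRates Mean evoked rate (spk/s) per frequency.
#' @param freqsKhz Frequencies in kHz (same length, >= 4 distinct values).
#' @param baselineRate Optional measured baseline rate (spk/s).
#' @return A [TuningFit-class].
#' @examples
#' f <- tuningFrequencies()
#' r <- 5 + 20 * exp(-(log2(f) - log2(8))^2 / (2 * 0.5^2))
#' fitTuning(r, f)
#' @export
fitTuning <- function(meanRates, freqsKhz, baselineRate = NULL) {
  ok <- is.finite(meanRates) & is.finite(freqsKhz)
  meanRates <- meanRates[ok]; freqsKhz <- freqsKhz[ok]
  if (length(unique(freqsKhz)) < 4)
    stop("need mean rates at >= 4 distinct frequencies")
  x <- log2(freqsKhz); y <- meanRates
  rngY <- max(y) - min(y)
  sse <- function(p) sum((y - gaussOnLog2(x, p[1], p[2], p[3], p[4]))^2)
  lower <- c(0, -3 * max(rngY, 1), min(x), 0.05)
  upper <- c(max(y) + rngY + 1, 3 * max(rngY, 1), max(x), 5)
  best <- NULL
  for (mu0 in sort(unique(x))) {
    for (s0 in c(0.25, 0.5, 1, 2)) {
      p0 <- c(max(min(y), 0), min(max(rngY, 1e-3), upper[2]), mu0, s0)
      fit <- tryCatch(
        optim(p0, sse, method = "L-BFGS-B", lower = lower, upper = upper),
        error = function(e) NULL)
      if (!is.null(fit) && fit$convergence == 0 &&
          (is.null(best) || fit$value < best$value - 1e-12))
        best <- fit
    }
  }
  if (is.null(best))
    return(new("TuningFit", bfKhz = NA_real_, sigmaLog2 = NA_real_,
               amplitude = NA_real_, offset = NA_real_,
               baselineRate = NA_real_, maxDeltaFiring = NA_real_,
               rSquared = NA_real_, converged = FALSE))
  p <- best$par
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best$value / sst else 0
  bl <- if (is.null(baselineRate)) p[1] else baselineRate
  new("TuningFit", bfKhz = 2^p[3], sigmaLog2 = p[4], amplitude = p[2],
      offset = p[1], baselineRate = bl,
      maxDeltaFiring = (p[1] + p[2]) - bl, rSquared = min(r2, 1),
      converged = TRUE)
}

#' Fit tuning curves for every neuron and period of a session
#'
#' Computes each neuron's mean evoked rate per tuning-block frequency and
#' period, fits [fitTuning()], and tabulates the fitted parameters together
#' with the inclusion gate used downstream: a converged fit with positive
#' amplitude and R-squared above `rSquaredGate`.
#'
#' @param se [alignAndCount()] SummarizedExperiment.
#' @param rSquaredGate Minimum R-squared for a usable fit.
#' @param neurons Optional neuron subset.
#' @return `data.frame`: `neuron_id`, `period`, `bf_khz`, `sigma_log2`,
#'   `width_octaves`, `amplitude`, `offset`, `baseline_rate`,
#'   `max_delta_firing`, `r_squared`, `converged`, `usable`.
#' @export
fitTuningAll <- function(se, rSquaredGate = 0.05, neurons = NULL) {
  resp <- trialResponses(se, neurons)
  tone <- resp[resp$role == "tuning", ]
  if (!nrow(tone)) stop("session has no tuning-block trials")
  rows <- lapply(split(tone, list(tone$neuron_id, tone$period),
                       drop = TRUE), function(d) {
    mr <- tapply(d$evoked_rate, d$stimulus_id, mean)
    fr <- tapply(d$center_khz, d$stimulus_id, function(z) z[1])
    fit <- fitTuning(as.numeric(mr), as.numeric(fr),
                     baselineRate = mean(d$baseline_rate))
    data.frame(neuron_id = d$neuron_id[1], period = d$period[1],
               bf_khz = fit@bfKhz, sigma_log2 = fit@sigmaLog2,
               width_octaves = widthOctaves(fit),
               amplitude = fit@amplitude, offset = fit@offset,
               baseline_rate = fit@baselineRate,
               max_delta_firing = fit@maxDeltaFiring,
               r_squared = fit@rSquared, converged = fit@converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$usable <- out$converged & !is.na(out$amplitude) &
    out$amplitude > 0 & out$r_squared > rSquaredGate
  rownames(out) <- NULL
  out
}

#' Population summary of tuning changes between saline and DOI
#'
#' Pairs each neuron's usable tuning fits in the two periods and summarizes
#' the per-neuron changes in best frequency (in octaves), tuning width and
#' maximum evoked firing (`max_delta_firing`): population medians with
#' paired signed-rank p-values, plus Pearson correlations of the saline BF
#' and width with the change in evoked-response magnitude.
#'
#' @param fits [fitTuningAll()] table (or an equivalent pair of tables via
#'   `fitsDoi`).
#' @param fitsDoi Optional second table; by default both periods are taken
#'   from `fits`.
#' @param periods The two periods compared.
#' @return List with `pairs` (per-neuron deltas), `summary` (medians, n and
#'   p per metric) and `correlations`.
#' @export
tuningChangeSummary <- function(fits, fitsDoi = NULL,
                                periods = c("saline", "doi")) {
  a <- fits[fits$period == periods[1] & fits$usable, ]
  b <- if (is.null(fitsDoi)) fits[fits$period == periods[2] & fits$usable, ]
       else fitsDoi[fitsDoi$period == periods[2] & fitsDoi$usable, ]
  common <- intersect(a$neuron_id, b$neuron_id)
  a <- a[match(common, a$neuron_id), ]
  b <- b[match(common, b$neuron_id), ]
  pairs <- data.frame(
    neuron_id = common,
    d_bf_octaves = log2(b$bf_khz) - log2(a$bf_khz),
    d_width_octaves = b$width_octaves - a$width_octaves,
    d_max_delta_firing = b$max_delta_firing - a$max_delta_firing,
    stringsAsFactors = FALSE)
  summarize <- function(xa, xb) {
    data.frame(n = length(xa), median_a = median(xa), median_b = median(xb),
               median_delta = median(xb - xa),
               p = wilcoxSignedRank(xb, xa))
  }
  summary <- rbind(
    cbind(metric = "bf_octaves", summarize(log2(a$bf_khz), log2(b$bf_khz))),
    cbind(metric = "width_octaves",
          summarize(a$width_octaves, b$width_octaves)),
    cbind(metric = "max_delta_firing",
          summarize(a$max_delta_firing, b$max_delta_firing)))
  corWith <- function(x) {
    if (length(common) < 3) return(c(r = NA_real_, p = NA_real_))
    ct <- suppressWarnings(cor.test(x, pairs$d_max_delta_firing))
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  list(pairs = pairs, summary = summary,
       correlations = rbind(bf = corWith(log2(a$bf_khz)),
                            width = corWith(a$width_octaves)))
}
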