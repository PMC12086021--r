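#' Firing-rate stability between the pre-injection and saline periods
#'
#' Screens out neurons whose firing changed substantially with time in the
#' rig before any drug was given: the relative change of mean spontaneous
#' (baseline-window) firing and of mean evoked firing between the
#' pre-injection and saline periods, `|saline - pre| / pre`, must both be
#' at most `maxChange`. A change of exactly `maxChange` passes (the
#' criterion excludes changes *greater than* 30%). A zero pre-period mean
#' is stable only if the saline mean is also zero; otherwise the neuron is
#' flagged unstable with a `"division by zero rate"` diagnostic.
#'
#' @param respPre,respSal [trialResponses()] rows of one neuron for the
#'   pre-injection and saline periods.
#' @param maxChange Maximum tolerated relative change.
#' @return List: `stable`, `change_spont`, `change_evoked`, `diagnostic`.
#' @export
stabilityFilter <- function(respPre, respSal, maxChange = 0.30) {
  stopifnot(nrow(respPre) >= 1, nrow(respSal) >= 1)
  relChange <- function(pre, sal) {
    if (pre == 0) {
      if (sal == 0) 0 else Inf
    } else abs(sal - pre) / pre
  }
  cs <- relChange(mean(respPre$baseline_rate), mean(respSal$baseline_rate))
  ce <- relChange(mean(respPre$evoked_rate), mean(respSal$evoked_rate))
  list(stable = cs <= maxChange && ce <= maxChange,
       change_spont = cs, change_evoked = ce,
       diagnostic = if (!is.finite(cs) || !is.finite(ce))
         "division by zero rate" else NA_character_)
}

#' Sound responsiveness by paired signed-rank test
#'
#' For each stimulus, tests whether evoked firing differs from baseline
#' firing across trials (paired Wilcoxon signed-rank on per-trial rates),
#' and Bonferroni-corrects over the number of stimuli tested. A neuron is
#' responsive if any corrected p-value falls below `alpha`. Stimuli whose
#' paired differences are all zero are undefined under the signed-rank test
#' and treated as p = 1.
#'
#' @param resp [trialResponses()] rows of one neuron (typically one period).
#' @param alpha Significance level on the corrected p-values.
#' @param minTrials Minimum trials per stimulus for a defined test.
#' @return List: `responsive`, `min_p_corrected`, and `p_table` (per
#'   stimulus raw and corrected p-values).
#' @export
responsivenessTest <- function(resp, alpha = 0.05, minTrials = 6L) {
  byStim <- split(resp, resp$stimulus_id)
  praw <- vapply(byStim, function(d) {
    p <- wilcoxSignedRank(d$evoked_rate, d$baseline_rate,
                          minPairs = minTrials)
    if (is.na(p)) p <- 1  # degenerate: no usable evidence
    p
  }, numeric(1))
  pcor <- pmin(praw * length(praw), 1)
  list(responsive = any(pcor < alpha),
       min_p_corrected = if (length(pcor)) min(pcor) else NA_real_,
       p_table = data.frame(stimulus_id = names(praw), p_raw = unname(praw),
                            p_corrected = unname(pcor),
                            stringsAsFactors = FALSE))
}

#' Evoked-rate floor across all periods
#'
#' Requires the neuron's strongest stimulus (largest mean evoked rate) to
#' exceed `floor` spk/s in every period; a maximum of exactly `floor` fails
#' (the criterion requires rates *above* the floor).
#'
#' @param resp [trialResponses()] rows of one neuron covering all periods.
#' @param floor Evoked-rate floor in spk/s.
#' @param periods Periods that must all pass.
#' @return List: `ok`, `max_evoked` (named per period), `diagnostic`.
#' @export
evokedFloor <- function(resp, floor = 5, periods = PERIODS) {
  maxByPeriod <- vapply(periods, function(p) {
    d <- resp[resp$period == p, ]
    if (!nrow(d)) return(NA_real_)
    max(tapply(d$evoked_rate, d$stimulus_id, mean))
  }, numeric(1))
  missing <- periods[is.na(maxByPeriod)]
  list(ok = all(!is.na(maxByPeriod)) && all(maxByPeriod > floor),
       max_evoked = maxByPeriod,
       diagnostic = if (length(missing))
         sprintf("missing period(s): %s", paste(missing, collapse = ", "))
       else NA_character_)
}

#' Otsu threshold of a bimodal series
#'
#' Histogram-based threshold maximizing between-class variance; used as the
#' default motion-energy threshold separating the quiet and running modes.
#'
#' @param x Numeric vector.
#' @param nBins Number of histogram bins.
#' @return Threshold value.
#' @export
otsuThreshold <- function(x, nBins = 256L) {
  x <- x[is.finite(x)]
  if (diff(range(x)) == 0) return(x[1])
  h <- graphics::hist(x, breaks = seq(min(x), max(x),
                                      length.out = nBins + 1), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[length(mu)]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  mids[which.max(sigmaB)]
}

#' Classify locomotion state at each trial onset
#'
#' Boxcar-smooths the motion-energy trace with a `smoothFrames`-frame square
#' window and thresholds the smoothed value at the frame nearest each
#' stimulus onset: running if the value exceeds the threshold. With
#' `threshold = NULL` an Otsu threshold between the two modes of the
#' smoothed trace is used. Onsets outside the trace span get `NA` (unknown).
#'
#' @param trace Motion-energy series, one value per frame from time 0.
#' @param onsets Trial onset times (s).
#' @param frameRateHz Frame rate of `trace` (Hz).
#' @param smoothFrames Boxcar width in frames.
#' @param threshold Motion-energy threshold, or `NULL` for Otsu.
#' @return Logical vector of running flags (`NA` = unknown), with the
#'   threshold used in attribute `"threshold"`.
#' @export
classifyLocomotion <- function(trace, onsets, frameRateHz = 30,
                               smoothFrames = 10L, threshold = NULL) {
  sm <- as.numeric(stats::filter(trace, rep(1 / smoothFrames, smoothFrames),
                                 sides = 2))
  # boxcar leaves NA at the edges; carry the nearest defined value
  ok <- which(!is.na(sm))
  if (!length(ok)) stop("trace shorter than the smoothing window")
  sm[seq_len(ok[1] - 1)] <- sm[ok[1]]
  sm[seq(ok[length(ok)] + 1, length.out = length(sm) - ok[length(ok)])] <-
    sm[ok[length(ok)]]
  if (is.null(threshold)) threshold <- otsuThreshold(sm)
  frames <- round(onsets * frameRateHz) + 1
  out <- rep(NA, length(onsets))
  inSpan <- frames >= 1 & frames <= length(sm)
  out[inSpan] <- sm[frames[inSpan]] > threshold
  structure(as.logical(out), threshold = threshold)
}

#' Oddball-enhancement-index stability between pre-injection and saline
#'
#' Keeps neurons whose OEI varied by less than `maxChange` (relative to the
#' pre-injection magnitude) between the pre-injection and saline periods;
#' a change of exactly `maxChange` is dropped (the criterion is *less
#' than* 30%). Vectorized over neurons; zero pre-injection OEI passes only
#' if the saline OEI is also zero.
#'
#' @param oeiPre,oeiSal OEI values in the two periods.
#' @param maxChange Maximum tolerated relative change (exclusive).
#' @return Logical vector (`NA` where either OEI is undefined).
#' @export
oeiStabilityFilter <- function(oeiPre, oeiSal, maxChange = 0.30) {
  change <- ifelse(oeiPre == 0, ifelse(oeiSal == 0, 0, Inf),
                   abs(oeiSal - oeiPre) / abs(oeiPre))
  change < maxChange
}

#' Per-neuron inclusion report
#'
#' Applies the neuron-inclusion criteria to every neuron of a session:
#' (1) spontaneous and evoked firing stable (change <= 30%) between the
#' pre-injection and saline periods, pooled over all trials; (2) responsive
#' to the tuning tones (Bonferroni-corrected signed-rank) in every period;
#' (3) maximum mean evoked tone rate above `floor` spk/s in every period.
#' Included neurons are exactly those passing all three.
#'
#' @param se [alignAndCount()] SummarizedExperiment of the session.
#' @param alpha Responsiveness significance level.
#' @param maxChange Stability threshold.
#' @param floor Evoked-rate floor (spk/s).
#' @param stimuliRole Trials used for responsiveness and the floor
#'   (default the tuning block).
#' @return `data.frame`, one row per neuron: flags `stable`, `responsive`,
#'   `evoked_floor_ok`, `included`, plus diagnostics (`change_spont`,
#'   `change_evoked`, `min_p_corrected`, `max_evoked_min` = the smallest
#'   per-period maximum evoked rate).
#' @export
inclusionReport <- function(se, alpha = 0.05, maxChange = 0.30, floor = 5,
                            stimuliRole = "tuning") {
  resp <- trialResponses(se)
  tone <- resp[resp$role %in% stimuliRole, ]
  out <- lapply(split(resp, resp$neuron_id), function(d) {
    dt <- tone[tone$neuron_id == d$neuron_id[1], ]
    st <- stabilityFilter(d[d$period == "pre", ],
                          d[d$period == "saline", ], maxChange)
    rsp <- vapply(PERIODS, function(p) {
      dp <- dt[dt$period == p, ]
      if (!nrow(dp)) return(c(FALSE, NA_real_))
      r <- responsivenessTest(dp, alpha)
      c(r$responsive, r$min_p_corrected)
    }, numeric(2))
    fl <- evokedFloor(dt, floor)
    data.frame(neuron_id = d$neuron_id[1], stable = st$stable,
               responsive = all(rsp[1, ] == 1),
               evoked_floor_ok = fl$ok,
               change_spont = st$change_spont,
               change_evoked = st$change_evoked,
               min_p_corrected = max(rsp[2, ]),
               max_evoked_min = min(fl$max_evoked),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$included <- out$stable & out$responsive & out$evoked_floor_ok
  rownames(out) <- NULL
  out
}
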