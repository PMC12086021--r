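#' Oddball enhancement index
#'
#' `OEI = (O - S) / (O + S)` for mean oddball response `O` and mean
#' standard response `S`. Undefined (NA) when the denominator is not
#' positive. Vectorized.
#'
#' @param o,s Mean evoked rates (spk/s) of a sound as oddball and as
#'   standard.
#' @return OEI in `[-1, 1]` for nonnegative inputs; `NA` when `o + s <= 0`.
#' @examples
#' computeOEI(10, 5) # 1/3
#' @export
computeOEI <- function(o, s) ifelse(o + s > 0, (o - s) / (o + s), NA_real_)

#' Drug modulation index
#'
#' `MI = (DOI - Sal) / (DOI + Sal)` for mean responses under the two
#' conditions; negative values mean weaker responses under the drug.
#' Undefined (NA) when the denominator is not positive. Vectorized.
#'
#' @param sal,doi Mean responses under saline and DOI.
#' @return MI in `[-1, 1]` for nonnegative inputs; `NA` when
#'   `sal + doi <= 0`.
#' @examples
#' computeMI(10, 5) # -1/3
#' @export
computeMI <- function(sal, doi)
  ifelse(sal + doi > 0, (doi - sal) / (doi + sal), NA_real_)

#' Per neuron x stimulus x period oddball responses
#'
#' Averages each neuron's evoked rate over a sound's oddball presentations
#' (from the block where it is the rare stimulus) and over its standard
#' presentations (from the role-swapped companion block), and derives the
#' OEI. Optionally excludes the first standard after each oddball from the
#' standard average.
#'
#' @param resp [trialResponses()] rows (any number of neurons).
#' @param excludeFirstStandard Drop the standard immediately following each
#'   oddball within a block.
#' @return `data.frame`: `neuron_id`, `stimulus_id`, `period`, `o`, `s`,
#'   `n_oddball`, `n_standard`, `oei`.
#' @export
oddballResponses <- function(resp, excludeFirstStandard = FALSE) {
  if (is.null(resp$neuron_id)) resp$neuron_id <- "n1"
  d <- resp[resp$role %in% c("standard", "oddball"), ]
  if (!nrow(d)) stop("no oddball-block trials in responses")
  if (excludeFirstStandard) {
    d <- d[order(d$neuron_id, d$block_id, d$onset_s), ]
    prevOdd <- c(FALSE, d$role[-nrow(d)] == "oddball") &
      c(TRUE, d$block_id[-nrow(d)] == d$block_id[-1]) &
      c(TRUE, d$neuron_id[-nrow(d)] == d$neuron_id[-1])
    d <- d[!(d$role == "standard" & prevOdd), ]
  }
  agg <- aggregate(evoked_rate ~ neuron_id + stimulus_id + period + role,
                   data = d, FUN = mean)
  cnt <- aggregate(evoked_rate ~ neuron_id + stimulus_id + period + role,
                   data = d, FUN = length)
  key <- function(df) paste(df$neuron_id, df$stimulus_id, df$period)
  odd <- agg[agg$role == "oddball", ]
  std <- agg[agg$role == "standard", ]
  co <- cnt[cnt$role == "oddball", ]
  cs <- cnt[cnt$role == "standard", ]
  keys <- unique(key(agg))
  out <- data.frame(do.call(rbind, strsplit(keys, " ")),
                    stringsAsFactors = FALSE)
  names(out) <- c("neuron_id", "stimulus_id", "period")
  out$o <- odd$evoked_rate[match(keys, key(odd))]
  out$s <- std$evoked_rate[match(keys, key(std))]
  out$n_oddball <- co$evoked_rate[match(keys, key(co))]
  out$n_standard <- cs$evoked_rate[match(keys, key(cs))]
  out$oei <- computeOEI(out$o, out$s)
  out[order(out$neuron_id, out$stimulus_id,
            match(out$period, PERIODS)), , drop = FALSE] |>
    (\(x) { rownames(x) <- NULL; x })()
}

#' Per neuron x stimulus x role drug-modulation indices
#'
#' Computes `MI = (DOI - Sal)/(DOI + Sal)` separately for a sound's oddball
#' responses and its standard responses.
#'
#' @param odd [oddballResponses()] table.
#' @param periods The two compared periods (reference first).
#' @return `data.frame`: `neuron_id`, `stimulus_id`, `role`, `mi`.
#' @export
modulationIndices <- function(odd, periods = c("saline", "doi")) {
  a <- odd[odd$period == periods[1], ]
  b <- odd[odd$period == periods[2], ]
  key <- function(df) paste(df$neuron_id, df$stimulus_id)
  i <- match(key(a), key(b))
  a <- a[!is.na(i), ]; b <- b[i[!is.na(i)], ]
  rbind(
    data.frame(neuron_id = a$neuron_id, stimulus_id = a$stimulus_id,
               role = "oddball", mi = computeMI(a$o, b$o),
               stringsAsFactors = FALSE),
    data.frame(neuron_id = a$neuron_id, stimulus_id = a$stimulus_id,
               role = "standard", mi = computeMI(a$s, b$s),
               stringsAsFactors = FALSE))
}

#' Paired population comparison of OEI between two periods
#'
#' For each oddball stimulus, pairs neurons' OEIs in the two periods and
#' reports the medians and a two-sided Wilcoxon signed-rank p-value
#' (undefined below 6 pairs). Neurons with an undefined OEI in either
#' period are excluded pairwise. Apply responsiveness / OEI-stability
#' screens by subsetting `odd` beforehand (e.g. with [inclusionReport()]
#' and [oeiStabilityFilter()]).
#'
#' @param odd [oddballResponses()] table, already filtered to the analysis
#'   population.
#' @param periods The two compared periods (reference first).
#' @return `data.frame` per stimulus: `n`, `median_ref`, `median_cmp`, `p`.
#' @export
populationTests <- function(odd, periods = c("saline", "doi")) {
  a <- odd[odd$period == periods[1], ]
  b <- odd[odd$period == periods[2], ]
  key <- function(df) paste(df$neuron_id, df$stimulus_id)
  i <- match(key(a), key(b))
  a2 <- a[!is.na(i), ]; b2 <- b[i[!is.na(i)], ]
  rows <- lapply(split(seq_len(nrow(a2)), a2$stimulus_id), function(idx) {
    x <- a2$oei[idx]; y <- b2$oei[idx]
    ok <- is.finite(x) & is.finite(y)
    data.frame(stimulus_id = a2$stimulus_id[idx[1]], n = sum(ok),
               median_ref = median(x[ok]), median_cmp = median(y[ok]),
               p = wilcoxSignedRank(x[ok], y[ok]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adaptation control: drug effect versus passage of time
#'
#' Distinguishes drug effects from slow response adaptation over the
#' session by comparing, for each oddball stimulus, the change in oddball
#' responses from pre-injection to saline with the change from saline to
#' DOI: signed-rank tests on the paired oddball responses for each step,
#' and a paired comparison of the per-neuron modulation indices
#' `MI(Pre->Sal)` versus `MI(Sal->DOI)`. Run on all neurons responsive to
#' the stimulus, without the OEI-stability screen.
#'
#' @param odd [oddballResponses()] table.
#' @return `data.frame` per stimulus: `n`, `p_pre_sal`, `p_sal_doi`,
#'   `median_mi_pre_sal`, `median_mi_sal_doi`, `p_mi_paired`.
#' @export
adaptationControl <- function(odd) {
  wide <- lapply(split(odd, odd$stimulus_id), function(d) {
    byP <- split(d, d$period)
    common <- Reduce(intersect, lapply(byP[PERIODS], `[[`, "neuron_id"))
    o <- vapply(PERIODS, function(p)
      byP[[p]]$o[match(common, byP[[p]]$neuron_id)],
      numeric(length(common)))
    if (length(common) == 1) o <- matrix(o, 1, dimnames = list(NULL, PERIODS))
    miPreSal <- computeMI(o[, "pre"], o[, "saline"])
    miSalDoi <- computeMI(o[, "saline"], o[, "doi"])
    ok <- is.finite(miPreSal) & is.finite(miSalDoi)
    data.frame(stimulus_id = d$stimulus_id[1], n = sum(ok),
               p_pre_sal = wilcoxSignedRank(o[, "saline"], o[, "pre"]),
               p_sal_doi = wilcoxSignedRank(o[, "doi"], o[, "saline"]),
               median_mi_pre_sal = median(miPreSal[ok]),
               median_mi_sal_doi = median(miSalDoi[ok]),
               p_mi_paired = wilcoxSignedRank(miSalDoi[ok], miPreSal[ok]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, wide)
  rownames(out) <- NULL
  out
}

#' Early/late session split
#'
#' Labels the first two sessions of each animal "early" and the remaining
#' sessions "late".
#'
#' @param sessionIndex Integer session number within animal (1-based).
#' @param nEarly Number of early sessions.
#' @return Character vector of `"early"` / `"late"` labels.
#' @export
earlyLateSplit <- function(sessionIndex, nEarly = 2L)
  ifelse(sessionIndex <= nEarly, "early", "late")

#' Compare the drug effect between two neuron groups
#'
#' Unpaired two-sided Mann-Whitney U test on per-neuron effect sizes
#' (e.g. OEI(saline) - OEI(DOI)) between neurons recorded in early versus
#' late sessions.
#'
#' @param effectEarly,effectLate Per-neuron effect values.
#' @return List with group medians, ns, and the p-value.
#' @export
effectComparison <- function(effectEarly, effectLate) {
  list(n_early = sum(is.finite(effectEarly)),
       n_late = sum(is.finite(effectLate)),
       median_early = median(effectEarly, na.rm = TRUE),
       median_late = median(effectLate, na.rm = TRUE),
       p = mannWhitneyU(effectEarly, effectLate))
}

#' Saline-OEI-matched resampling control
#'
#' Tests whether a weaker drug effect in late sessions merely reflects
#' sampling neurons with lower control-period OEI: repeatedly draws subsets
#' of the late-session neurons (without replacement) whose mean saline OEI
#' matches the early-session mean within `tol`, and reports in what
#' fraction of resamples the subset's median saline OEI exceeds its median
#' DOI OEI.
#'
#' Each resample starts from a random subset and stochastically swaps
#' members for non-members that move the subset mean toward the target,
#' accepting only improvements; a resample failing to reach `tol` within
#' `maxAttempts` swap proposals raises an error with diagnostics.
#'
#' @param earlySal Early-session saline OEIs (defines the target mean).
#' @param lateSal,lateDoi Late-session saline and DOI OEIs, aligned by
#'   neuron.
#' @param nResamples Number of matched subsets to draw.
#' @param subsetSize Size of each subset (default: early-set size, capped
#'   at the late-set size).
#' @param tol Tolerance on `|mean(subset saline OEI) - mean(early)|`.
#' @param maxAttempts Maximum swap proposals per resample.
#' @param seed Optional seed.
#' @return List: `fraction_sal_gt_doi`, `n_resamples`, `target_mean`,
#'   `subset_size`, and a `resamples` data.frame (per resample: achieved
#'   mean, median saline and DOI OEI).
#' @export
matchedResampling <- function(earlySal, lateSal, lateDoi, nResamples = 100,
                              subsetSize = NULL, tol = 0.01,
                              maxAttempts = 10000, seed = NULL) {
  stopifnot(length(lateSal) == length(lateDoi))
  target <- mean(earlySal)
  if (!is.finite(target)) stop("early-session mean OEI is undefined")
  k <- if (is.null(subsetSize)) min(length(earlySal), length(lateSal))
       else subsetSize
  if (k > length(lateSal))
    stop("late set smaller than the requested subset size")
  withSeed(seed, {
    draws <- lapply(seq_len(nResamples), function(r) {
      idx <- sample(length(lateSal), k)
      attempts <- 0L
      repeat {
        diffNow <- mean(lateSal[idx]) - target
        if (abs(diffNow) <= tol) break
        if (attempts >= maxAttempts)
          stop(sprintf(paste0("no matched subset within tol %.3g after %d ",
                              "attempts (resample %d, residual %.3g)"),
                       tol, maxAttempts, r, diffNow))
        attempts <- attempts + 1L
        pool <- setdiff(seq_along(lateSal), idx)
        if (!length(pool))
          stop(sprintf("subset uses the whole late set but its mean misses the target by %.3g (> tol %.3g)",
                       diffNow, tol))
        out <- idx[sample.int(length(idx), 1)]
        cand <- pool[sample.int(length(pool), 1)]
        diffNew <- diffNow + (lateSal[cand] - lateSal[out]) / k
        if (abs(diffNew) < abs(diffNow)) idx[idx == out] <- cand
      }
      data.frame(mean_sal = mean(lateSal[idx]),
                 median_sal = median(lateSal[idx]),
                 median_doi = median(lateDoi[idx]))
    })
    res <- do.call(rbind, draws)
    list(fraction_sal_gt_doi = mean(res$median_sal > res$median_doi),
         n_resamples = nResamples, target_mean = target, subset_size = k,
         resamples = res)
  })
}
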