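#' Fano factor of one stimulus's responses
#'
#' `FF = var / mean` across repeated presentations, with the unbiased
#' (n - 1) variance. Undefined (NA) for fewer than `minTrials` trials or a
#' zero mean. The classical definition operates on spike counts; rates over
#' a fixed window give values scaled by `1 / window length`.
#'
#' @param x Responses across trials (counts, or rates over a fixed window).
#' @param minTrials Minimum trials for a defined FF.
#' @return The Fano factor, or `NA`.
#' @examples
#' fanoFactor(c(0, 4)) # mean 2, unbiased var 8 -> FF 4
#' @export
fanoFactor <- function(x, minTrials = 2L) {
  x <- x[is.finite(x)]
  if (length(x) < minTrials || mean(x) == 0) return(NA_real_)
  var(x) / mean(x)
}

#' Neuron-level Fano factors per period
#'
#' Computes the Fano factor of each tuning stimulus's evoked spike counts
#' for every neuron and period, then averages across stimuli within the
#' neuron. With `split = "running"` or `"stationary"` only trials in that
#' locomotion state are used and a stimulus enters the neuron average only
#' if it has at least `minTrialsSplit` trials in *each* running state; the
#' unsplit analysis requires `minTrials` trials per stimulus.
#'
#' @param resp [trialResponses()] rows.
#' @param split One of `"all"`, `"running"`, `"stationary"`.
#' @param minTrials Minimum trials per stimulus (unsplit analysis).
#' @param minTrialsSplit Minimum trials per stimulus in each running state
#'   (split analyses).
#' @param on Compute FF on `"count"` (classical, default) or `"rate"`.
#' @param role Trials analyzed (default the tuning block).
#' @return `data.frame`: `neuron_id`, `period`, `split`, `ff_mean`,
#'   `n_stimuli_included`.
#' @export
fanoByNeuron <- function(resp, split = c("all", "running", "stationary"),
                         minTrials = 2L, minTrialsSplit = 4L,
                         on = c("count", "rate"), role = "tuning") {
  split <- match.arg(split)
  on <- match.arg(on)
  d <- resp[resp$role %in% role, ]
  val <- if (on == "count") d$evoked_count else d$evoked_rate
  d$.value <- val
  rows <- lapply(base::split(d, list(d$neuron_id, d$period), drop = TRUE),
                 function(g) {
    ffs <- vapply(base::split(g, g$stimulus_id), function(s) {
      if (split == "all") {
        if (nrow(s) < minTrials) return(NA_real_)
        return(fanoFactor(s$.value, minTrials))
      }
      run <- s[!is.na(s$running) & s$running, ]
      sta <- s[!is.na(s$running) & !s$running, ]
      if (nrow(run) < minTrialsSplit || nrow(sta) < minTrialsSplit)
        return(NA_real_)  # needs >= minTrialsSplit trials in each state
      use <- if (split == "running") run else sta
      fanoFactor(use$.value, minTrialsSplit)
    }, numeric(1))
    data.frame(neuron_id = g$neuron_id[1], period = g$period[1],
               split = split,
               ff_mean = if (any(is.finite(ffs))) mean(ffs[is.finite(ffs)])
                         else NA_real_,
               n_stimuli_included = sum(is.finite(ffs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population comparison of Fano factors between two periods
#'
#' Pairs neuron-level Fano factors across the two periods and reports the
#' per-condition medians, the paired signed-rank p-value, and the
#' percentage of neurons whose FF is larger in the second period.
#'
#' @param ff [fanoByNeuron()] table.
#' @param periods The two compared periods (reference first).
#' @return List: `n`, `median_ref`, `median_cmp`, `p`, `pct_increased`.
#' @export
fanoSummary <- function(ff, periods = c("saline", "doi")) {
  a <- ff[ff$period == periods[1], ]
  b <- ff[ff$period == periods[2], ]
  i <- match(a$neuron_id, b$neuron_id)
  a2 <- a[!is.na(i), ]; b2 <- b[i[!is.na(i)], ]
  ok <- is.finite(a2$ff_mean) & is.finite(b2$ff_mean)
  x <- a2$ff_mean[ok]; y <- b2$ff_mean[ok]
  list(n = sum(ok), median_ref = median(x), median_cmp = median(y),
       p = wilcoxSignedRank(x, y),
       pct_increased = 100 * mean(y > x))
}
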