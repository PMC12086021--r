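#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline with the study defaults:
#' 15 ms evoked-window latency, (-200, 0) ms baseline window, alpha 0.05,
#' 30% stability thresholds (firing rate and OEI), 5 spk/s evoked floor,
#' R-squared gate 0.05 for tuning fits, 10-frame locomotion smoothing with
#' an automatic (Otsu) threshold, Fano-factor trial minimums (2 unsplit,
#' 4 per running state), and 100 matched resamples at tolerance 0.01.
#'
#' @param latencyS Evoked-window latency shift (s).
#' @param baselineS Baseline window relative to onset (s).
#' @param alpha Significance level of the responsiveness tests.
#' @param maxChange Firing-rate stability threshold (fraction).
#' @param evokedFloor Evoked-rate floor (spk/s).
#' @param rSquaredGate Minimum tuning-fit R-squared.
#' @param oeiMaxChange OEI stability threshold (fraction).
#' @param smoothFrames Locomotion boxcar width (frames).
#' @param motionThreshold Motion-energy threshold (`NULL` = Otsu).
#' @param ffMinTrials,ffMinTrialsSplit Fano-factor trial minimums.
#' @param resamples,resampleTol,resampleMaxAttempts Matched-resampling
#'   parameters.
#' @param excludeFirstStandard Drop the first standard after each oddball
#'   from standard averages.
#' @param seed Seed for the resampling control (`NULL` = current stream).
#' @return A validated list with class `AnalysisConfig`.
#' @export
analysisConfig <- function(latencyS = 0.015, baselineS = c(-0.2, 0),
                           alpha = 0.05, maxChange = 0.30, evokedFloor = 5,
                           rSquaredGate = 0.05, oeiMaxChange = 0.30,
                           smoothFrames = 10L, motionThreshold = NULL,
                           ffMinTrials = 2L, ffMinTrialsSplit = 4L,
                           resamples = 100L, resampleTol = 0.01,
                           resampleMaxAttempts = 10000L,
                           excludeFirstStandard = FALSE, seed = NULL) {
  cfg <- list(latencyS = latencyS, baselineS = baselineS, alpha = alpha,
              maxChange = maxChange, evokedFloor = evokedFloor,
              rSquaredGate = rSquaredGate, oeiMaxChange = oeiMaxChange,
              smoothFrames = as.integer(smoothFrames),
              motionThreshold = motionThreshold,
              ffMinTrials = as.integer(ffMinTrials),
              ffMinTrialsSplit = as.integer(ffMinTrialsSplit),
              resamples = as.integer(resamples),
              resampleTol = resampleTol,
              resampleMaxAttempts = as.integer(resampleMaxAttempts),
              excludeFirstStandard = isTRUE(excludeFirstStandard),
              seed = seed)
  stopifnot(alpha > 0, alpha < 1, maxChange >= 0, evokedFloor >= 0,
            rSquaredGate >= 0, rSquaredGate < 1, smoothFrames >= 1,
            ffMinTrials >= 2, ffMinTrialsSplit >= 2, resamples >= 1,
            resampleTol > 0, length(baselineS) == 2,
            baselineS[1] < baselineS[2])
  structure(cfg, class = "AnalysisConfig")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return `readAnalysisConfig` returns an `AnalysisConfig`;
#'   `writeAnalysisConfig` returns `path` invisibly.
#' @export
readAnalysisConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysisConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  do.call(analysisConfig, vals)
}

#' @rdname readAnalysisConfig
#' @param config An `AnalysisConfig`.
#' @export
writeAnalysisConfig <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path,
                   precision = 15)
  invisible(path)
}

configHash <- function(config)
  fnv1a32(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 12))

# Neurons responsive to each oddball stimulus: per neuron, signed-rank of
# evoked vs baseline over the stimulus's trials in `period`, Bonferroni
# over the oddball stimuli tested.
stimulusResponsiveNeurons <- function(resp, alpha = 0.05,
                                      period = "saline") {
  d <- resp[resp$role %in% c("standard", "oddball") & resp$period == period, ]
  stims <- unique(d$stimulus_id)
  res <- lapply(split(d, d$neuron_id), function(g) {
    r <- responsivenessTest(g, alpha)
    r$p_table$neuron_id <- g$neuron_id[1]
    r$p_table
  })
  tab <- do.call(rbind, res)
  lapply(stats::setNames(stims, stims), function(s)
    tab$neuron_id[tab$stimulus_id == s & tab$p_corrected < alpha])
}

# Paired comparison of oddball-MI vs standard-MI per stimulus.
miSummary <- function(mi) {
  rows <- lapply(split(mi, mi$stimulus_id), function(d) {
    o <- d[d$role == "oddball", ]
    s <- d[d$role == "standard", ]
    s <- s[match(o$neuron_id, s$neuron_id), ]
    ok <- is.finite(o$mi) & is.finite(s$mi)
    data.frame(stimulus_id = d$stimulus_id[1], n = sum(ok),
               median_mi_oddball = median(o$mi[ok]),
               median_mi_standard = median(s$mi[ok]),
               p = wilcoxSignedRank(o$mi[ok], s$mi[ok]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on one session
#'
#' Executes the whole workflow: trial alignment, locomotion classification
#' (when trial running labels are absent and a motion trace is available),
#' neuron inclusion, tuning fits and their saline-vs-DOI summary, oddball
#' responses with OEI population tests (on neurons responsive to each
#' stimulus whose OEI is stable between pre-injection and saline),
#' modulation indices for oddballs versus standards, the adaptation
#' control (responsive neurons, OEI stability not required), and
#' Fano-factor comparisons overall and split by locomotion state.
#'
#' @param session An [OddballSession-class].
#' @param config An [analysisConfig()].
#' @return List of result tables: `inclusion`, `tuning_fits`,
#'   `tuning_change`, `oddball`, `oei_tests`, `mi`, `mi_summary`,
#'   `adaptation`, `fano`, `fano_summary`, plus `config_hash`.
#' @export
runPipeline <- function(session, config = analysisConfig()) {
  se <- alignAndCount(session, responseWindows(config$latencyS,
                                               config$baselineS))
  trials <- trialInfo(session)
  if (all(is.na(trials$running)) && length(motionTrace(session))) {
    run <- classifyLocomotion(motionTrace(session), trials$onset_s,
                              session@frameRateHz, config$smoothFrames,
                              config$motionThreshold)
    SummarizedExperiment::colData(se)$running <- as.logical(run)
  }
  resp <- trialResponses(se)
  inclusion <- inclusionReport(se, config$alpha, config$maxChange,
                               config$evokedFloor)
  included <- inclusion$neuron_id[inclusion$included]
  fits <- fitTuningAll(se, config$rSquaredGate,
                       neurons = if (length(included)) included else NULL)
  tuningChange <- tuningChangeSummary(fits)
  odd <- oddballResponses(resp, config$excludeFirstStandard)
  responsiveByStim <- stimulusResponsiveNeurons(resp, config$alpha)
  keyPS <- paste(odd$neuron_id, odd$stimulus_id)
  respOK <- keyPS %in% unlist(lapply(names(responsiveByStim), function(s)
    paste(responsiveByStim[[s]], s)))
  wide <- stats::reshape(odd[c("neuron_id", "stimulus_id", "period", "oei")],
                         idvar = c("neuron_id", "stimulus_id"),
                         timevar = "period", direction = "wide")
  stableOEI <- oeiStabilityFilter(wide$oei.pre, wide$oei.saline,
                                  config$oeiMaxChange)
  okKeys <- paste(wide$neuron_id, wide$stimulus_id)[!is.na(stableOEI) &
                                                      stableOEI]
  oddTested <- odd[respOK & keyPS %in% okKeys, ]
  oeiTests <- if (nrow(oddTested)) populationTests(oddTested) else NULL
  mi <- if (nrow(oddTested)) modulationIndices(oddTested) else NULL
  adaptation <- adaptationControl(odd[respOK, , drop = FALSE])
  respInc <- resp[resp$neuron_id %in% included, ]
  if (!nrow(respInc)) respInc <- resp
  fano <- do.call(rbind, lapply(c("all", "running", "stationary"),
    function(sp) fanoByNeuron(respInc, sp, config$ffMinTrials,
                              config$ffMinTrialsSplit)))
  fanoSumm <- lapply(stats::setNames(c("all", "running", "stationary"),
                                     c("all", "running", "stationary")),
                     function(sp) fanoSummary(fano[fano$split == sp, ]))
  list(inclusion = inclusion, tuning_fits = fits,
       tuning_change = tuningChange, oddball = odd, oei_tests = oeiTests,
       mi = mi, mi_summary = if (!is.null(mi)) miSummary(mi) else NULL,
       adaptation = adaptation, fano = fano, fano_summary = fanoSumm,
       config_hash = configHash(config))
}

#' Write pipeline results to a report directory
#'
#' Writes the result tables as CSV, a `summary.json` with the population
#' medians, ns and p-values (stamped with the configuration hash), and
#' optionally figures: OEI saline-vs-DOI scatter with a median cross,
#' median MI bars for oddballs versus standards, and a Fano-factor
#' scatter.
#'
#' @param results [runPipeline()] output.
#' @param outDir Output directory.
#' @param figures Write PNG figures.
#' @return `outDir`, invisibly.
#' @export
writeReport <- function(results, outDir, figures = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("inclusion", "tuning_fits", "oddball", "mi", "fano",
               "oei_tests", "mi_summary", "adaptation"))
    if (!is.null(results[[nm]]))
      write.csv(results[[nm]], file.path(outDir, paste0(nm, ".csv")),
                row.names = FALSE)
  summary <- list(
    config_hash = results$config_hash,
    n_neurons = nrow(results$inclusion),
    n_included = sum(results$inclusion$included),
    oei_tests = results$oei_tests,
    mi_summary = results$mi_summary,
    adaptation = results$adaptation,
    tuning_change = results$tuning_change$summary,
    fano_summary = results$fano_summary)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows",
                       pretty = TRUE)
  if (figures) {
    if (!is.null(results$oddball))
      saveFigure(plotOEIComparison(results$oddball),
                 file.path(outDir, "oei_scatter.png"), 7, 3)
    if (!is.null(results$mi))
      saveFigure(plotMIBars(results$mi),
                 file.path(outDir, "mi_bars.png"), 6, 3)
    fanoAll <- results$fano[results$fano$split == "all", ]
    if (nrow(fanoAll))
      saveFigure(plotFanoComparison(fanoAll),
                 file.path(outDir, "fano_scatter.png"), 4, 4)
  }
  invisible(outDir)
}

saveFigure <- function(p, path, width, height) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  print(p)
  grDevices::dev.off()
}
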