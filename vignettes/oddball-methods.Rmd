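---
title: "Analyzing deviance detection in auditory cortex with oddball"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing deviance detection in auditory cortex with oddball}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddball)
```

## The scientific problem

Auditory cortical neurons respond more strongly to a sound when it occurs
rarely (an *oddball*) than when the same sound is repeated frequently (a
*standard*). This deviance detection is probed with the oddball paradigm:
a sequence in which one sound is repeated 9–11 times before a single
presentation of the other sound, continued until at least 50 oddballs have
been delivered, and then repeated with the two roles exchanged so that
every sound is measured both as standard and as oddball.

`oddball` implements a complete analysis pipeline for such experiments in
which each recording session contains three periods — before any
injection (`pre`), after a saline control injection (`saline`), and after
administration of the serotonergic psychedelic DOI
(2,5-dimethoxy-4-iodoamphetamine, `doi`) — together with a seeded
synthetic spike-train generator that emulates the paradigm, so that every
stage of the pipeline can be validated end-to-end without access to
recorded data.

## Data model

A session is an `OddballSession`: a named list of sorted spike-time
vectors (one per isolated unit), a trial table (onset, stimulus, role,
period, block, locomotion state), a stimulus dictionary, and an optional
motion-energy trace. `alignAndCount()` converts a session into a
`SummarizedExperiment` with one row per neuron and one column per trial,
holding spike counts and firing rates for two windows per trial:

* **baseline**: −200 ms to 0 ms before sound onset;
* **evoked**: 15 ms after onset to 15 ms after offset. The 15-ms shift,
  applied to both edges, compensates the ear-to-cortex transmission
  delay, so the evoked window length equals the stimulus duration. The
  baseline window is not shifted.

Windows are half-open `[start, end)`, so a spike on a boundary is counted
exactly once, and counting is translation-invariant.

## Neuron inclusion

Following standard practice for within-session pharmacology, neurons
enter the main analyses only if they are demonstrably stable and
responsive:

1. **Stability** (`stabilityFilter`): mean spontaneous and mean evoked
   firing may each change by at most 30% between the pre-injection and
   saline periods (`|saline − pre| / pre`; exactly 30% passes, the
   criterion excludes changes *greater than* 30%). This screens out
   drifts caused by time in the rig rather than the drug.
2. **Responsiveness** (`responsivenessTest`): for each stimulus, a paired
   Wilcoxon signed-rank test of evoked versus baseline rates across
   trials, Bonferroni-corrected by the number of stimuli tested; a neuron
   is responsive if any corrected p < 0.05. Stimuli with all-zero paired
   differences are undefined under the signed-rank test and treated as
   p = 1.
3. **Evoked floor** (`evokedFloor`): the best tone must drive the neuron
   above 5 spk/s in every period (exactly 5 fails).

For OEI analyses a fourth screen applies (`oeiStabilityFilter`): the OEI
must vary by *less than* 30% between pre-injection and saline. The
adaptation control deliberately omits this screen.

The stability screen pools rates across stimuli before computing the
relative change; a per-stimulus variant would be stricter, and the
pooled reading was chosen because the screen targets overall drift of a
cell's firing, not stimulus-specific changes. The Bonferroni family is
the set of stimuli in the analyzed ensemble (16 tones for the
tuning-based inclusion; the oddball sounds for per-stimulus
responsiveness).

## Locomotion state

The motion-energy trace (average pixel-intensity change around the paws,
30 Hz) is smoothed with a 10-frame square window, sampled at the frame
nearest each stimulus onset, and thresholded (`classifyLocomotion`).
No numeric threshold is prescribed by the protocol, so the default is an
Otsu threshold: the value maximizing between-class variance of the
smoothed trace histogram, i.e. the split between its quiet and running
modes. The threshold is configurable.

## Frequency tuning

`fitTuning` fits `r(x) = b + A·exp(−(x − µ)² / 2σ²)` to the mean evoked
rate at each of the 16 log-spaced tone frequencies, with `x = log2(f)` so
that σ is in octaves. Derived metrics: best frequency `BF = 2^µ`, tuning
width `2.355σ` (the full width at half maximum of a Gaussian), and
maximum evoked firing (Gaussian peak minus baseline rate). Numerical
choices:

* bounded least squares (`optim`, L-BFGS-B) with µ confined to the
  presented frequency span and σ ∈ [0.05, 5] octaves, preventing
  degenerate spikes and plateaus;
* multi-start over a grid of all 16 frequencies × σ ∈ {0.25, 0.5, 1, 2}
  octaves, best converged SSE wins, ties broken by the first grid point
  (the optimizer is deterministic, so fits are reproducible);
* octaves (log base 2) are used throughout; any base is equivalent up to
  a rescaling of σ;
* R² is computed against the per-frequency mean rates, and defined as 0
  when those means are constant. Fits enter downstream comparisons only
  if they converged with positive amplitude and R² > 0.05.

The fit is applied to rates with a free offset `b`, which subsumes both
raw and baseline-subtracted readings of the procedure. Note that the
means-based R² gate is *permissive* under trial noise: with Poisson
variability at 20 repetitions a flat cell's 16 noisy means can be fit
above R² = 0.05 most of the time. The gate excludes structurally
degenerate (constant or non-converged) profiles; it is not a test of
tuning significance.

## Deviance detection and drug modulation

For each neuron, sound, and period, `oddballResponses` averages evoked
rates over the sound's oddball presentations (O) and its standard
presentations in the role-swapped companion block (S):

* **Oddball enhancement index**: `OEI = (O − S) / (O + S)`;
* **Modulation index**: `MI = (DOI − Sal) / (DOI + Sal)`, computed
  separately for a sound's oddball and standard responses.

Both indices lie in [−1, 1] for nonnegative responses and are undefined
(excluded pairwise, never imputed) when the denominator is zero. All
standards contribute to S by default; `excludeFirstStandard = TRUE`
drops the standard immediately following each oddball. Responses are raw
evoked rates (not baseline-subtracted), consistent with both roles
showing negative MI under a general rate reduction.

Population inference is nonparametric and paired throughout
(`populationTests`): per stimulus, a two-sided Wilcoxon signed-rank test
across neurons of OEI under saline versus DOI, reported with medians and
n; p-values are undefined below 6 pairs. In the generative model an
oddball gain `g` applied to the evoked component yields
`OEI → (g − 1)/(g + 1)` for neurons with negligible baseline firing in
the evoked window; baseline firing dilutes the index toward 0, which is
why empirical medians sit slightly below the gain prediction.

Two control analyses address confounds:

* **Adaptation control** (`adaptationControl`): compares the response
  change from pre-injection to saline with the change from saline to
  DOI, on all neurons responsive to the stimulus. Pure adaptation
  predicts equal steps; a drug effect predicts a larger saline→DOI step.
* **Matched resampling** (`matchedResampling`): when late-session neurons
  have lower control-period OEI, subsets of the late set are drawn whose
  mean saline OEI matches the early-session mean within 0.01 OEI units,
  100 times, and the fraction of subsets whose median saline OEI exceeds
  the median DOI OEI is reported. Because a random subset's mean
  concentrates near the late-set mean, plain rejection sampling cannot
  reach a 0.01 tolerance across a shifted distribution; each resample
  therefore refines a random subset by stochastic improving swaps
  (member ↔ non-member, accepted only when the subset mean moves toward
  the target), with proposals counted against a 10,000-attempt cap and a
  hard error if matching fails.

The early/late boundary is the first two sessions per animal
(`earlyLateSplit`), and early-versus-late effect sizes are compared with
an unpaired Mann–Whitney U test (`effectComparison`).

## Trial-to-trial variability

`fanoFactor` computes `FF = σ²/µ` across a stimulus's repeated trials,
with the unbiased (n−1) variance (the estimator is configurable in
principle; the unbiased form is the default because trial counts per
stimulus per state can be small). `fanoByNeuron` computes FF per tuning
stimulus on evoked-window spike counts — the classical convention; FF on
rates equals FF on counts divided by the window length, and the count
convention is stated in outputs — then averages across stimuli within a
neuron. For locomotion-split analyses a stimulus contributes only with
at least 4 trials in *each* running state; the unsplit analysis requires
2 trials. `fanoSummary` reports paired medians, the signed-rank p, and
the percentage of neurons with increased FF.

## The synthetic-data generator

`simulateSession` generates sessions with the full paradigm structure:
three periods, each containing a 16-frequency tuning block (20
repetitions, 1–1.4 s silent intervals), a role-swapped chord oddball
pair (12-component chords centered at 8 and 13 kHz, 50 ms sounds, 500 ms
gaps), and a role-swapped FM oddball pair (8–13 kHz up/down sweeps,
100 ms), with at least 50 oddballs per block and uniform 9–11 standards
per oddball.

Each neuron is a count process: the evoked-window count is drawn with
mean `(baseline + tuning(f) × oddballGain(role) × runningGain(state)) ×
window` and variance `dispersion × mean` — Poisson at dispersion 1, and
a gamma-mixed Poisson (negative binomial with `size = µ/(φ−1)`) above,
the simplest process with a controllable Fano factor. The oddball gain
multiplies only the evoked (tuned) component, matching the evoked-window
analysis; spikes are placed uniformly within their windows because no
implemented statistic is sensitive to within-response temporal shape,
and spiking between the counted windows is not modeled.

Default population parameters encode the study conditions the pipeline
is meant to detect: oddball gain 1.5 in pre/saline dropping to 1.1 under
DOI; evoked amplitude and baseline rate scaled by 0.8 under DOI; count
dispersion 1.0 rising to 1.3 under DOI; running probabilities
0.44 / 0.20 / 0.72 across pre / saline / DOI. Per-neuron baseline rates
and tuning amplitudes are lognormal (medians 5 and 20 spk/s), tuning
peaks uniform on log frequency over 4–26 kHz and widths uniform over
0.7–1.8 octaves — values chosen once as realistic for awake auditory
cortex; since per-neuron effect-size distributions are not prescribed,
these qualitatively reproduce the population effect structure and are
fully configurable rather than fitted. All draws flow from a master seed
through per-neuron substreams, so neuron *i* is identical regardless of
population size and sessions are byte-reproducible.

The generator emulates the statistical structure the analysis assumes —
stationary rates within periods, independent trials, uniform spike
placement, motion energy that cleanly separates running from quiet
frames. It does not emulate drug onset dynamics, slow drift within a
period, bursting or refractory structure, or correlated variability
across neurons. Passing tests therefore validate the *analysis* under
its stated assumptions; they do not certify behavior on data violating
them.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at sizes chosen to
make Monte-Carlo error small relative to the tested tolerances: 10,000
trials for dispersion calibration (FF within 0.05 of 1), 200 oddballs
per role across 30–40 neurons for OEI-estimator convergence (within 0.02
of the gain prediction), 100 replicate populations of 100 neurons for
drug-effect detection power, 500 replicate populations of 30 neurons
for the null rejection rate (α ± 2 SE), and 100 matched resamples for
the late-session control.

## Known limitations

* The locomotion threshold assumes a bimodal motion-energy histogram;
  unimodal traces yield an arbitrary split (supply `motionThreshold`).
* The Gaussian tuning model is unimodal by design; multi-peaked cells
  are summarized by whichever lobe wins the least-squares fit.
* The R² > 0.05 usability gate does not control the false-tuning rate
  under trial noise (see above).
* OEI and MI are undefined for silent responses; heavily suppressed
  cells can vanish from those analyses while remaining in the firing-rate
  and Fano comparisons.
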