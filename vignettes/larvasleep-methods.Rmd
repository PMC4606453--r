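---
title: "Methods: sleep scoring, arousal-threshold fitting and stimulus-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep scoring, arousal-threshold fitting and stimulus-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvasleep)
```

`larvasleep` analyzes videotracker recordings of larval zebrafish
behavior. This vignette is the package's account of the models and
procedures it implements, the parameters that matter, the design choices
that were genuinely open, and what the synthetic-data validation does and
does not show.

## Sleep/wake scoring

The behavioral input is an *activity matrix*: seconds-active per larva
per time bin, recorded in quantization mode by a videotracking system
(60-s bins for sleep scoring; acquisition parameters such as detection
threshold, burst and freeze settings belong to the tracker and are
treated as upstream metadata). Time is stored as seconds since the start
of the recording; an `epoch_schedule()` anchors it to clock time on a
14 h:10 h light/dark cycle (lights on 09:00, off 23:00 by default) and
names the epochs ("day 5", "night 5", ...).

A **sleep minute** is a 60-s bin with exactly zero activity — the
standard one-minute-inactivity criterion for larval zebrafish — and a
**sleep bout** is a maximal run of consecutive sleep minutes. We chose
strict zero rather than "below a threshold" because the quantization
threshold already lives in the tracker; the comparison threshold is
nevertheless exposed (`threshold` argument) for sensitivity analyses.

Per larva and epoch, `summarize_epoch()` reports six measures: total
activity (s), waking activity (seconds-active per waking minute), sleep
(min), bout count, mean bout length (min) and sleep latency (min). Three
conventions were open and are fixed as follows:

* **Boundary-spanning bouts** are split at epoch boundaries and the
  clipped portions counted in each epoch. This affects bout counts by at
  most one per boundary and keeps the accounting identity
  `sleep + waking minutes = epoch minutes` exact within every epoch.
* **Latency** is measured from epoch start (the lights transition) to
  the first bout start, for day and night epochs alike; a larva that
  never sleeps is censored at the epoch length and flagged
  (`latency_censored`) rather than dropped, which keeps group means
  defined while letting users reproduce the drop-censored convention.
* **Waking activity** divides by the number of non-sleep minutes; an
  all-sleep epoch reports 0 with an explicit `zero_waking` flag instead
  of NaN.

For heat-shock overexpression experiments,
`heat_shock_sleep_change()` expresses each larva's post-induction night
sleep as a percentage of the *genotype mean* of the pre-induction night
— the denominator is the group mean, not the larva's own baseline, so
individual percentages above and below 100% average to the genotype
effect.

## Arousal-threshold (tap) assay

Taps of 14 intensities (power settings within a driver range of 0.01 to
40.95; the assay uses 1–36.31) are delivered in random order at a 1-min
inter-trial interval, 30 trials per intensity, so each larva contributes
420 observations. A larva *responds* to a tap if it moves within the
post-stimulus window. The post-stimulus window length is not fixed by
convention; we default it to 5 s to mirror the 5-s pre-stimulus window
used for the background estimate, and expose it as a parameter.

Spontaneous movement inflates raw response fractions, so the assay is
background-corrected: the **background probability** *b* is the
fraction of all 420 stimuli preceded by movement in the 5 s before
delivery, computed per larva and averaged over the group, and the
corrected response at power *p* is `c(p) = r(p) − b`. Negative corrected
values are retained — clipping at zero would bias the fitted lower
asymptote. Responses are aggregated per power across trials and larvae
(for a balanced design this equals averaging per-event response
fractions); the per-larva/per-genotype alternative for *b* is noted in
the function documentation.

`fit_dose_response()` fits the variable-slope four-parameter logistic in
log dose by ordinary least squares:

$$c(p) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{\,(\log_{10}\mathrm{ETP}_{50} - \log_{10} p)\, h}}$$

ETP50 — the effective tap power at which the response reaches half its
maximum — is the arousal-threshold summary; *h* is the Hill slope. The
lower asymptote is fixed at 0 by default because responses are
background-corrected; any parameter can be fixed or freed. Numerically,
the sum of squares is minimized from five deterministic starts (half-max
positions spread over the stimulated power range, paired with Hill
slopes from 0.5 to 8), each polished by Nelder–Mead followed by BFGS at
a relative tolerance of 1e-12; the best converged minimum is kept. The
fit is equivariant under rescaling of the power axis and the fitted
curve is monotone for positive slopes; both properties are tested.

Groups are compared with the **extra sum-of-squares F test**
(`compare_fits()`): the null model ties the parameter(s) of interest
across groups (the whole curve, the ETP50 only, or the top only —
parameter-specific nesting), the alternative fits the groups
separately, and

$$F = \frac{(SS_{\mathrm{shared}} - SS_{\mathrm{sep}})/
(df_{\mathrm{shared}} - df_{\mathrm{sep}})}{SS_{\mathrm{sep}}/df_{\mathrm{sep}}}.$$

Because "maximal response" can mean either the fitted top or the
largest observed corrected fraction, both are available (the fit
coefficient and the response table's maximum).

## Optogenetic light-response analysis

Thirty-minute light exposures are analyzed on 10-s bins, three trials
per night at a 3-h inter-trial interval. Light onset and offset each
evoke a ~30-s startle burst in every genotype, so the minute before and
after onset is excluded and the response window ends at offset
(discarding the offset burst): baseline = 30 min pre-onset minus its
final minute; response = 30 min of illumination minus its first minute.
The exclusion is structural — excluded bins are simply never indexed —
and a test verifies that zeroing them changes nothing.

Each larva's response-window total is divided by the *genotype mean*
baseline total (`normalize_light_activity()`), ratios are averaged
across the night's trials with equal weight, pooled across experiments,
and expressed as a percentage of the reference genotype
(`genotype_percent()`). The percentage is invariant to rescaling all
activities, so it compares response gain, not absolute movement.

Response dynamics are summarized by **A**, the maximum of the
genotype-mean trace over the response window, and **T_A**, the time from
light onset to first attain it. Raw 10-s-bin means are noisy, so the
trace is smoothed with a centered 5-bin (50-s) moving average (odd
widths only; partial windows at the edges); ties are broken by the
earliest bin. The smoothing width is a parameter.

## Calcium ΔF/F₀

For stimulus-locked GCaMP trials (4 Hz imaging, 30 s per cycle, 8
cycles, 60-s baseline before the first stimulation), each trial's
baseline F₀ is the mean of the 10 frames immediately preceding the
stimulation marker and F the mean of the 10 frames from the marker on;
the trial statistic is 100·(F − F₀)/F₀. "Post" frames are taken as the
first 10 imaging frames — the sub-0.1-s gap between the last stimulation
pulse and imaging start is treated as coincident. Negative values are
retained. Aggregation (`aggregate_dff()`) reports mean ± s.e.m. with n
counting trials, per neuron or per condition.

## Group statistics

`one_way_anova()`, `tukey_hsd()` and `proportion()` wrap the standard
base-R machinery (`aov`, `TukeyHSD`, exact binomial test) behind a
uniform interface returning group means ± s.e.m. alongside the test;
the test suite audits them against explicitly written sum-of-squares
formulas. Proportions carry Clopper–Pearson exact intervals. The
Steel–Dwass nonparametric procedure is deliberately not implemented;
users needing it should use a dedicated nonparametric package.

## Synthetic-data generators

Raw recordings from tracking hardware are rarely shareable, so every
assay has a generator that is a pure function of its parameters and
seed, and the package's principal validation is *parameter recovery*:
analysis(simulate(θ)) must estimate θ.

**Sleep/wake** (`simulate_sleep_wake()`) is an alternating-renewal
(semi-Markov) process at 1-min resolution: wake and sleep bouts
alternate with geometric (minute-discretized, minimum 1) lengths whose
means depend on the epoch type; bouts are drawn per epoch segment and
clipped at its end so each epoch carries exactly its own parameters;
waking minutes receive gamma-distributed activity clipped to the bin.
Published bout-length distributions are not available, so the defaults
are order-of-magnitude choices for a wild-type larva — day: 25-min wake
/ 1.2-min sleep bouts (≈ 4.6% sleep), night: 4-min wake / 4-min sleep
bouts (50% sleep, 7.5 bouts/h) — chosen once as realistic for the
field, not fitted to any dataset. This process reproduces the six
summary measures; it does not emulate circadian drift, homeostatic
rebound or inter-larva heterogeneity, so passing recovery tests
validates the *scoring arithmetic*, not any biological model.

**Tap assay** (`simulate_tap_experiment()`) draws, for each tap and
larva, a stimulus response with probability given by the logistic curve
and, independently, background movement with probability *b* in any
5-s window; observed movement is their OR, so the corrected response is
approximately r(p)·(1 − b) — a scaled logistic with the *same* ETP50,
which is why recovery of the planted ETP50 is unbiased while the
recovered top is shrunk by (1 − b) ≈ 5%. Movement is placed as a 1-s
active bin at a random position inside the pre- or post-stimulus
window; between windows the trace is quiescent, as the assay runs at
night. Defaults follow the standard design: ETP50 3.1, slope 2, top
0.34, b 0.05, 14 log-spaced powers in 1–36.31, 30 trials per power, 90
larvae.

**Optogenetics** (`simulate_opto_night()`): gamma noise (CV 0.4)
around a baseline of 0.6 s-active per 10-s bin; during illumination the
expectation follows the smooth peaked profile
$\mu(t) = \mathrm{base} + (A^* - \mathrm{base})\,(t/T_A)^k e^{k(1-t/T_A)}$
with $A^* = 3$, $T_A = 12$ min, $k = 2$, plus 30-s onset/offset bursts.
A flat plateau would make T_A unidentifiable (with any noise, the argmax
is uniform over the plateau), and the reported faster-to-maximum
phenotype presupposes a discernible peak, so the generator uses this
mild-adaptation shape — a rise to a single maximum followed by slow
relaxation — as its model of the described dynamics. A genotype's
`response_scale` multiplies the whole lit-window expectation, so a scale
of 1.46 plants exactly a 46% increase in baseline-normalized activity
and a maximum of 1.46·A*. The defaults keep the gamma clipping at the
physical 10-s bound negligible (<0.2% at the peak).

**Calcium** (`simulate_calcium()`): baseline at 100 a.u. with 2%
Gaussian frame noise; stimulated trials add an exponential transient
(τ = 4 s, the slow-indicator regime) whose amplitude is calibrated so
that the *expected 10-frame post-window mean* equals the requested
ΔF/F₀ — the planted "30%" is defined on the same statistic the analysis
measures.

## Problem sizes used in the validation suite

The acceptance checks run at the study's design sizes where those are
stated, and at sizes chosen by the package elsewhere: ETP50 recovery
uses 100 replicates of the full 14 × 30 × 90-larva assay (median
relative error, observed ≈ 2–3%); the F-test null calibration uses 500
replicate pairs at 48 larvae per group (the criterion fixes replicates
but not group size); sleep recovery uses 96 larvae × 10 h; opto
recovery 50 replicate nights of 48 + 48 larvae; ΔF/F recovery one
neuron × 8 trials. The bout-detection oracle check covers 1000 random
traces against an independent brute-force scanner.

## Known limitations

* The sleep generator's bout-length defaults are stipulated, not
  estimated; recovery tolerances (5%) are statements about estimator
  accuracy at the stated n, not about biological effect sizes.
* The extra-SS F test assumes homoscedastic Gaussian residuals;
  per-power binomial variances are heteroscedastic, and the null
  calibration (observed rejection ≈ 0.05–0.06 at α = 0.05) shows the
  approximation is adequate at the assay's trial counts, not in
  general.
* Latency-from-epoch-start for day epochs, per-group background
  subtraction, and the 5-s response window are conventions; all are
  parameterized.
* `run_pipeline()` covers the delimited-text formats described here; it
  does not parse proprietary tracker exports, and missing bins are an
  error rather than imputed, because the tracker emits dense bins.
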