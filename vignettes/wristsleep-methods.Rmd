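---
title: "Models and design choices in wristsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in wristsleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristsleep)
```

## What the package models

`wristsleep` analyses two wrist-worn signals that move in opposite phase
around sleep. Distal skin temperature rises before and during sleep, as the
body dissipates heat through the extremities, and falls after waking; it
mirrors core body temperature and is therefore a usable window on circadian
phase that does not require invasive measurement. Wrist movement collapses
during sleep, which is why nearly all consumer sleep trackers are
actigraphy-based — and why they fail on sleepers who move while asleep.
The package implements the full analysis chain for validating motion-based
sleep detection against temperature and reference journals, for three
sleeper archetypes: quiet consolidated sleepers, sleepers with periodic
in-sleep limb movements, and severely fragmented sleepers (common among
older adults living with dementia, OAWD).

## Temperature preprocessing

Loggers come off the wrist for showers and baths, and off-wrist readings
fall towards ambient temperature. Cleaning (`clean_temperature()`) treats
every reading strictly below 28 °C as non-wear and replaces it with the
temporally nearest retained reading, breaking equidistant ties towards the
earlier neighbour; a reading of exactly 28 °C is kept. A recording with no
retained reading at all is unrecoverable and reported as an error rather
than imputed. Smoothing is a running median of window 3
(`median_smooth()`), which removes single-sample spikes without smearing
the sleep-onset temperature rise; the one sample at each end is copied
unchanged, a choice that is invisible to all day-level statistics.

Days are segmented 3 PM-to-3 PM (`segment_days()`) so that each analysis
window contains one complete night plus any daytime naps. At the default
5-min sampling interval a complete window holds 288 samples; incomplete
windows are flagged and excluded from the rhythm statistics by default.

All timestamps live on a fixed-offset local clock (no daylight-saving
transitions); DST handling is orthogonal to the methods and deliberately out
of scope.

## Circadian indices

**Sleep/wake contrast.** `sleep_wake_means()` averages the cleaned series
inside and outside reference sleep intervals; the contrast (sleep minus
wake, positive for distal temperature) shrinks with age and dementia and is
the package's headline thermoregulatory summary.

**Interday stability and intraday variability.** The series is first
reduced to a chronological bin-mean sequence $X_1 \dots X_N$ (hourly bins by
default, the van Someren convention; `bin_width` exposes a full-resolution
variant where binning is the identity). With $\bar X_h$ the pooled
time-of-day profile means,

$$IS = \frac{N \sum_h (\bar X_h - \bar X)^2}{p \sum_i (X_i - \bar X)^2},
\qquad
IV = \frac{N \sum_{i=2}^{N} (X_i - X_{i-1})^2}{(N-1) \sum_i (X_i - \bar X)^2},$$

with $p$ the number of bins per day. IS is 1 for a signal that repeats
exactly with 24-h period, and has expectation $(p-1)/(N-1) \to p/N$ for
white noise. IV is about 2 for white noise, exactly 4 for a two-level
alternating sequence, and $4\sin^2(\pi/24) \approx (2\pi/24)^2 \approx
0.0685$ for a 24-h cosine at hourly bins. A constant series makes both
indices 0/0 and is reported as undefined, never as 0 or 1. Both indices are
invariant under affine rescaling of the temperature, which the tests check.

**Cosinor.** `cosinor_fit()` is ordinary least squares of
$y(t) = M + \beta\cos\omega t + \gamma\sin\omega t$, $\omega = 2\pi/24\,
\mathrm{h}^{-1}$, $t$ in hours since local midnight on complete days.
MESOR $= M$, amplitude $= \sqrt{\beta^2+\gamma^2}$, acrophase
$= \mathrm{atan2}(\gamma,\beta)/\omega$, reported in minutes after local
midnight in $[0, 1440)$. Early-morning distal-temperature peaks make the
midnight reference the natural one for this signal; a numerically zero
amplitude leaves the acrophase undefined. The fit is equivariant — shifting
all timestamps by $\Delta$ shifts the acrophase by $\Delta \bmod 1440$, and
adding a constant shifts only the MESOR — which the tests exploit.

## Sleep detection from actigraphy

`epoch_activity()` reduces raw tri-axial accelerometry to 30-s epochs
scored by the standard deviation of the vector magnitude
$\sqrt{x^2+y^2+z^2}$; gravity cancels out of an SD, so orientation does not
matter. Epochs under 0.02 g are static. Manual scorers identify sleep as
"least varied" stretches of the raw trace; the score, epoch length, and
threshold make that operational and are all exposed in the configuration
because no published numeric criterion exists for the manual procedure.

`identify_sleep_periods()` forms maximal static runs per 3 PM day, merges
runs across non-static gaps shorter than 10 min (the gap still counts as
wake when crediting slept minutes), splits candidates at internal wake gaps
over 2 h — a long mid-night wake is not sleep, and only the longer side can
be the main sleep — and reports the longest candidate of at least 3 h as
main sleep, breaking ties by lower mean activity and then by earlier start
so output is deterministic. Remaining candidates of at least 20 min are
naps. When no candidate reaches 3 h — the fragmented-sleep signature of
static episodes each under 30 min interleaved with movement — no main sleep
is reported and everything is labelled a fragment.

`recreate_journal()` merges identified intervals with a half-hour
caregiver observation sheet. Observed slots always win; only missing slots
are filled from accelerometry. The slot sequence is reduced to one entry
per night (longest sleeping run; additional runs are counted as wake-ups),
and nights whose sleep evidence comes only from fragments are flagged
low-confidence.

`surrogate_device_detect()` is a deliberately motion-biased stand-in for
proprietary wristband detection: open after 120 consecutive static epochs
(60 min), close after 10 non-static ones, report only the longest period
per day or nothing. It is documented as a research surrogate, not a
reverse-engineering; its two thresholds were chosen so that the qualitative
failure modes of motion-only detection appear — every quiet night is
reported, onsets are delayed past periodic-movement windows by roughly the
window length, and fragmented sleepers (no static run close to an hour) get
no sleep at all.

## Agreement statistics

`absolute_differences()` matches device and reference journals on 3
PM-anchored days and reports absolute onset/offset/duration differences in
minutes; days without any device-reported sleep are invalid and excluded
from means. Duration compares main-sleep duration only (naps excluded),
matching how recreated journals summarise nighttime sleep.
`valid_day_summary()` pools counts, not percentages — the pooled percent is
pooled valid over pooled total, rounded half-up. Group contrasts use the
one-tailed Welch test (`one_tailed_t()`): with unequal group sizes the
unequal-variance form is the safer default, and a direction must be
supplied explicitly because each contrast's hypothesis is directional.
No multiple-testing correction is applied, and that caveat is deliberate:
the analysis reports per-contrast p-values as-is. `pearson_corr()` wraps
the standard Pearson test for index-vs-parameter correlations.

## The synthetic-data generator

No wearable recordings ship with the package, so `generate_subject()`
creates them with known ground truth. Its defaults are the study
conditions: three phenotypes whose sleep schedules (onset 00:32 ± 53 min /
offset 07:55 ± 54 min; 23:49 ± 61 / 07:31 ± 78; 21:37 ± 105 / 07:05 ± 40),
temperature contrasts (2.48 / 2.04 / 1.26 °C), cosinor parameters (MESOR
33.34 / 33.65 / 33.90 °C, amplitude 1.72 / 1.45 / 0.93 °C, acrophase 246 /
183 / 44 min) and observation-sheet fill (100% / 100% / 40%) are the group
means of the validation study the package operationalises. Where the two
printed summaries disagree by a rounding step (group mean temperatures vs
the group mean contrast), the contrast wins, because it is the analyzed
statistic: `wake_temp` defaults are set to `sleep_temp` minus the printed
contrast.

**Temperature model.** Additive: a 24-h cosine plus a sleep-state elevation
plus iid Gaussian noise (σ = 0.5 °C). The elevation is the sleep indicator
smoothed by a symmetric exponential kernel with a 30-min time constant, so
temperature begins rising shortly *before* onset and decays after offset,
matching the observed shape. Because sleep always occupies a similar
circadian phase, the cosine and the sleep indicator are correlated, and a
naive sum would not deliver the configured sleep/wake contrast; the
generator therefore calibrates the elevation coefficient and baseline per
realization so that the noise-free sleep and wake means equal `sleep_temp`
and `wake_temp` exactly. Recovery of the contrast from cleaned data is then
a genuine test of the cleaning and averaging chain, not of a lucky
cancellation. Showers force 10–20 min excursions to 25 °C (sample-aligned,
recorded in the ground truth) so the 28 °C rule is exercised.

**Actigraphy model.** Gravity as a constant 1 g on one axis plus 0.003 g
sensor noise. Wake carries continuous 0.05 g postural jitter — so every
wake epoch scores well above the static threshold — plus intermittent
Poisson movement bursts for realism. Sleep is near-static except for the
phenotype's injected movement: `periodic_30s` adds a ~2-s burst every 30 s
during a 2.5-h window after each onset (the movement-window length and
burst amplitude are configurable; the study describes the pattern but not
its amplitude, so the defaults are plausible rather than attributed);
`fragmented` breaks every sleep interval into static episodes strictly
shorter than 30 min separated by 12–25 min movement bouts, long enough that
no merge rule can fuse the episodes back together — the published
fragmented-sleep trace shows substantial movement between episodes.

The generator is seeded explicitly, leaves the caller's RNG state
untouched, and identical calls are byte-identical.

**What it does not emulate.** Postural transitions, apnea-specific
movement signatures, tremor spectra, heart rate, sensor drift, non-wear
other than showers, and DST. Passing recovery tests on this generator shows
the analysis chain is correct and well-calibrated under the modelled
conditions; it does not validate the detector against real polysomnography.

## Numerical choices and degenerate inputs

* Cleaning: strictly-below-28 °C removal; all-below-floor input errors.
* IS/IV on a constant series: undefined (0/0), raised as an error.
* Cosinor on a constant series: amplitude 0, acrophase `NA`.
* Welch test with two constant equal samples: p = 0.5 by convention,
  flagged degenerate; constant unequal samples give p of 0 or 1.
* Tie-breaks in sleep identification: span, then mean activity, then start
  time — output never depends on iteration order.
* Percentages round half-up to integers.

## Problem sizes used in the tests

The test and acceptance suites run entirely on generated data at sizes
chosen to keep Monte-Carlo error well inside the asserted tolerances while
completing in minutes: 200 seeds for the IS/IV white-noise means, 50 seeds
of 14 simulated days for cosinor recovery, 50 quiet nights (and 30 per
group in the acceptance script) for detector recovery at a 1-Hz
accelerometer rate, and 20 seeds of 7 days per phenotype at 0.1 Hz for the
temperature-contrast recovery, where the accelerometer stream is incidental.
Epoch statistics are rate-invariant by construction, so the lower simulated
rates leave the detectors' inputs unchanged in distribution.

## Known limitations

The IS/IV resolution question (hourly vs per-sample bins) is exposed rather
than resolved: the default follows the cited hourly convention, and
`bin_width` switches. The acrophase reference (local midnight) is a
convention; other references shift all acrophases by a constant. The
surrogate detector's thresholds reproduce qualitative failure modes, not
any specific commercial firmware. Recreated journals resolve sleep at
half-hour granularity, so sub-slot onset errors are invisible there.
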