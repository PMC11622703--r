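---
title: "Methods: rest-activity, sleep and melanopic exposure analysis for dynamic-lighting studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rest-activity, sleep and melanopic exposure analysis for dynamic-lighting studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circalux)
```

## The problem

People living with dementia commonly show disrupted circadian rhythms:
fragmented rest-activity patterns, poor sleep, late-afternoon agitation
("sundowning"), and reduced well-being. Because light is the dominant
zeitgeber, daylight-simulating ("dynamic") indoor lighting — warm and dim
in the morning and evening, cool and bright at midday — is a candidate
intervention in residential care, where residents spend most of their
time indoors.

`circalux` implements the full analysis pipeline for a
baseline-versus-intervention trial of such lighting in a care home:

1. radar positional frames at a nominal 8 Hz are reduced to 15-minute
   activity epochs (`bin_translations()`, `normalize_activity()`),
2. nightly rest periods and sleep disturbances are detected by
   run-length rules (`detect_rest_period()`, `count_disturbances()`),
3. nonparametric circadian statistics are computed
   (`interdaily_stability()`, `intradaily_variability()`,
   `relative_amplitude()`), together with pre-sunset activity
   (`sundowning_activity()`),
4. the lighting program is characterised photopically and melanopically
   (`lighting_schedule()`, `melanopic_edi()`, `circadian_stimulus()`)
   and per-resident exposure to the dynamic lighting is accounted for
   (`exposure_summary()`),
5. weekly QUALIDEM well-being panels are scored into subscales A–H
   (`score_qualidem()`; I and J are reported but not analyzed), and
6. every parameter is contrasted across study phases with a
   normality-gated paired protocol (`paired_compare()`), plus an a
   priori sample-size calculation (`required_sample_size()`).

The study design is three phases over 16 weeks: a static-lighting
baseline (weeks 1–4) and two dynamic-lighting analysis windows
(weeks 5–10 and 10–16). Week ranges are half-open internally
(`[5,10)`, `[10,17)`) so week 10 — which colloquially belongs to both
dynamic windows — is counted exactly once, in the final phase. Each
resident is their own control (repeated measures).

Because raw care-home sensor data cannot be released, the package ships
a seeded synthetic-cohort generator with known ground truth, so every
stage is testable end to end, and the whole pipeline can be exercised
with `run_study()`.

## The synthetic cohort

### Activity model

Each resident's deterministic diurnal profile is a clipped cosinor

$$a(t) = \min\{100, \max\{0,\; M + A\cos(2\pi (t - \phi)/24)\}\}$$

with mesor $M$ (activity %), amplitude $A$ and acrophase $\phi$ (clock
hours). Inside the bed window the profile is attenuated to a low
`rest_level` — sleep suppresses movement below what the raw cosinor
would give — and night disturbances are inserted as bouts of elevated
activity (`disturb_level`, default 60%) whose nightly count is Poisson
and whose length in epochs is Poisson around the configured bout mean.
Gaussian epoch noise is added (attenuated by `night_noise_factor`
inside the bed window) and the result is clipped to $[0, 100]$.

Defaults (per resident, mildly varied across the default cohort of 11):
mesor ≈ 30%, amplitude ≈ 25%, acrophase ≈ 14:00 (afternoon activity
peak), epoch noise SD ≈ 10%, 1.5–2.5 disturbances per night of ~30
minutes, bed window 22:30–07:00, rest level 2%, night noise factor
0.25, daytime room-occupancy fraction ≈ 0.6. These are the package's
own choice of a plausible moderate-to-severe dementia cohort in
residential care: a present but damped rhythm (recovered IS ≈ 0.8,
RA ≈ 0.7), roughly two night-time disturbances, and a 07:00 care-home
wake routine. They are configuration, not estimates of any real cohort.

Bout placement is greedy and non-adjacent, at least 4 epochs clear of
the bed-window edges, and the *placed* bouts are recorded as truth: a
bout at the very edge of the window would be invisible to any rest-gated
detector by construction, and truth must be sufficient to recompute the
expected metric values.

### Frames versus epochs

Cohort-scale simulation happens directly at the 15-minute-epoch level —
the analytic aggregate of the frame model. Raw 8 Hz frame streams
(11 residents × 112 days would be ~10⁸ rows) add nothing to the
statistical questions, so frame emission (`simulate_resident()`) is
intended for day-scale ranges, where it exercises the full ingest path.
The simulated path is circular pacing around the room centre with the
per-frame arc step set by the epoch's activity: summed translation per
epoch is then an exact deterministic, nearly linear function of the
generating curve (chord-versus-arc distortion ~10⁻⁵ relative at 8 Hz).
A reflected random walk was rejected because wall reflections distort
inter-frame distances and break the exact periodicity that the
noiseless closure tests rely on. Position geometry is plumbing;
translation magnitude is what the analysis consumes.

Presence alternates between the sensored flat and the (unsensored)
common areas by a two-state chain with a one-hour mean in-room dwell,
pinned to "present" inside the bed window, with stationary daytime
presence equal to `room_occupancy_fraction`. A daily light-switch log
is generated (lights on across waking hours on a per-day Bernoulli
basis), which drives the exposure accounting.

### Injectable intervention effects

`intervention_effect(parameter, phase, delta)` shifts a *metric's*
ground truth, not a raw generator knob. The mapping inverts the
analytic metric maps:

* **RA**: the expected observed RA — computed from the expected hourly
  profile including the disturbance mixture and clipped-noise means —
  is shifted by `delta` and the amplitude solved by `uniroot()`.
* **IS**: expected IS is `Var_h / (Var_h + c·σ² + v_dist)`; the noise
  SD is solved in closed form. When the disturbance mixture variance
  alone caps IS below the target, noise is zeroed and the nightly
  disturbance rate damped to reach it (a rhythm-stabilising
  intervention acts on both).
* **IV**: solved through the noise SD with the mean-squared successive
  difference formula (an error if IS and IV are both targeted in one
  phase: they act through the same parameter).
* **sleep_disturbances**: shifts the Poisson mean directly.
* **qualidem_A…J**: shifts the subscale's weekly latent mean in units
  of its weekly latent SD.

The expected-observed calibration matters: recovered RA on the default
cohort is ≈ 0.68 against an expected 0.667, and an injected RA + 0.1
is recovered as ≈ +0.10 (the naive noiseless-profile map would predict
RA ≈ 0.92 and leave no headroom for the shift). The hourly-mean
disturbance variance carries a clustered-sampling inflation equal to
the mean bout length in epochs, since bout epochs arrive in runs.

### QUALIDEM panel

Each resident has a latent mean per subscale on the 0–3 rating scale;
weekly subscale latents are drawn around it (SD `latent_week_sd`,
default 0.25), item responses around the weekly latent (SD `item_sd`,
default 0.5), rounded and truncated to the legal range.
Negative-worded items are emitted pre-reversal so that scoring recovers
the latent direction. With all SDs zero the panel repeats exactly, and
an effect on one subscale leaves every other subscale untouched.

## Analysis choices

### Activity normalization

The sensing convention normalizes each epoch's summed translation "by
the maximum total translation in the current window" to give a
percentage. Read literally per-epoch, every epoch would be 100%; the
package therefore normalizes each epoch total by the *running maximum*
epoch total for that resident (`normalize_activity(mode =
"running_max")`), which stabilizes once the first activity peak has
been seen; a whole-series `"global_max"` variant is the config
alternative. Consequence: the first day is a warm-up in which the
running maximum still grows, so noiseless-closure checks on the frame
route discard day 1. Epochs with no frames are explicitly missing,
never zero-filled. Displacement spanning an epoch boundary is credited
to the later epoch (half-open epochs).

### Circadian statistics

IS, IV and RA use the standard actigraphy definitions on hourly bins
(within-hour means of the 15-minute series; hours under 50% epoch
coverage dropped with counts adjusted):

* $IS = \sum_h n_h(\bar x_h - \bar x)^2 / \sum_i (x_i - \bar x)^2$ —
  the count-weighted form, which reduces to the classic
  $N\sum_h(\bar x_h-\bar x)^2 / (p\sum_i(x_i-\bar x)^2)$ when hours are
  balanced and stays within $[0,1]$ when they are not.
* $IV = N\sum(x_i - x_{i-1})^2 / (m\sum(x_i-\bar x)^2)$ with $m$ the
  number of contiguous hourly pairs (differences are never taken across
  gaps). IV is often described as ranging 0–2 in practice; the formula
  itself is bounded by 4, attained by a strictly alternating series,
  and the package implements the formula as defined.
* M10/L5 are means of the 10 most / 5 least active *consecutive* hours
  of the phase-average 24 h profile, windows wrapping midnight;
  $RA = (M10 - L5)/(M10 + L5)$. The per-day variant is deliberately not
  the default (the average-profile convention is the common one).

Zero-variance series are flagged (`NA` with a `flag` attribute), not
scored. Both IS and IV are validated against independent brute-force
evaluations of the formulas to 10⁻¹².

One subtlety the noiseless tests surfaced: IV contains a finite-length
$O(1/N)$ term (the midnight-boundary pair occurs $D-1$ times against
$D$ for within-day pairs over $D$ days), so phases of unequal length
differ by ~4·10⁻⁴ even for a perfectly periodic series. With every
stochastic source silenced a paired t test flags that artifact;
with any realistic noise it is invisible. The null-cohort test
therefore asserts the artifact's magnitude stays below 10⁻³ rather
than pretending the contrast is stochastic.

### Sundowning

Mean activity in the 4 hours before sunset, with the phase→sunset
mapping fixed at 20:00 / 21:00 / 22:00 (baseline, weeks 5–10,
weeks 10–16) as configuration rather than ephemeris computation. Note
the windows differ across phases *by design*, so a sundowning contrast
is not a null comparison even on an unchanged cohort.

### Sleep

Defaults: night window 22:00–08:00 (configurable; widening to 10:00
accommodates the latest plausible wake times), rest threshold θ = 10
(activity %), rest-run minimum R = 4 epochs (1 h), minimum bout 1
epoch. Rest onset is the start of the first sub-θ run of length ≥ R in
the window, offset the end of the last; disturbances are maximal
above-θ runs inside the rest period; total sleep is the rest span minus
summed bout minutes, exactly. Nights with no qualifying run are
unscored and excluded from medians. Summaries take per-resident medians
over nights, then the group median (median-of-medians, to limit skew
from heterogeneous sleepers), with a leave-one-out option for
sensitivity reruns (e.g. excluding a resident on sleep medication).
Care-staff two-hourly night checks can create spurious bouts in real
data; no correction is applied — this is a documented confound.

### Lighting and melanopic quantities

The dynamic program (packaged YAML) steps through 300 lx/3350 K in the
early morning up to 550 lx/6500 K at midday and down to 300 lx/2700 K
in the evening; lookups hold the first/last entry outside the
programmed span. The luminaire's spectral power distribution is not
available, so melanopic conversions are *anchored scalars*: the
melanopic ratio defaults to 331/260 M-EDI lx per lx, and circadian
light per lux is obtained by inverting the CS saturation model

$$CS = 0.7\left(1 - \frac{1}{1 + (CL_A/355.7)^{1.1026}}\right)$$

at the 260-lux level's CS of 0.404 (`cl_a_per_lux()`, with
`invert_cs()` the closed-form inverse). With that single anchor the
300-lux level reproduces CS 0.431 at 3-decimal rounding; the 550-lux
level comes out 0.530 against a published-style 0.532 — a ~0.002
residual that is expected, because the programmed colour temperature
(hence spectrum, hence the true CL_A/lux) differs between levels. The
residual is asserted, not hidden. M-EDI is reported to integer lux and
CS to 3 decimals, matching the precision such program tables print.

Exposure accounting assumes time not spent in the resident's own
(sensored) room is spent under fully dynamic common-area lighting:
dynamic exposure = (present ∧ lights on) + absent, and is 0 by
definition in the static baseline.

### Statistics

Per parameter and contrast (each dynamic phase against baseline, paired
within resident): Shapiro–Wilk on the paired differences at α = 0.05
gates a two-tailed paired t test (effect size Cohen's d on the
differences, the matched-pairs d_z convention; the averaged-SD variant
is available) or a Wilcoxon signed-rank test (exact for n ≤ 25 without
ties, normal approximation with continuity correction otherwise, zero
differences dropped) with Cliff's delta. The branch can be forced per
parameter to reproduce analyses that report specific subscales
nonparametrically. Zero-variance differences are flagged, never
tested. Raw P values are reported across endpoints without
multiple-testing correction, matching the reporting convention of
small pilot trials; a correction is a one-liner on the output table if
wanted. Effect-size labels follow Cohen's bands for d
(0.2/0.5/0.8) and the corresponding Cliff's delta bands
(0.147/0.33/0.474), with |δ| below the medium band labelled "high
overlap". QUALIDEM phase values are the mean of a resident's weekly
scores in the phase (how weekly panels collapse to one paired value per
phase is a convention; mean is the default, median available); sleep
metrics aggregate by median.

`required_sample_size()` scans for the smallest n whose two-tailed
paired t power (noncentral t, ncp $\sqrt n\,d$) reaches the target:
at d = 0.5, α = 0.05, power 0.80 it returns 34, cross-checked in the
tests against an independent exhaustive scan and `power.t.test()`.

## What the tests do and do not show

The suite validates closures (noiseless periodic cohort → IS exactly 1;
placed bouts recovered exactly; total sleep + bouts = rest span),
brute-force equivalence (IS/IV to 10⁻¹², Cliff's delta against O(n²)
enumeration, run detection against a plain scan), protocol size
(rejection rate of the gate-plus-test chain on 2,000 null cohorts of
n = 11 within [0.03, 0.07]), and injected-effect recovery (RA + 0.1
recovered within the generator's own 200-replicate Monte-Carlo
interval; a +0.5 SD QUALIDEM latent shift detected at n = 11 with power
matching an independent Monte-Carlo oracle of the same generator).
Monte-Carlo problem sizes are chosen for a laptop-scale run: 14-day
phase windows and 200 replicates for RA recovery, 250 replicates per
route for QUALIDEM power, 2,000 draws for type-I.

Passing these tests shows the machinery is correct and calibrated *for
the generator's world*: additive Gaussian noise on a cosinor, Poisson
bouts, a single resident per flat, fully observed epochs. Real radar
data adds multi-person confusion, sensor dropouts, visitors, naps
outside the night window, care-staff checks, and seasonally moving
sunsets — none of which the generator emulates, and all of which are
reasons the package keeps every threshold in configuration.

## Known limitations

* Melanopic quantities are anchored scalar conversions, not spectral
  integrations over CIE S 026 action spectra; per-level spectra would
  be needed for exact CS/M-EDI at every schedule step.
* The sundowning analysis uses fixed representative sunset times per
  phase, not an ephemeris.
* "Sleep disturbance" means a movement bout; bed-exit events are not
  distinguished.
* No mixed-effects or longitudinal modelling: the design is strictly
  paired phase contrasts, so time-varying confounders (season, daylight
  length) are only controlled by the within-resident pairing.
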