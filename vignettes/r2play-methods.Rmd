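---
title: "Methods: protocol generation, multi-domain cost scoring, and session simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protocol generation, multi-domain cost scoring, and session simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(r2play)
```

## The assessment in brief

Return-to-play clearance after paediatric concussion is usually decided from
symptoms and a clinic exam that look nothing like sport. The assessment this
package implements embeds classic neuropsychological paradigms (trail making,
go/no-go, Stroop) in a physically exerting task: six touch tablets are placed
around a start position and the athlete runs between them, tapping characters
in alternating alphanumeric order (1-A-2-B-3-C). Four core levels layer
demand onto this baseline -- an exercise level interrupting the trail with an
exercise bout at a beep, a go/no-go level (tap green, skip red), and a Stroop
level with the rule reversed -- each run four times: first a standard
repetition, then a standard, an auditory-interference, and a mid-trail
scramble repetition in randomized order. A short two-repetition motor task
brackets the assessment so a pre/post fatigue contrast exists.

## Distance standardization

Completion times are only comparable if every repetition demands the same
amount of running. Trails are therefore generated so the summed Euclidean
path over *correct* selections -- start position to first target, then target
to target -- hits a standardized total: 45 m (&plusmn;1%) for 12-selection
repetitions and 30 m (&plusmn;1%) for the 8-selection go/no-go and Stroop
repetitions, about 3.75 m per correct selection in all cases.

The generator draws a uniformly random bijection between the six trail
characters and the six tablets and rejects draws until the path distance
falls inside the tolerance window, bounded at 10,000 proposals (an infeasible
target reports the best distance achieved). The default layout -- tablets
evenly spaced on a 3.5 m arc spanning 148&deg;, start at the arc centre --
was calibrated once so that a few percent of random bijections land in each
window, which makes rejection sampling cheap and leaves genuine variety in
the accepted assignments. Layouts are fully configurable; it is the distance
window, not the geometry, that carries the standardization.

Three choices here are ours, because no published value exists:

* **Distractor count.** Go/no-go and Stroop repetitions display 12 items of
  which 4 are lures, leaving 8 correct selections -- the count implied by
  30 m at 3.75 m per selection.
* **Motor-task length.** The motor task is described only as a short trail;
  we use one 6-character cycle standardized to 22.5 m, preserving the 3.75 m
  per selection invariant. Its absolute pace cancels out of the fatigue cost,
  which is a within-task pre/post contrast.
* **Scramble trigger.** The relocation fires "partway through the trail"; we
  default to after the 6th correct selection (12-item repetitions) or the 4th
  (8-item repetitions), configurable. The post-trigger items are re-assigned
  by a fresh bijection, redrawn until at least one item actually moves, no
  character lands on the tablet the athlete currently occupies (a zero-length
  run segment), and the total distance still satisfies the window.

## Scoring model

Each repetition yields three metrics: **seconds per tablet** (span minus
exercise-pause time, divided by correct selections), **errors** (incorrect
selections), and **average heart rate** (time-weighted trapezoidal mean over
the repetition span). Where a condition is duplicated, the *best* of the two
repetitions -- fastest, fewest errors, lowest HR, each metric independently --
serves as the baseline.

A cost score is a percent change,

$$\mathrm{cost} = \frac{\text{challenge} - \text{baseline}}{\text{baseline}} \times 100\%,$$

computed per metric for six contrasts: exertion (number-letter vs exercise,
standard bests), cognitive moderate (vs go/no-go), cognitive high (vs
Stroop), fatigue (pre vs post motor task), and the auditory and scramble
costs, which compare the mean across the four core levels of the per-level
standard best against the mean of the per-level auditory (resp. scramble)
repetition. Undefined values are first-class: a zero baseline (typical for
errors in healthy cohorts) yields `zero_baseline`, absent heart-rate coverage
`missing_hr`, and a missing level `missing_level` -- never an imputed number.

Two conventions are deliberate. The baseline for the auditory/scramble costs
uses the best-of-two standard rule (the footnote convention) rather than the
mean of both standard repetitions, because the best-of rule is stated as the
comparison convention wherever a duplicate exists. And HR costs average over
the repetition span only, not the 10 s recovery tail; the tail belongs to the
exertion summary, where it captures the effort just completed.

Reported costs are rounded to 2 decimals half-up; internal arithmetic is full
precision. Cohort summaries report n, mean, sample SD (n&minus;1), a normal
95% CI (mean &plusmn; 1.96&middot;SD/&radic;n), median (midpoint of the
middle two), and IQR with linear-interpolation quartiles by default (Tukey
hinges are available via `quartile = "tukey"`; published IQRs for small
cohorts are sensitive to this choice, which is why only medians are treated
as reproducible anchors).

## Clinical measures

Exertion is summarized over *active windows* -- each repetition plus 10 s --
merged when they overlap: time-weighted average HR, peak HR, and both as
percentages of the Tanaka age-predicted maximum (208 &minus; 0.7&middot;age),
plus the highest post-level OMNI RPE (0--10). Sessions whose HR stream misses
every active window (a real failure mode: lost synchronization between the
chest strap and event markers) get undefined HR fields.

The System Usability Scale follows Brooke's instrument: odd (positively
worded) items contribute response&nbsp;&minus;&nbsp;1, even items
5&nbsp;&minus;&nbsp;response, total = 2.5 &times; sum, bands at 68 and 80.
The odd/even polarity is the cited instrument's convention; the deployed
questionnaire states only the 0--4 contribution rule.

Symptom check-ins use four ordered responses; response 4 ("so much worse I
had to stop") triggers the stop flag at the first occurrence, response 3
raises a non-stopping worsened flag.

## What the simulator emulates

`simulate_session()` walks a protocol and emits a complete event log:

* **Tap timing.** Per-tap intervals are lognormal -- positive and
  right-skewed, the standard shape for response times -- parameterized by a
  coefficient of variation `noise_cv` (default 0.05). Interval means are
  proportional to the segment distance and scaled so a repetition's expected
  seconds-per-tablet is exactly `base_spt` times the product of applicable
  time factors; at `noise_cv = 0` the equality is exact, which the tests
  exploit.
* **Demand loading.** `effect_config()` holds multiplicative time factors
  per challenge. A factor *f* on one challenge makes the matching time cost
  recover 100(*f*&nbsp;&minus;&nbsp;1) in expectation, so injected factors are
  their own oracle. The defaults (exercise 0.93, go/no-go 0.97, Stroop 1.20,
  auditory 1.09, scramble 1.21, fatigue 0.88) encode the demand ordering
  observed in the instrument's ten-youth proof-of-concept cohort, so a
  default cohort reproduces its qualitative result: largest costs in the
  cognitive (high) and scramble contrasts, auditory intermediate, and
  negative exertion/fatigue time costs.
* **Heart rate.** First-order exponential relaxation toward
  piecewise-constant targets (time constant `tau_s`, default 30 s): level-
  and condition-dependent steady states during repetitions (exercise highest,
  with an extra spike during the exercise pause), resting HR during breaks,
  sampled at 1 Hz with small Gaussian noise and clamped to
  [rest, predicted max]. This is the standard exercise-physiology
  approximation for on/off HR kinetics.
* **Errors.** Each correct selection is preceded by an error tap with a
  small probability (base rate 0.02/tap), with per-challenge odds
  multipliers. At these rates error-based cost scores are usually undefined
  (zero error baseline), mirroring the near-error-free behaviour of healthy
  athletes.
* **Timing envelope.** Configuration 360 s, per-level orientation 75 s,
  40 s between repetitions, 45 s check-ins, 15 s exercise pauses -- chosen
  once so simulated sessions land near the observed duration structure
  (roughly 6 min configuration, high-20s active minutes).
* **Check-ins.** RPE = clamp(round(`rpe_slope` &times; %max/10), 0, 10) with
  a default slope of 0.55, placing peaks in the 2--7 range reported for
  healthy youth; symptom responses are drawn from {1, 2}.

Cohorts draw integer ages uniformly on 10--22, baseline pace on 1.3--2.0
s/tablet, resting HR on 60--80 bpm, and per-participant protocols and
sessions from seed-derived sub-streams, so everything is reproducible from
one integer.

What the simulator does **not** model: concussed performance profiles (no
in-scope data exists to calibrate them), wheelchair biomechanics (the flag is
metadata only), learning effects across repeat administrations, and
speed--accuracy trade-offs. Passing recovery tests therefore demonstrates
that the scoring pipeline measures what it claims on data with known
structure -- not that real athletes behave like the generator.

## Numerical choices and degenerate inputs

* Rounding of reported scores is half-up with an epsilon guard; R's default
  banker's rounding would print 22.625 as 22.62.
* `best_of()` skips undefined repetitions and is undefined only when every
  repetition is.
* Zero correct taps make seconds-per-tablet undefined rather than infinite.
* Trapezoidal HR averaging interpolates the stream at window edges; duplicate
  timestamps contribute zero-width segments and are harmless.
* Trail generation and the scramble redraw are bounded searches (10,000
  proposals) that fail loudly with the best achieved distance rather than
  silently relaxing the window.
* All randomized operations take explicit seeds; derived sub-seeds stay below
  2^31.

## Problem sizes used in the checks

The test suite and the acceptance script regenerate everything from code:
1,000 trails for the distance-window property, cohorts of 200 simulated
sessions (noise CV 0.05) for parameter recovery of injected factors 1.05 and
1.20 and for the null check, a 60-session default cohort for the qualitative
ordering, and 1,000 random perturbations for SUS monotonicity. The pinned
cohort statistics (mean average HR 139.0 bpm over 8 sessions with usable HR,
peak 163.5 &plusmn; 19.0 bpm, CI 151.7--175.3, mean peak 83.1% of predicted
max, mean peak RPE 4, median configuration time 6.01 min) are recomputed
from the per-participant values shipped in `inst/extdata/`.

Two published summary values are deliberately not pinned: the active and
total duration medians (inconsistent with their table's own rows, unlike the
configuration median) and the peak-RPE SD (which matches a population-SD
convention; this package uses sample SD throughout).
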