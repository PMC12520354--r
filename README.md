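# r2play

An R implementation of a multi-domain return-to-play assessment engine for
paediatric concussion rehabilitation. The assessment is a physical
trail-making task: an athlete runs between six touch tablets, tapping
characters in alternating alphanumeric order (1-A-2-B-3-C), while successive
levels layer exercise bouts, response inhibition (go/no-go), rule reversal
(Stroop), background-noise interference, and mid-trail relocation
("scramble") onto the baseline task. The package provides everything except
the hardware:

* **Protocol generation** — distance-standardized trail sequences (45 m ± 1%
  over 12 selections, 30 m ± 1% over 8) on a configurable tablet layout.
* **Session event logs** — a versioned JSON schema for taps, heart-rate
  streams, exercise pauses and post-level check-ins, with validation and
  byte-stable round-tripping.
* **Multi-domain cost scoring** — the generalization of the dual-task cost
  statistic to six contrasts × three metrics.
* **Clinical measures** — exertion summaries against the Tanaka age-predicted
  HRmax, System Usability Scale scoring, OMNI RPE extraction, and the
  symptom stop rule.
* **A session simulator** — synthetic cohorts with controllable demand
  loading, so the full pipeline is testable and injected effects can be
  recovered.

## The core statistic

Performance on each repetition is standardized as seconds per correct tablet
selection (plus error counts and average heart rate). A cost score is the
percent change between a baseline and a more demanding level or condition,

cost = (challenge − baseline) / baseline × 100%,

with the better of duplicated repetitions (fastest / fewest errors / lowest
HR) as baseline: exertion (number-letter vs exercise), cognitive moderate
(vs go/no-go), cognitive high (vs Stroop), auditory and scramble (per-level
standard bests vs the interference repetitions, averaged across the four
core levels), and fatigue (pre vs post motor task). Zero baselines and
missing heart rate yield explicit `undefined` states with machine-readable
reasons, never imputed values.

## Worked example

```r
library(r2play)

protocol <- build_protocol(protocol_config(seed = 1))
session  <- simulate_session(protocol, participant_profile(base_spt = 1.68),
                             effect_config(noise_cv = 0), seed = 7)
costs <- compute_cost_scores(session)
subset(costs, metric == "time", select = c(cost, value))
#>                  cost value
#> 1            exertion    -7
#> 4  cognitive_moderate    -3
#> 7      cognitive_high    20
#> 10           auditory     9
#> 13           scramble    21
#> 16            fatigue   -12
```

With timing noise switched off, each time cost equals `100 × (f − 1)` for
its injected factor exactly — the defaults are Stroop 1.20, scramble 1.21,
auditory 1.09, exercise 0.93, go/no-go 0.97, fatigue 0.88, so the values
above read directly as the configured demand loading. The companion
summaries:

```r
ex <- exertion_summary(session)
round(c(avg = ex$avg_pct_max, peak = ex$peak_pct_max), 1)
#>  avg peak
#> 55.3 80.4
sus_score(rep(3, 10))$total
#> [1] 50
```

`avg`/`peak` are percentages of the Tanaka age-predicted maximal heart rate
(208 − 0.7 × age) over the active assessment windows (each repetition plus
10 s). A command-line pipeline is installed as `exec/r2play` with
subcommands `protocol | simulate | score | report | validate`.

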