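---
title: "Methods: structured SMBG pattern analysis and the decision flowchart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structured SMBG pattern analysis and the decision flowchart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smbgflow)
```

## The problem and the model

Intermittent fingerstick glucose monitoring (SMBG) produces sparse,
irregular time series. Clinical pattern management does not fit a
statistical model to them; it applies *counting rules* over a structured
representation of the data — readings classified into glycemic classes,
localized in named time blocks of the day, and grouped into analysis
days — and gates the resulting alarms on data sufficiency and glycemic
variability. `smbgflow` implements that pipeline as a deterministic,
configurable rule engine. Every quantity it reports is reproducible from
the input CSV and the configuration alone.

### Glycemic classification

Each reading is assigned exactly one of `very_low < hypo < in_range <
hyper < very_high`. Comparisons are strict: *below* 54 mg/dL is very low,
*above* 250 mg/dL is very high, so a reading exactly on a limit stays in
the lower-severity class. The very-low and very-high limits are the
platform rule constants; the hypoglycemia limit (70 mg/dL) and the
tag-dependent hyperglycemia limits (130 pre-meal / 180 post-meal mg/dL)
are consensus clinical targets, declared here as defaults rather than
derived — the source material names no values for them. Class semantics
are containing: a very-low reading also counts as a hypoglycemic event in
every trend rule, and very-high counts as hyperglycemic.

### Time blocks and analysis days

A `time_block_scheme` partitions the 24-h clock into half-open intervals
(default: night [00:00–06:00), breakfast [06:00–10:30), midday
[10:30–15:00), dinner [15:00–21:00), bedtime [21:00–24:00)); boundary
readings belong to the block that starts there. The analysis day rolls
over at a configurable `day_start` (default midnight — the platform's
behaviour is unstated, and midnight is the least surprising choice; a
03:00 rollover is available because nocturnal readings straddle
midnight). All timestamps are handled on a DST-free clock.

## Step 1 — sufficiency

Two stated densities anchor the gate: 28 tests per 2 weeks (Step-1
quantity minimum) and 72 tests per 4 weeks (pattern-analysis activation,
settable 30–120). For other window lengths both thresholds scale
linearly by days and round up, preserving the stated per-day densities
(2.0/day and ≈2.57/day); whether the platform itself pro-rates the
activation count is unknown, so the pro-rating is logged in the result's
`thresholds_used`. Quality is made concrete as tag coverage — each of
pre/post breakfast, pre/post dinner and bedtime must appear at least 3
times per 2 weeks (pro-rated the same way) — because the requirement is
stated only as "the recommended testing time" with no numbers. A log
with zero readings produces a normal result with all gates false: the
insufficient branch is a clinical outcome with its own actions, not an
error.

## Step 2 — detectors

All detectors run over the readings inside the analysis window and
return `red`/`clear` with the triggering evidence, or `inactive` when
the sufficiency gate failed (or, for heuristics, when disabled or
unannotated). Parameters are clamped into their settable ranges, never
rejected, and a clamp warns.

Numerical and tie-break choices:

- **"Consecutive days"** means calendar-consecutive analysis days each
  meeting the per-day count. A day with *no readings at all* breaks a
  run: absence of evidence is treated conservatively, not interpolated.
- **"Over 7 days"** (time-block recurrence) is a *sliding* span of 7
  consecutive analysis days anywhere in the window, not fixed calendar
  weeks — "during the analysis time period" suggests any-position
  windows.
- **Ties** between qualifying runs or spans: the earliest is reported
  (for spans, earliest start day, then scheme block order);
  `all_evidence = TRUE` reports every occurrence.
- **No consumption semantics:** one reading may serve as evidence for
  several detectors simultaneously (a 48 mg/dL night reading can fire
  the very-low, hypo-trend and time-block rules at once). Whether the
  platform shares evidence this way is unknown; sharing is the choice
  that never hides an alarm.
- The hyperglycemia time-block detector is not specified by the source
  material, which details only the hypoglycemic variant while naming
  both; it is implemented as the exact mirror (same rule, same ranges)
  and labelled as such.
- The overcorrection detectors (hypo-after-hyper and its mirror) and the
  missed-bolus detector are *declared heuristics*: the platform names
  these patterns without publishing rules. The rules here — a
  hypo reading following a hyper reading within 5 h with no in-range
  reading between them; a post-meal hyper whose same-meal pre-meal
  reading carries `bolus_given = FALSE` — are off by default, enabled by
  config, and tagged `"heuristic"` in every report.
- The variability pattern block (SD, LBGI, HBGI on the platform) has no
  published red rule either; `run_all_patterns()` fills that block with
  a `high_variability` finding, red exactly when the gate CV exceeds the
  36 % cutpoint, so all four blocks report a status through one
  interface.
- The adherence finding turns red on the *absence* of tests, so it is
  the one detector exempt from the red-implies-evidence invariant; its
  evidence is the (possibly empty) sparse log itself.

Each rule also exists as an independent brute-force oracle
(`oracle_*()`): an exhaustive enumeration of candidate day-runs, sliding
spans, or reading pairs sharing no code with the production detectors.
The test suite asserts agreement on hundreds of random logs, and the
simulator refuses to emit a fixture whose labels the oracle contradicts.

## Step 3 — variability and actions

SD is the sample standard deviation (n−1); CV = 100·SD/mean. The risk
indices use the published log-symmetrization for mg/dL,
f(BG) = 1.509·((ln BG)^1.084 − 5.381), r = 10·f², with LBGI/HBGI the
one-sided means of r; their sum equals the mean total risk (tested to
1e−9), and both vanish for constant logs at the risk-neutral glucose
exp(5.381^(1/1.084)) ≈ 112.5 mg/dL. CV is reported both overall and on
daily means ("CV of mean daily glucose"); which one feeds the gate is
configurable (`overall` by default — the platform's choice is unstated,
and the overall CV is defined for every active window, whereas daily
means need ≥ 2 days). Boundary classification: exactly 33 → `acceptable`
(the protective claim is strict "< 33 %"), exactly 36 → `acceptable`
("≤ 36 %").

Red findings map to *categorical* flags only — no dosing arithmetic, no
free text beyond fixed rationale strings, since dosing advice is outside
the evidence this engine can carry. The mapping is the minimal reading
of the flowchart's suggestion list: hypo patterns → review correction
rules + consider de-intensification; hyper patterns → consider
intensification; missed bolus → review ISF/carb ratio; any pattern →
reinforce lifestyle; adherence red → investigate adherence. Under high
CV the treatment-change flags are suppressed and
`intensify_smbg_before_change` emitted instead — intensifying or
de-intensifying therapy under high variability raises the risk of the
opposite excursion. Flags sort hypoglycemia-first, mirroring the
structured-testing prioritization (hypoglycemia, then fasting, then
postprandial hyperglycemia).

## The synthetic world

`simulate_smbg()` states one generative world and keeps it fixed:

| parameter | default | why |
|---|---|---|
| regimen | 7-point daily | the structured-testing profile (pre/post × 3 meals + bedtime) |
| `n_days` | 28 | the activation horizon (4 weeks) |
| `base_mean` | 130 mg/dL | typical insulin-treated T2D mean glucose |
| `meal_offset` | +40 mg/dL | declared post-meal excursion |
| `interday_cv_target` | 25 % | realistic interday variability, below the 33/36 % gates |
| `intraday_noise_sd` | 15 mg/dL | meter + within-day physiological noise |
| `missingness` | 5 % | occasional skipped tests |

Values are drawn as a lognormal day multiplier times the time-of-day
mean plus Gaussian noise, truncated to [40, 500] mg/dL. This emulates
the *statistics* a pattern engine consumes — regimen structure, interday
vs intraday spread, missingness — and none of the physiology (no
glucose–insulin dynamics, no autocorrelation within a day, no
meal-size variation). A green detector test on synthetic data therefore
establishes rule correctness, not clinical sensitivity on real logs.

Injections shape readings to hit a detector's default trigger exactly
(`magnitude = 0`) or miss it by one unit (`-1`: one fewer day or event,
or a value exactly on a strict threshold). When injections are present
the background is clamped into 90–125 mg/dL so the injected readings are
the only pattern evidence; an injection may still legitimately fire a
sibling rule (two same-block events on consecutive days satisfy both the
trend and the time-block rule), so labels for non-targeted detectors are
recorded from the oracle, while the targeted detector's label is fixed
by intent and *asserted* against the oracle. `sweep_cv()` rescales the
two noise amplitudes and resamples (bounded retries) until the realized
overall CV lands within ±1 percentage point of a target; targets outside
what the spec's noise sources can express are an error, not a silent
approximation.

All randomness flows from the mandatory seed through a local RNG scope
that never touches the caller's `.Random.seed`.

## Reports

Reports serialize to JSON with stable key order and fixed number
formatting; two runs on identical input and config are byte-identical
(the input digest is an md5 of the canonical CSV serialization — no
timestamps anywhere). The text rendering works from the same payload, so
a report read back from JSON renders identically. Exit code 0 includes
the insufficient-data outcome; nonzero codes are reserved for I/O,
config and usage failures, and output files are written atomically.

## Known limitations

- Internal unit is mg/dL only; mmol/L is converted once at ingest
  (× 18.016).
- No CGM support and no CGM-era metrics (time in range, MAGE, CONGA);
  the CV gate is the only variability threshold acted on.
- The heuristic detectors are plausible operationalizations, not
  validated clinical rules; they stay off unless explicitly enabled.
- Free-text clinical recommendations, messaging, and device connectivity
  are out of scope by design: the engine ends at categorical flags with
  evidence.
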