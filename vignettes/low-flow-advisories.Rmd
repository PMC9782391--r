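---
title: "Low-flow advisories and mL per MAC-hour: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-flow advisories and mL per MAC-hour: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgfcds)
```

## The problem

Volatile anesthetics (sevoflurane, isoflurane, desflurane) are potent
greenhouse gases, with 100-year global warming potentials spanning roughly
130 to 2540 times that of CO~2~. The fresh gas flow (FGF) — the total gas
volume per minute carried from the machine into the breathing circuit — is
the main determinant of how much agent is vaporized and vented: at a given
dial concentration, halving FGF roughly halves consumption. Sustained low
flow during the maintenance phase is safe and effective, but practice drifts
toward high flows without reinforcement. A minimally intrusive, per-minute
advisory at the point of care addresses that drift.

This package is a vendor-neutral, file-based implementation of such an
advisory engine together with the consumption-reporting pipeline used to
evaluate it, and a synthetic case generator so the full chain can be tested
without clinical data.

## The advisory rules

The engine evaluates seven rules once per minute:

1. A volatile agent is the *set agent*. The flowsheet carries one dial
   column per agent; we define the set agent as the volatile agent with the
   highest dial concentration at that minute, ties broken in the fixed order
   sevoflurane, isoflurane, desflurane. A minute with no recorded dial
   reading has no set agent. N~2~O alone therefore never fires; N~2~O used
   alongside a volatile agent can.
2. The set agent is in use: its dial concentration is > 0.
3. Total FGF has been **strictly above** the threshold (default 0.7 L/min;
   "exceeded" is read as `>`) for at least the last `lookback` consecutive
   minutes (default 5), so short reactive flow changes do not fire.
4. The procedure start event has occurred (`t >= procedure_start`). This is
   the sole induction exclusion: induction legitimately uses high flows.
5. The procedure stop event has not occurred (`t < procedure_stop`),
   excluding emergence.
6. The patient is strictly older than the age cutoff (default 1 year).
7. The advisory is neither snoozed (default snooze: 10 minutes) nor
   disabled.

An advisory is emitted at each evaluated minute on which rules 1–6 hold and
rule 7 permits. Consecutive eligible minutes form one **episode**; the
episode count is the headline burden measure, with per-minute firings also
logged for sites that count every refire. The alert *mode* (passive /
noninterruptive / interruptive) changes only event metadata — `displayed`
and `requires_ack` flags — never the firing logic. Site presets
(`site_preset()`) encode the five deployed configurations: thresholds of
0.7 or 1 L/min with noninterruptive, interruptive or passive display.

Decisions made where the rule text left room:

* **Grid gaps reset the counter.** A missing minute is not evidence of high
  flow; the consecutive-minute count restarts after a gap, and an open
  episode closes.
* **Snooze does not stop condition tracking** (configurable via
  `snooze_resets_counter`): if the rules still hold when the snooze
  expires, the advisory fires at exactly that minute. The suppressed
  minutes still belong to the same episode, so burden counts are comparable
  across snooze behavior.
* **Rule 3 evaluates total FGF**, not a per-agent flow, following the
  definition of FGF as the total flow into the breathing system.

## The efficiency metric

All windows are half-open `[start, stop)` in integer minutes — a record
describes the minute beginning at its timestamp, and a cumulative reading
describes consumption through the end of that minute — so phase boundaries
are never double counted.

* induction: `[first minute with dial > 0, procedure_start)`
* maintenance: `[procedure_start, min(procedure_stop, gas_stop))`, where
  `gas_stop` is the minute of the last nonzero dial
* `set_agent_volume` (mL liquid): difference of cumulative ventilator
  readings at the window boundaries when present, otherwise the per-minute
  calculated consumption
  $$V_{liquid} = \frac{c_{dial}/100 \cdot \mathrm{FGF} \cdot 1000 \cdot
  \Delta t}{V_{vapor}/V_{liquid}}, \qquad
  \frac{V_{vapor}}{V_{liquid}} = \frac{\rho}{MW}\,V_m(T)$$
  with the ideal-gas molar volume at a configurable reference temperature
  (default 21 °C, room-temperature vaporizer output). When both sources
  exist, the cumulative reading wins and a discrepancy above 10% is
  reported.
* age-adjusted MAC multiple: mean of all end-tidal concentrations recorded
  in the window divided by the patient's age-adjusted MAC — the ratio of
  the mean, as in the reporting pseudocode, which coincides with the mean
  of per-minute ratios because the denominator is constant within a case.
  The age adjustment uses the standard iso-MAC power relation
  $\mathrm{MAC}(age) = \mathrm{MAC}_{40}\cdot 10^{-0.00269\,(age-40)}$.
* `MAC_hrs` = MAC multiple × window hours;
  `ml_per_MAC_hr = set_agent_volume / MAC_hrs` — the inverse-gas-mileage
  metric, lower is better. A window with zero MAC-hours yields an explicit
  `undefined_metric` flag (and an `NA` ratio), never a silent zero; a
  zero-volume window yields a genuine 0.

End-tidal sampling inside the window is averaged unweighted over the
recorded values; when fewer than 80% of window minutes carry a reading the
row is flagged `low_et_coverage`.

Per-professional metrics use the intersection of each signed-in interval
with maintenance. Intervals of different professionals may overlap
(supervision), so role-wise double counting is intentional; over a
non-overlapping partition the volumes sum exactly to the case volume.

Reporting exclusions: non-reportable locations (pediatric induction rooms,
non-OR anesthesia, labor and delivery); any case with a flowsheet entry
setting a nonzero dial for more than one volatile agent (scanned over the
whole recorded case by default, configurable to maintenance only); and
fewer than 15 recorded delivery minutes, strictly — a 15-minute delivery is
included.

Agent constants (molecular weight, density, MAC~40~, GWP~100~) ship as an
editable YAML table, not code. The printed GWP range is attributed
per-agent (sevoflurane 130, isoflurane 510, desflurane 2540) following the
atmospheric-chemistry literature; the file records this provenance and a
site can substitute its own inventory values.

## What the simulator emulates

`simulate_cohort()` generates phase-structured cases: a 5–15 minute
induction at ~6 L/min with the dial near twice the age-adjusted MAC; a
maintenance segment whose FGF is one draw from a two-component mixture — a
low-flow practice mode near 0.5 L/min and a high-flow mode near 2 L/min,
equal weights by default; and an emergence segment after the dial goes to
zero with flows raised, extending past the procedure stop so the rule-5
exclusion is exercised. Case duration is lognormal (median ≈110 minutes,
truncated to 40–480); ages are truncated normal (50 ± 18 years, 2–95).
End-tidal concentration relaxes exponentially (τ = 3 minutes) toward the
age-adjusted MAC times the target multiple, and decays (τ = 8) after gas
stop. Cumulative liquid volumes are written from the same calculated-
consumption formula the metrics module uses, which is what makes the
two-path agreement test meaningful rather than tautological: the paths
differ in *mechanism* (boundary subtraction vs per-minute summation), not
in source data.

Practitioner behavior is memoryless per episode: each firing episode
independently triggers, with probability `response_probability` (default
0.7), a reduction of FGF below the threshold after `response_latency`
(default 2) minutes. In a high-flow case the flow condition is already
satisfied throughout induction, so the first episode opens exactly at the
procedure start. `estimate_response_probability()` recovers the probability
from the alert log alone, counting an episode as responded when FGF falls
to or below the threshold within latency-plus-tolerance minutes of the
episode's first firing, with an exact Clopper–Pearson interval.

Maintenance FGF is deliberately **constant within a segment**
(`fgf_jitter_sd = 0` by default). With minute-level noise around a swept
threshold, a single eligibility run can split at counter resets, so the
episode count is *not* monotone in the threshold on noisy traces — only
the firing-minute count is. Holding the within-case flow constant makes
episode counts on a fixed cohort genuinely monotone in both threshold and
lookback, which is the regime the burden-sweep analyses assume. The
engine-level property tests assert the generally true statements
(firing-minute monotonicity in threshold; episode monotonicity in
lookback) on arbitrary randomized traces.

What the simulator does **not** model — and therefore what passing tests do
not establish about real data: pharmacokinetic uptake (end-tidal follows a
fixed exponential, not patient physiology), circuit volume and leak
effects, vaporizer temperature/pressure compensation, sub-minute device
dynamics, documentation artifacts (duplicate or clock-skewed rows beyond
what validation rejects), and practitioner habituation (alert fatigue would
make response probability decay over time; here it is exchangeable across
episodes).

## Numerical and testing choices

* Time is integer minutes from the first record of each case; wall-clock
  input is snapped to the floor minute with a warning; duplicate
  timestamps are an error; gaps are never imputed.
* CSV serialization renders doubles with the shortest representation that
  round-trips bit-exactly, so write→read→write is byte-stable and every
  metric is invariant under re-serialization.
* The engine has two equivalent drivers: a vectorized pass used when no
  scripted snooze/disable actions are present, and a minute-by-minute fold
  of `evaluate_minute()` otherwise. Tests assert equality of the two and
  of both against an independent brute-force oracle that re-scans the full
  trailing window every minute, over randomized traces with gaps, snoozes
  and disables (1,000 traces of 60–300 minutes in the acceptance suite).
* Problem sizes used by the verification suites: 1,000 random traces for
  oracle equivalence; 200 simulated cases for the volume cross-path check
  (agreement well below the 1% bound); 100 replicates of 500 cases for
  confidence-interval coverage of the response probability; 100 cases for
  the burden monotonicity sweep. These sizes give stable Monte-Carlo
  behavior while keeping the default check quick on a laptop.
* Engine parameter values are recovered in the acceptance suite by probing
  behavior (bisection on constant traces for the threshold and age cutoff;
  direct observation of first-fire and refire timing for lookback and
  snooze), never by reading configuration back.

## Known limitations

* The per-professional split assigns each professional the full window they
  are signed in for; it does not attribute flow decisions to the individual
  who made them.
* Cost and CO~2~e reporting are volume multiplied by user-supplied
  constants; no prices are shipped, and GWP values are inventory figures,
  not physical constants.
* N~2~O carries no MAC or vapor entry: cohorts maintained on N~2~O alone
  are outside the engine's and the metric's scope, mirroring their
  exclusion from reporting.
* Induction and emergence gas use is out of scope for the efficiency
  metric by design; the metric covers maintenance only.
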