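---
title: "Modelling methods: ezetimibe add-on cost-utility after ACS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling methods: ezetimibe add-on cost-utility after ACS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezcua)
```

## Scope and question

`ezcua` implements a cohort-level cost-utility comparison of two
secondary-prevention strategies after acute coronary syndrome (ACS) in
patients intolerant of high-intensity statins: ezetimibe 10 mg/day added
to a moderate-intensity statin versus the moderate-intensity statin
alone. The evaluation setting is Thailand: costs in 2024 THB, a
willingness-to-pay ceiling of 160,000 THB/QALY, 3% annual discounting of
both costs and outcomes, and societal and healthcare-provider cost
perspectives (the societal perspective adds direct non-medical costs —
transport and caregiver time; indirect productivity costs are excluded
throughout, per Thai HTA guidance).

## Model structure and assumptions

The model is a four-state annual-cycle Markov cohort: *no further
event*, *non-fatal MI*, *non-fatal stroke*, *death*. The cohort enters
at age 62 in the no-event state and is followed to age 100. Structural
assumptions, all shared with the source decision model this analysis
follows:

* no recurrent events beyond the first post-event state, and no
  MI↔stroke crossover;
* no concurrent MI and stroke within a cycle;
* treatment discontinuation and adverse events are not modelled
  (ezetimibe add-on tolerability is comparable to statin monotherapy);
* event probabilities are age-constant (trial-average annual risks),
  while background mortality is age-specific.

These simplifications apply identically to both arms, so their impact
falls mainly on absolute rather than incremental results.

## Transition probabilities

Background mortality comes from a life table of age-specific annual
mortality rates. The conversion and adjustment chain for the no-event
state is

1. multiply the rate by the post-ACS excess-mortality hazard ratio
   HR = exp(0.693) ≈ 2.0 (hazard ratios act on the rate scale);
2. convert to an annual probability, `p = 1 − exp(−r·t)` with `t = 1`;
3. multiply by the all-cause death relative risk (1 in the comparator
   arm, 0.99 under ezetimibe; relative risks act on the probability
   scale, clamped at 1 with a warning).

Post-event states use registry-derived annual case-fatality
probabilities (0.090263 post-MI, 0.071593 post-stroke), multiplied in
the ezetimibe arm by the state-specific relative risks (0.84, 0.90).

**Post-event mortality convention.** How state case fatality should
combine with age-specific background mortality is not uniquely
determined by the published description, so the package exposes a switch
(`post_event_mortality`): `"event_only"` (case fatality is the sole
mortality in the state), `"max"` (never below general-population
mortality) and `"competing"` (independent-risk combination). The default
is `"event_only"`: it is the only convention under which the model's
comparator discounted life-years (11.28 with the synthetic life table)
and the one-way sensitivity profile of the MI-death relative risk
(ICER changes −27%/+45% across 0.55–1.07) line up with the reference
analysis's reported values (11.32; −27.31%/+54.32%), and it matches how
the original four-state model family handled post-event survival. Its
known cost is that beyond roughly age 95 the post-event states become
*less* lethal than the general population; the age-100 horizon keeps the
affected mass small (the cohort is ~97% absorbed by the horizon).

## Costs and outcomes

Per cycle, state-time is the half-cycle-corrected trapezoid
`(occupancy[t−1] + occupancy[t])/2` (switchable to end-of-cycle
occupancy), and cycle `t` is discounted by `1/(1+r)^(t−offset)` with
mid-cycle offset 0.5 by default (offset 0 available). Categories:

* **Drug costs** — annual price × living state-time, so the statin
  ledger entry is exactly `292 THB × discounted life-years` (the
  relation the reference base-case table satisfies: 292 × 11.3216 ≈
  3,306 THB). Annual prices are daily prices × 365 (0.80 and 4.74
  THB/day, recorded in the configuration metadata).
* **Post-ACS care** — first-year cost (65,507) on no-event state-time in
  cycle 1; maintenance cost (39,617) on no-event state-time thereafter.
  A switch (`acs_cost_states = "all_living"`) extends accrual to the
  post-event states; the default keeps categories disjoint.
* **MI / stroke care** — the default attribution
  (`first_year_cost_basis = "cycle1"`) charges the first-year cost on
  the state's occupancy in model cycle 1 only and the maintenance cost
  on its occupancy thereafter. This is deliberately chosen because it
  reproduces the reference ledger *to the THB* (e.g. first-year MI cost
  148,366 × 0.0169 / 1.03 ≈ 2,434), implying that is how the original
  spreadsheet model kept its books. The epidemiologically more natural
  alternative — a one-cycle tunnel charging the first-year cost once per
  incident event in its inflow cycle (`"inflow"`) — is implemented and
  tested; it raises the first-year categories roughly tenfold and lowers
  the ICER by ~10%, which is why the convention is surfaced as an
  explicit, logged switch rather than buried.
* **Direct non-medical costs** — first-year value on living state-time
  in cycle 1, the subsequent-year value on living state-time thereafter;
  included only under the societal perspective.

QALYs weight state-time by utilities `u = 0.82` (no event),
`0.82 − 0.41635` (post-MI), `0.82 − 0.2259` (post-stroke); a sampled
decrement exceeding the sampled baseline utility is a validation error
(such probabilistic draws are rejected and re-sampled). The ICER is
`ΔCost/ΔQALY` with dominance flags replacing the ratio when signs make
it misleading; cost-effectiveness at the threshold means dominance or
ICER ≤ 160,000 THB/QALY.

## Parameter uncertainty

Reported intervals are treated as normal-approximation 95% confidence
intervals, `SE = (high − low)/3.92`. Method-of-moments fits:

* **beta** (probabilities, utilities): `ν = m(1−m)/SE² − 1`,
  `α = mν`, `β = (1−m)ν` — mean-preserving;
* **gamma** (costs, utility decrements): `shape = (m/SE)²`,
  `scale = SE²/m` — mean-preserving;
* **log-normal** (relative risks): `meanlog = ln m`,
  `sdlog = (ln high − ln low)/3.92` — median-preserving, the standard
  treatment of ratio-scale CIs. The excess-mortality parameter is stored
  as a log hazard ratio with its interval already on the log scale, so
  its fit uses `meanlog = 0.693`, `sdlog = (0.76 − 0.62)/3.92`.

Several printed intervals are asymmetric around their point estimate
(e.g. the cost intervals, which look like −31%/+3.4% bands); the
moment fits preserve the point estimate and the interval *width*, not
asymmetry. One-way sensitivity analysis uses the reported interval when
present and otherwise ±10% (probabilities/utilities) or ±20% (costs).

The probabilistic analysis samples every parameter independently (no
correlation structure is published), one draw per parameter per
iteration in the fixed canonical parameter order, shared by both arms
within an iteration; 1,000 iterations by default, seeded, and
bit-reproducible for a given seed. Infeasible draws are re-sampled and
counted. The NMB tie-break at exactly zero counts as *not*
cost-effective; cost-effectiveness plane quadrants use a half-open
convention (a delta of exactly zero counts as positive). The CEAC grid
runs 0–400,000 THB in steps of 10,000 and therefore contains the
160,000 threshold exactly.

## The synthetic life table

The national life table behind the reference analysis is not printed in
any redistributable source, so the package generates a deterministic
stand-in from a Gompertz–Makeham hazard,
`rate(a) = α·e^{β(a−62)} + γ`, with defaults `α = 0.012`, `β = 0.085`,
`γ = 0.001` over ages 62–100. The calibration target was a plausible
undiscounted remaining life expectancy at 62 of 18–22 years; the default
gives 20.6 years, matching published general-population values at that
age in Thailand, and was fixed once from that external anchor. Ages past
the table's end hold the last rate constant; tables with gaps in the age
index are rejected rather than interpolated.

What the synthetic table does and does not emulate: it reproduces the
level and broad age-gradient of elderly background mortality, which is
what the incremental comparison mainly needs — with it, the base case
lands within ~4% of the reference headline values (ICER 160,874 vs
155,312 THB/QALY societal). It does not reproduce the exact age profile
of the national table, and results that depend on fine balance at single
parameter bounds can flip qualitatively: at the upper bound of the
all-cause death relative risk (1.07) the synthetic table's heavier
old-age mortality drives ΔQALY slightly negative (a dominated corner,
hence a sign-flipped ICER ratio and an inflated tornado spread), whereas
the reference analysis reports the ICER staying positive there. Passing
tests under the synthetic table therefore demonstrate engine
correctness and the published qualitative profile, not agreement with
the national-life-table numbers; supplying a real `age,mortality_rate`
CSV enables the tighter reproduction checks in the test suite.

## Numerical choices

* Row-stochasticity is enforced to 1e-12 at matrix construction and
  re-audited by `validate_model()`; cohort conservation is tested to
  1e-10 over the full trace.
* The engine and the direct life-table survivorship computation agree to
  1e-9 on undiscounted life-years when events and adjustments are
  switched off (a cross-module oracle, part of the test suite).
* `max_age = 100` truncates the trace; the surviving mass (<3% at base
  case) receives its final-cycle half-credit and nothing beyond. The cap
  is a setting, not a constant.
* Probabilities produced by relative-risk scaling are clamped at 1 with
  a warning; clamping never occurs at base-case inputs.
* Problem sizes used by the shipped tests: the full 38-cycle horizon
  everywhere; probabilistic runs of 300–1,000 iterations for
  consistency checks (a 1,000-iteration run takes a few seconds); a
  20,000-draw Monte-Carlo moment check for the distribution fits.

## Known limitations

* The two arms' event probabilities are sampled independently in the
  probabilistic analysis, slightly widening the spread of incremental
  outcomes relative to a correlated (shared-draw) design; no published
  correlation structure exists to calibrate one.
* The ezetimibe-arm event probabilities are primary inputs, not derived
  from the comparator by any published relative risk (their implied
  ratios, 0.874 for MI and 0.859 for stroke, match no reported effect
  estimate), so they cannot be updated by swapping in a different
  treatment-effect source without re-deriving both.
* First-year event costs under the default attribution are charged only
  in model cycle 1 (see above): events occurring in later cycles incur
  maintenance costs only. This mirrors the reference ledger but
  understates acute-care costs of late events; use `"inflow"` for the
  tunnel-based alternative.
* No recurrent events, crossovers, discontinuation, adverse events,
  indirect costs, or budget-impact extensions; no EVPI.
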