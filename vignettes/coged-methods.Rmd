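---
title: "Measuring the subjective cost of cognitive effort: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the subjective cost of cognitive effort: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coged)
library(dplyr)
```

## The measurement problem

Cognitive effort discounting (COG-ED) treats willingness to work as an
economic preference. A participant repeatedly chooses between performing an
easy task (the 1-back) for a small, adjustable payment and a harder N-back
level for a larger, fixed payment. The adjustable offer is titrated until
the two options are equally attractive; the resulting *indifference point*,
expressed as a fraction of the fixed offer, is the *subjective value* (SV)
of performing the harder task. SV below 1 quantifies, in dollars, how much
reward the effort cost destroys. `coged` implements the whole measurement
chain — stimulus generation, titration, valuation, synthetic participants,
and the statistical models — so the paradigm can be simulated, stress-tested
and analyzed end to end.

## N-back stimulus lists

A run is a sequence of 64 consonants containing 16 *targets* (items that
match the item exactly N positions back) and a level-specific number of
*lures* — items that repeat within N+2 positions of their last occurrence
but not at exactly lag N, included to elicit false alarms (8 lures at N = 1,
6 at N = 2, 5 at N = 3, 3 at N = 4-6). All remaining items are *fillers*
that repeat at no lag up to N+2.

Design choices where the protocol leaves room:

* **Alphabet.** The 20 uppercase English consonants excluding Y (ambiguous
  between vowel and consonant). Matching is case-insensitive.
* **Lure lags.** "Within N+2 but not exactly N" is implemented literally:
  any lag `1..N+2` except N counts, including lags shorter than N.
* **Clean fillers.** Fillers are required to match nothing within the full
  N+2 window, so lure and target counts are exact, not merely minimums.
  Placement uses rejection sampling capped at 10,000 attempts; infeasible
  requests (e.g. more targets than positions beyond N) fail with an error
  naming the violated count.
* **Validation is independent.** `validate_stimulus_list()` recounts roles
  by a brute-force scan over all lags, sharing no bookkeeping with the
  generator; the test suite asserts the two agree for every level and seed
  tried.

Scoring follows signal detection: d′ = z(hit rate) − z(false-alarm rate),
with rates clamped to `[1/(2n), 1 − 1/(2n)]` of their trial counts so
perfect runs stay finite (the protocol does not state a correction; the
1/(2n) rule is the package's choice). The first N positions can never be
targets and are excluded from hit-rate denominators. A non-response counts
as incorrect for both scores, since a response was required for every item.
Mean RT is computed over correct trials only. Run feedback is "Good job!"
only when both the percent-of-targets and percent-of-non-targets scores
exceed 50%. Timing parameters (1.5 s response window, 3.5 s inter-item
interval) are stored as metadata; no real-time presentation is implemented.

## The adjusting-amount staircase

The easy offer starts at half the base amount ($1.00 against a $2.00 base)
and moves by a step that begins at a quarter of the base ($0.50) and halves
after every choice: up when the harder option is chosen, down otherwise.
After six choices the final adjustment is $0.015625 — the "$0.015" of the
protocol at millicent truncation — and the post-final amount is the
indifference point.

```{r staircase}
always_hard <- function(offer, condition, base) "HARD"
run_titration(always_hard, condition = 4, base_amount = 2)
```

Properties the implementation guarantees (and the tests enumerate):

* The reachable indifference points form exactly the 64-point dyadic grid
  `start ± subset sums of {0.5, 0.25, ..., 0.015625}`, spanning
  $0.015625-$1.984375 on a $2 base.
* For any deterministic agent with threshold in that span, the estimate is
  within one final step ($0.015625) of the threshold — verified by brute
  force over all 2⁶ choice paths.
* All staircase amounts are dyadic rationals, which IEEE-754 doubles
  represent exactly, so no rounding ever perturbs the grid (an integer
  fixed-point representation would not help: $0.015625 is not a whole
  number of tenths of cents).

Offer order is *non-nested*: each round presents every (condition, base
amount) pair once in an independently re-shuffled order, so consecutive
choices for one staircase are separated by others. Per-round re-shuffling
(rather than one global shuffle) was chosen as the natural reading of
"randomized and non-nested"; it is what `build_schedule()` implements.
Exact ties in an agent's valuation resolve to the easy option. Delay
discounting reuses the same machinery with delays in days as conditions;
the start (50% of the delayed amount) and first step (25%) mirror standard
adjusting-immediate-amount practice. Six months is coded as 182.5 days and
a year as 365 days.

## Valuation: SV curves and AUC

`subjective_value()` is the indifference amount over the base;
`extra_payment()` is the implied premium `base × (1 − SV)`. The
area under the discounting curve (`discount_auc()`) integrates SV against
the condition axis by trapezoids after rescaling the axis to total width 1,
so AUC lies in [0, 1], equals 1 for a non-discounter, and is invariant to
affine rescaling of the raw axis. Effort AUCs use levels 2-4 so every
participant is scored on the same basis.

Under this normalized convention the all-EASY responder scores
`0.015625 / 2 = 0.0078125` and the all-HARD responder `0.9921875`. A
printed range of "0.015 to 1.0" cannot arise from any single convention
(0.015625 is the *unnormalized* floor, 1.0 slightly exceeds the reachable
ceiling); the package keeps the normalized convention and documents the
discrepancy rather than special-casing either bound.

The NASA-TLX composite averages per-scale trapezoid AUCs over the
normalized level axis, computed on raw 0-21 ratings so the composite stays
in rating units. Missing scales raise an error; nothing is imputed.

## Synthetic agents

Agents exist to close the loop: they make titration choices from known
latent preferences so that recovery can be checked against ground truth.

* **Effort.** True SV is linear in load,
  `SV = clamp(1 − κ·(N−1)·base^(−γ), 0, 1)`: the reference level N = 1 has
  SV 1; κ is the cost per load step as a fraction of the base; γ ≥ 0 makes
  larger offers proportionally cheaper to work for (the amount effect
  emerges iff γ > 0). The linear form matches the observed roughly linear
  decline of SV with load; a convex (quadratic) cost is available behind
  `convex_cost = TRUE`.
* **Delay.** Hyperbolic, `V = A / (1 + k(A)·D)` with
  `k(A) = k_delay·(A/1000)^(−ξ)`, so the discount rate at $25,000 never
  exceeds the rate at $1,000.
* **Choice.** The hard option is valued at `SV·base` (or the discounted
  present value); with temperature τ = 0 the better option is chosen
  deterministically (ties → EASY), otherwise
  `P(HARD) = logistic((value_hard − value_easy)/τ)`, with τ interpretable
  as dollars of decision noise.
* **Performance.** d′ declines linearly with load
  (`d0 − δ·(N−1)`, floored at 0) and RT grows linearly, both with Gaussian
  noise; group differences enter through the parameters, not the model.

### Cohort defaults

The default cohort emulates the published study populations: 25 agents per
age group; performance intercepts and slopes taken from the reported
group-by-level means (YA d′ 3.42 at N = 1 falling by ≈0.59 per level, OA
3.13 falling by ≈0.58; YA ≈0.59 s baseline RT, OA ≈0.79 s). Effort-cost
distributions are κ ~ N(0.175, 0.12²) for YA and N(0.35, 0.15²) for OA,
truncated at 0. These means were set once, by forward simulation of the
truncated/clamped cost model, so the implied group statistics land near the
reported effort-discounting summaries (YA mean AUC ≈ 0.72 and mean SV at
N = 4 ≈ 0.49; OA ≈ 0.36 and 0.20); because a single linear cost cannot
reproduce both statistics exactly, the defaults compromise within ±0.05 of
each. Choice noise defaults to τ = $0.05 and amount sensitivity to
γ = 0.12. Older adults draw from a higher income distribution (retirees'
pre-retirement income), and the delay discount rate decreases with income —
so, as in the human data, income rather than age accounts for group
differences in delay (but not effort) discounting. Need-for-cognition
scores are generated as increasing in the agent's true AUC plus noise, and
the two 1-10 decision-basis ratings use the reported group means (amount:
7.7 YA / 5.8 OA; scoring: 4.9 YA / 6.6 OA).

All randomness flows from a single cohort seed through fixed per-agent
substreams, so a cohort is byte-reproducible from one integer.

### What the generator does not emulate

Synthetic agents have exactly linear true SV, independent logistic choice
noise, and performance that is statistically independent of effort cost.
Real participants show none of these conveniences: SV curves can be convex,
choices serially dependent, and motivation correlated with performance.
Passing recovery tests therefore demonstrates that the *procedure and
estimators* are correct and unbiased under the model, not that the model
exhausts real behavior — the empirical coefficient values reported for the
human samples are deliberately out of scope.

## Statistical models

`fit_sv_mlm()` fits, by REML through `nlme`, a random-intercept model of SV
on d′, mean RT (seconds) and load centered at 2.5 (levels 1-4 code as
−1.5..1.5), optionally adding age (0 = YA, 1 = OA) and its interaction with
load, and optionally stratifying residual variance by age group via
`varIdent` (reporting a restricted-likelihood-ratio statistic against the
homogeneous fit, which is non-negative by nesting). The theoretical
reference point SV₁ = 1 enters as an *anchor row* carrying the observed
N = 1 performance; `include_anchor = FALSE` drops those rows.
`fit_sv_mlm_ratio()` is the anchor-free variant: levels 2-4 only, load
centered at 3, with each level's performance expressed as a ratio to the
participant's own N = 1 baseline (constant ratios are dropped with a
warning rather than silently aliased).

Denominator degrees of freedom follow the within/between decomposition and
are computed from the documented formula rather than inherited from the
library: terms varying within participants are tested on
`n_obs − n_participants − p_within` df (e.g. 100 − 25 − 3 = 72 for a
single-group fit of levels 1-4), participant-constant terms on
`n_participants − 1 − p_between` df (e.g. 48 for the age effect in a
50-participant fit). p-values are two-sided throughout and no
multiple-testing correction is applied.

`linear_contrast()` implements the one-way linear-trend test with centered
condition coordinates as weights, F on (1, n_obs − k) df and
η² = SS_contrast/SS_total; a constant response returns F = 0 rather than an
error. `group_compare()` wraps rank-sum/signed-rank and t tests;
`hierarchical_delta_r2()` reports ΔR² with its incremental F; logistic fits
surface complete separation as an explicit warning. Income enters
regressions as its ordinal bin index 1-9.

### Degenerate inputs

Exactly linear SV data (zero residual variance) defeat the REML iteration;
when that happens and an OLS fit is numerically exact, the model falls back
to reporting the exact coefficients with zero variance components instead
of failing. Rank-deficient fixed-effect designs are rejected with an error
naming the columns; mixed-model non-convergence on non-degenerate data is
re-raised as a diagnostic error.

## Simulation sizes and reproducibility

The bundled tests and the acceptance script size their simulations as
follows, chosen to make Monte-Carlo standard errors small relative to the
asserted tolerances: staircase properties are verified exhaustively (all 64
paths, plus ~300 threshold probes); load-slope recovery uses 100-200
replicate cohorts of 25 participants; power checks use 100-200 replicates;
cohort-level group comparisons use 16-40 agents per group. The
`run_pipeline()` manifest records the seed, configuration and MD5 checksums
of every CSV it writes; the same seed yields byte-identical artifacts.

## Known limitations

* The titration floor means a participant who always chooses EASY is
  recorded at SV = 0.0078 (on a $2 base), not 0; true SVs below the grid
  floor or above its ceiling are censored to one grid step.
* The elicitation never offers *less* money for the harder task, so
  preferences for engagement (SV > 1) are unmeasurable by design.
* The heterogeneous-variance likelihood-ratio statistic is data-dependent;
  only its non-negativity and calibration are testable properties.
* Parametric discount functions are deliberately not fitted to effort
  curves; AUC is used as the atheoretical summary.
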