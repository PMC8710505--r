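---
title: "Methods: a lifetime Markov cost-utility model for community hypertension management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime Markov cost-utility model for community hypertension management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htncea)
```

`htncea` evaluates three strategies for managing hypertension in a rural
community — usual practice, an integrated-care package (Option 1:
multidisciplinary teams plus a multi-institutional pathway), and the same
package with global-budget pay-for-performance (Option 2) — by projecting
trial-period observations over a lifetime with a Markov cohort model. This
vignette records the model, its assumptions, and the design decisions taken
where the methodology was genuinely open.

## State space and dynamics

The model tracks nine mutually exclusive states: prehypertension,
hypertension grades L1–L3 (defined by the standard SBP/DBP cutpoints:
prehypertension 120–139/80–89, L1 140–159/90–99, L2 160–179/100–109,
L3 ≥180/≥110 mmHg), four complication states (myocardial infarction,
stroke, congestive heart failure, end-stage renal disease), and absorbing
death. Two structural assumptions shape the space:

* **No return to normotension.** Managed patients are assumed never to
  regain normotension; prehypertension is the best attainable state.
  Normotension therefore appears in the observed transition counts but not
  in the model.
* **No recovery from complications.** The complication states have no
  outgoing transitions except death; residual probability stays in state.

A cohort enters at age 35 distributed 0.32/0.53/0.12/0.03 over the four
blood-pressure states and is propagated for 65 one-year cycles — a lifetime
horizon: about 98.6% of the cohort is absorbed into death by the final
cycle. Each cycle's 9×9 matrix is rebuilt at the cohort's current age:

1. the annual transition probabilities fill the off-diagonals
   (prehypertension→ESRD is a structural zero: no estimate exists for it);
2. every living state receives the 5-year age band's background mortality
   into death, *added* to any disease-specific death probability (so an
   ESRD patient faces both the ESRD case-fatality hazard and ordinary
   mortality);
3. the arm effect is applied (below), and the residual probability stays
   in state.

Rows are validated to sum to 1 within 1e-12 every cycle; a row whose
off-diagonals exceed 1 aborts the run with the offending state named,
rather than being renormalized silently.

## From trial observations to annual probabilities

The estimation stage consumes longitudinal records (patient, arm,
bi-monthly visit index 0–12, SBP/DBP, assigned blood-pressure state, eight
SF-36 dimension scores) and follows the source study's six-step procedure:
classify patients at baseline and at the 12th follow-up, count one
transition per patient between those two endpoints, convert the count to a
*study probability*, then annualize through a constant hazard:
rate = −(1/t)·ln(1−p) and annual p = 1−exp(−rate).

Three conventions deserve emphasis because they are unusual and are
implemented deliberately, as defaults with documented alternatives:

* **Whole-cohort denominator.** A pair's study probability divides its
  count by the *entire* analyzable cohort (e.g. 383/1248 = 0.3069 for
  L1→prehypertension), not by the number of patients starting in the
  origin state. This reproduces the published annual matrix exactly; the
  conventional row-conditional estimator is available via
  `denominator = "origin"`.
* **Study window t = 2 years.** The window is never stated explicitly in
  the source, but t = 2 (twelve bi-monthly visits) is the unique value
  under which every published 2-year study probability maps onto its
  published annual counterpart to 4 decimals; the test suite sweeps all
  12 rows. The window is a function argument.
* **Normotension is dropped, not folded.** Transitions into normotension
  are discarded before annualization (the published annual table contains
  no normotension rows and its values derive from the unfolded counts);
  `normotension = "fold"` relabels them as prehypertension instead.

Patients missing either endpoint (12.63% loss to follow-up in the source
cohort) are excluded from counting and reported. Whether the source study
excluded them before or after assembling its denominator is unknowable from
the publication; since the packaged count table is used directly for the
base case, the question only affects re-estimation from raw records.

The blood-pressure control rate — the effectiveness measure — is the
proportion of post-baseline measurements with SBP strictly below 120 mmHg
(the intensive-treatment threshold; 120 itself is not controlled), pooled
over all measurements in an arm. A per-patient-then-average variant exists
but is off by default; the pooling level is not stated in the source.

## Utilities

Blood-pressure state utilities are SF-36 profiles mapped to an EQ-5D index
with the published additive equation (intercept 0.03256; coefficients
PF 0.0037, SF 0.00111, RP −0.00024, RE 0.00024, MH 0.00256, VT −0.00063,
BP 0.00286, GH 0.00052). The equation is applied verbatim. Two numerical
consequences are handled explicitly: predictions below 0 (possible because
RP and VT carry negative weights) are clamped to 0 with a warning so QALY
arithmetic stays well defined, and predictions above 1 (the equation's
eight coefficients sum to 0.01012, so a perfect-health profile maps to
1.04456 — the mapping's known overprediction near full health) are clamped
into [0,1] only when estimates are installed into a runnable parameter
set. Complication-state utilities are literature constants
(MI 0.684, stroke 0.605, CHF 0.64, ESRD 0.60). Death has utility 0.

## Costs

All costs are 2021 US dollars. Recorded costs from earlier years pass
through `adjust_cost()` (2.5%/yr inflation; CNY converted at 0.156 USD/CNY
where applicable); programme staff time is costed by the human-capital
shortcut `salary / 250 days / 8 h × additional hours`.

State costs are annual treatment costs (prehypertension $140.69 through
ESRD $19,406.36/yr). Programme (human + project) costs are *trial-scale
totals*; the source gives no rule for allocating them per person-year, so
the package converts them as
`(human + project) / 415 patients / 1.5 years` — 415 ≈ one third of the
analyzable cohort, 1.5 years the intervention span — and, by default,
applies that per-person cost in every cycle a person is alive, modelling a
standing programme (`lifelong_intervention`; a fixed number of cycles is
available). This allocation is the single largest reproduction risk for
absolute cost totals and is therefore logged in every pipeline run.

## The arm effect

The source estimates one transition matrix (from the pooled cohort) and
three arm control rates, but never states how the control rate enters the
model. The package's mechanism: every *improvement* transition — a move to
a strictly less severe blood-pressure grade (L1→pre, L2→pre/L1,
L3→pre/L1/L2) — is multiplied by `control_rate / reference_control_rate`,
with the reference fixed at usual practice (0.61) and the change absorbed
by the origin's stay probability. The mechanism is monotone in the control
rate, leaves the usual arm at exactly the estimated matrix, and keeps rows
stochastic. It reproduces the published *orderings* (QALYs: Option 2 >
Option 1 > usual; Option 2 dominant against both comparators; Option 1 not
cost-effective) but not the published absolute totals, whose generating
mechanism is unrecoverable from the publication; the test suite treats
those totals as monitored sign/ordering checks rather than equality gates.

## Discounting and accumulation

Costs, QALYs and life-years accrue from beginning-of-cycle occupancy and
are discounted by 1/(1+r)^cycle with cycle 0 undiscounted (r = 5%,
varied 0–8% one-way). There is no half-cycle correction by default — the
source describes plain per-cycle accumulation — but
`half_cycle_correction = TRUE` averages start- and end-of-cycle occupancy.
Undiscounted totals are reported alongside discounted ones.

## Decision rules

For each ordered pair: ICER = ΔC/ΔE, NMB = λ·ΔE − ΔC, NHB = ΔE − ΔC/λ at
λ = $1,599.16/QALY. Dominance (ΔC<0, ΔE>0) is flagged *and* the raw
negative ratio is reported, matching the source's presentation of negative
ICERs. NMB = λ·NHB holds identically and is property-tested. Reports round
to cents and 3-decimal QALYs; internal arithmetic is full precision.

## Sensitivity analysis

**One-way:** each parameter in turn is set to the ends of its published
range (95% CI where given, ±20% where the source lacked references;
discount rate 0–8%) and the decision outcome (default: ICER of Option 2 vs
usual) recomputed; rows sort by swing. A parameter with a zero-width range
— or one whose pathway the cohort never visits — has provably zero swing,
which is property-tested.

**Probabilistic:** 1,000-iteration second-order Monte Carlo.
Probabilities, utilities and control rates draw from beta distributions,
costs from gamma, each parameterized by method of moments from the
published mean and interval with SD = (high − low)/3.92 (the interval
treated as a normal 95% range; the source states only the families). The
resulting distribution has the published mean exactly. Draws are
independent across parameters (no correlation structure is published) and
shared across arms within an iteration; transition cells are drawn
per cell with the residual diagonal re-absorbing the change. The CEAC
reports, over a willingness-to-pay grid from 0 to 4× the threshold in 100
steps (always containing the threshold exactly), the fraction of
iterations in which each arm has the highest NMB; exact ties split
equally, which matters only in the degenerate all-fixed case, where the
PSA reproduces the base case bit-for-bit (also property-tested). With all
parameters at their published ranges Option 2 attains the highest
cost-effectiveness probability at the threshold, as in the source; the
package's probabilities are flatter than the published triple because the
variance of the mechanism-dependent cost difference dominates.

## The synthetic trial

`generate_cohort()` emulates the study conditions so the estimation code
is testable without patient data: three arms (default 416 patients each),
baseline mix 0.32/0.53/0.12/0.03, twelve bi-monthly visits over two years,
states evolving by the annual matrix converted to a 2-month step
(1−(1−p)^(1/6), so six steps compose back to the annual value),
blood pressure drawn uniformly within the occupied state's cutpoint band —
except that each post-baseline visit is "controlled" with the arm's
control frequency (0.61/0.62/0.69), in which case SBP is drawn below
120 mmHg while the recorded state remains the underlying Markov state —
SF-36 scores equal across dimensions at the level that maps to the state's
published utility, plus Gaussian noise (SD 8 points, truncated to 0–100),
and geometric dropout calibrated so 12.63% of patients miss the final
visit. Everything is deterministic given the mandatory seed.

What it does *not* emulate: the intervention's causal pathway (arms differ
only through control frequencies and costs), within-band blood-pressure
structure, correlation between SF-36 dimensions, visit-level state
measurement error, and informative dropout. Passing recovery tests
therefore demonstrate that the estimators invert the generator's
mechanism, not that they are robust to real-data violations of it.

One subtlety in the recovery loop: because the study-probability
convention divides by the whole cohort, the estimand is the annualized
*joint* probability (baseline state *and* endpoint state), whose
expectation under the generator is π₀ᵢ·(S¹²)ᵢⱼ for step matrix S. The
recovery test compares estimates against that closed-form expectation —
computed independently by matrix power — within 3 binomial standard errors
(delta-method propagated through the annualization), on a 5,000-patient
cohort.

## Problem sizes and tolerances

The test suite runs the full 65-cycle model many times but keeps Monte
Carlo sizes modest by design: 5,000 patients for parameter recovery
(binomial SEs small enough to detect a mis-implemented conversion),
200 PSA iterations for the ordering check (the published claim is
qualitative), 10⁵ draws for distribution-mean checks. Conservation is
asserted at 1e-12, algebraic identities at 1e-9, published table
reproductions at the tables' own printed precision (4 decimals), and
printed decision arithmetic within 1% — the slack needed because the
source prints rounded inputs whose exact intermediates are unavailable.

## Known limitations

* The arm-effect mechanism and programme-cost amortization are the
  package's own reconstructions (documented above); absolute totals should
  be read comparatively, not as reproductions of the source's spreadsheet.
* Utilities and costs are age-invariant; only mortality is age-indexed.
* The cohort engine is deterministic at the population level; there is no
  microsimulation, so patient-level heterogeneity beyond the state space
  is out of scope.
* The published ESRD incidence decreases with hypertension severity
  (0.0152/0.0078/0.0017 for L1/L2/L3) — plausibly a transcription artifact
  in the source; the values are implemented as printed.
* The SF-36→EQ-5D mapping is a British general-population model applied to
  a rural Chinese cohort; mapped utilities inherit its biases, including
  overprediction near the healthy extreme.
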