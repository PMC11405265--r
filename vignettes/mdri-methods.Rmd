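---
title: "Methods: MCID responder analysis, dose titration and longitudinal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MCID responder analysis, dose titration and longitudinal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdri)
```

This package re-implements the complete statistical apparatus of an
open-label phase 1/2 dose-titration trial of daily subcutaneous anakinra (an
interleukin-1 receptor antagonist) in Sanfilippo syndrome (MPS III), a
childhood neurodegenerative lysosomal disease. The trial's design poses
three methodological problems that the package solves as reusable, tested
components: measuring heterogeneous treatment response across very different
symptom domains, driving dose decisions from caregiver-reported change, and
fitting longitudinal models on a two-dozen-participant cohort with
withdrawal. A synthetic cohort generator reproduces the trial's data
structure so every stage runs end to end without access to participant data.

## Instruments and scoring

Six caregiver instruments feed the multi-domain responder index (MDRI); all
are scored so that higher totals mean greater symptom burden, and benefit is
always a decrease:

| Instrument | Items and scale | Total | MCID |
|---|---|---|---|
| CSHQ (sleep) | 33 items, 1–3 | sum, 33–99 | 3.2 |
| SBRS (behavior) | 68 items, 0–6, 15 domain scales | mean of domain means, 0–6 | 0.57 |
| NCCPC-R (pain) | items 0–3 (form length configurable) | sum, stated 0–99 | 4.6 |
| PROMIS Fatigue parent proxy | 10 items, 1–5 | raw sum, 10–50 | 2.2 |
| APSI (parenting stress) | items 0–5 (form length configurable) | sum, stated 0–99 | 0.5 |
| 7-day movement log | 7 days × (duration 1–4, severity 1–3) | (mean duration + mean severity)/2 | derived, 0.14 |

Decisions taken where the scoring rules leave room:

* **Missing items.** Sum-scored instruments refuse missing items by default;
  an explicit proration mode (mean of present items × form length) exists but
  is off, because silent proration biases totals in a cohort this small.
* **Form lengths.** The CSHQ length (33) is forced by its 33–99 total range.
  The NCCPC-R and APSI lengths are configuration, validated only against
  their stated 0–99 total ranges; the stated ranges exceed the arithmetic of
  the commonly published forms, and the package uses them as validation
  bounds without resolving that discrepancy.
* **SBRS total.** "An average of the domain scores" is implemented as the
  unweighted mean of the 15 domain means (`total_method = "domain_mean"`),
  with an item-weighted mean available. The MDRI consumes the raw total mean
  — the scale its 0.57 MCID is defined on — never z-scores. Standardization
  against an MPS III reference cohort is supported but requires an explicit
  reference table; the published reference values are proprietary and no
  defaults are invented. The default item→domain map
  (`sbrs_default_map()`) is likewise a synthetic layout for simulation and
  testing; real analyses must supply the licensed form's map.
* **Movement log.** Days missing either rating are excluded from both 7-day
  averages; at least one complete day is required. The averaging rule's
  arithmetic maximum is (4 + 3)/2 = 3.5 even though the instrument's stated
  range is 1–7; the rule as written governs the computation, and the
  simulator treats 3.5 as the usable ceiling.
* **Vineland screening ratio.** Functional age (mean of subdomain age
  equivalents) over chronological age; the inclusion flag uses ≤ 0.5, with a
  strict < 0.5 variant because the screening text is worded both ways.

## Responder classification and the MDRI

For each instrument, change from day 1 is compared with its minimal
clinically important difference (MCID): improvement is a decrease of more
than one MCID, worsening an increase of more than one MCID, anything else no
change. A change of exactly one MCID is unassigned by that wording; it is
classified NO_CHANGE so the three states partition all outcomes (strict
inequalities on both sides). The MDRI counts, per participant and week, the
domains improved / worsened / unchanged among those assessable; `MISSING`
classifications are excluded from numerator and denominator rather than
imputed, which reproduces the shifting denominators of a cohort with
withdrawal. A participant counts as an "any-domain responder" when at least
one of the six domains improved.

The movement log is study-specific, so its MCID is derived from the data:
half the standard deviation of each participant's change across the 8-week
pre-treatment observation period (the standard distribution-based MCID), with
mean absolute change as an alternative. The published derivation formula is
not stated; both candidates are exposed and the method used is recorded on
the returned value.

## Dose titration

Treatment starts at 100 mg/day. The state machine implements:

* **Escalation (weeks 8 and 16 only, at most once).** At screening each
  caregiver names the two "most bothersome" outcomes. At week 8 the dose
  rises to min(200, 8 mg/kg) unless **both** outcomes improved by at least
  one MCID from day 1 (titration uses the inclusive ≥ comparison; the
  responder index keeps strict >; a config flag aligns them). Participants
  who improved at week 8 are re-checked at week 16 and escalate if either
  outcome worsened from week 8 to week 16 (the protocol's worked example
  fixes the week-8 reference; a conjunctive both-outcomes mode is
  available). The movement log, whose MCID does not exist until the
  observation dataset is complete, escalates on worsening or no change in
  either its duration or severity rating. If both outcomes are unobservable
  at a decision visit the dose is left unchanged and the week is flagged for
  manual review.
* **Safety de-escalation (any time).** Triggers: neutrophils below
  1,200 cells/µL persistent ≥ 2 weeks (the pre-amendment 1,500 threshold is
  configurable), platelets below 50 × 10⁹/L persistent ≥ 2 weeks, an active
  mild/moderate hypersensitivity reaction, or an active grade 3 adverse
  event. "Persistent ≥ 2 weeks" is read as at least two consecutive
  below-threshold measurements spanning ≥ 14 days. A trigger steps the dose
  down 50 mg (a step below the 50 mg minimum stops drug instead); a trigger
  still present 14 days after the decrease stops drug; resolution restarts
  at half the last administered dose (never below 50 mg); recurrence after
  restart discontinues. Escalation decisions are suppressed while a safety
  chain is open, so no dose path ever escalates after a stop.
* **Withdrawal** (caregiver or investigator) is an input flag, not a
  computed outcome: the engine implements the dosing algorithm only.

The cap is applied exactly (8 × weight in kg, no rounding to syringe sizes),
so light participants can carry doses such as 160 mg.

## Longitudinal statistics

Each outcome is fit with the trial's mixed model for repeated measures:
one fixed mean per visit week (time categorical, the saturated means model —
the fixed-effect structure beyond categorical time is unstated, and the
saturated model is the assumption-free default, recorded in the fit
metadata), an unstructured within-participant covariance, REML estimation
(via generalized least squares with per-week variances and free week-pair
correlations, `nlme::gls`). Least-squares means carry 95% t-intervals and
contrasts against day 1 use two-sided Wald tests at a fixed 23 degrees of
freedom — the trial's convention, configurable — with no multiplicity
adjustment, mirroring the source analysis. With complete balanced data the
LS-means provably equal the per-week sample means; the tests assert that
identity to 1e-6. If the unstructured fit fails to converge the model falls
back to heterogeneous compound symmetry and says so in its metadata, never
silently. Treatment-period fits use weeks {0, 8, 16, 24, 36}; the
off-treatment week-44 visit enters only the pre/post observation contrast
(week 0 vs week 44 from a fit over the full schedule), which measures
whether symptoms rebound to their pre-treatment level after drug withdrawal.

Sensitivity analyses: last observation carried forward within the treatment
period (missing post-baseline values take the most recent earlier
observation; leading missings are never back-filled; imputed cells are
masked), and Wilcoxon signed-rank tests on day-1-to-week-36 changes. The
signed-rank test drops zero differences, average-ranks ties, and keeps the
exact null distribution (by convolution over sign patterns, equivalent to
full enumeration) up to n = 25 — questionnaire change scores generate ties
and zeros constantly, exactly where the reference implementation abandons
exactness, which is why the test is written out here. Spearman correlations
(average ranks, t-approximate p, exact permutation option for n ≤ 9) link
16-week immunophenotype changes to each participant's count of improved and
worsened MDRI domains.

## Safety tabulation

Adverse events are classified by onset into a closed treatment interval
(an event on the stop day is on-treatment) or the post-treatment phase;
pre-day-1 events are excluded from the treatment tabulation with a warning.
Incidence is distinct affected participants, the event rate is events
divided by the safety population, rounded half-up to two decimals — the
published table's own arithmetic divides both percents and rates by the full
safety population in every phase, and that is the default, with a
phase-population percent convention available side by side. Rounding is
half-up throughout because report tabulation software rounds halves up,
where base R rounds half to even. Terms below 5% incidence in every phase
drop from the headline table but stay in the full listing.

## The synthetic cohort

The generator emulates the trial's structure: 23 participants; visits at
weeks −8, 0, 8, 16, 24, 36, 44; no systematic drift across the two
observation periods; treatment-onset improvement over weeks 0–36; rebound to
baseline by week 44; visit-driven withdrawal and drug-stop processes;
injection-site-dominated adverse-event streams; immune-cell changes coupled
to a latent response.

The observed score for participant *i*, instrument *k*, week *w* is

> y. = baseline(i,k) + effect_k(w) · latent(i) + noise,

with `effect_k(w) = effect36_k (1 − e^{−w/8})` during treatment, zero before
day 1, and `(1 − rebound) · effect_k(36)` at week 44 (full rebound by
default). `latent(i) ~ N(1, 0.4²)` makes some participants respond more than
others and is the quantity the immunophenotype couples to; visit noise is
exchangeably correlated across instruments within a visit (ρ = 0.3), a
deliberately simple stand-in for the unknown cross-instrument dependence.
Scores are clipped to instrument ranges (clipping is counted and reported).

Where the defaults come from, fixed once:

* published conditions: n = 23; the visit schedule; withdrawal and
  drug-stop hazards sized so the disposition flow thins to ≈21 assessable
  at week 8 and ≈16 at week 36; week-36 effects for the ICR (−2.7) and APSI
  (−3.8) from the printed least-squares mean changes, and visit noise for
  those two backed out of the printed confidence-interval widths; the
  movement-log noise sized so the half-SD observation-period MCID centers on
  the published 0.14; adverse-event intensities at the published event-rate
  magnitudes with injection-site terms dominating; an immunophenotype
  coupling reproducing the reported sign structure (CD4 up, CD8 and
  monocytes down with response, B cells null) — though at n ≈ 20 the
  rank correlation through the discrete MDRI counts is noisy, so its
  published magnitude is not a reproduction target;
* realistic choices where nothing is printed: baseline means and SDs placed
  mid-scale for a moderately-to-severely affected cohort; effects below one
  MCID for the instruments reported as showing no significant mean change;
  noise for the remaining instruments at ≈5% of the scale span. These are
  illustrative, not estimates of the trial's data.

The default generator emits score-level Gaussian data, chosen for analytic
checkability: between two visits a score changes by Normal(δ, 2σ²), so the
expected improved fraction is Φ((−δ − MCID)/σ√2) and the tests verify the
generated cohorts against that closed form. An item-level mode
(`noise_model = "items"`) discretizes each target score into valid item
responses — integer item scales, per-domain SBRS distribution, day-level
movement logs, per-participant stable ICR item sets — and exercises the full
scoring path; discretization moves totals by less than one scale point. A
truth sidecar (latent responses, withdrawal weeks) is emitted for diagnostics
and never consumed by any analysis function; a test deletes it and checks
nothing changes.

What passing on synthetic data does **not** show: the generator's Gaussian
marginals, exchangeable cross-instrument correlation and hazard-based
dropout are simplifications; real caregiver data carry floor/ceiling
concentration, informative missingness and rater drift that nothing here
emulates. Agreement between the pipeline and the generator validates the
*computations*, not the trial's clinical conclusions, and the package's
numbers on synthetic cohorts are stand-ins wherever the trial's
participant-level dataset would be required.

## Problem sizes and numerical choices

The test suite uses cohorts of 1,000 participants for the analytic
responder-fraction checks (three binomial standard errors), 200 simulated
trials for MMRM parameter recovery and coverage, full sign-pattern
enumeration up to n = 10 for the Wilcoxon oracle, and 10,000 random
participant histories for titration determinism and dose-path validity —
sizes at which the Monte-Carlo bounds are tight while a run stays
comfortably within a coffee break. Ties in ranks use average ranks
everywhere; MCID boundaries are resolved by the strict-inequality decision
above; degenerate inputs (all-zero differences, constant vectors, all-missing
instruments, zero-SD derivations) raise classed errors rather than returning
numbers.

## Known limitations

The PROMIS T-score conversion (an external scoring service), Vineland
norm-table lookups, SBRS reference-cohort values and flow-cytometry gating
are out of scope: their outputs are inputs here. The NCCPC-R/APSI stated
ranges are used as bounds without resolving their inconsistency with common
form arithmetic. The exact formula behind the published movement-log MCID is
unstated; both implemented candidates bracket it. Whether ICR menu items
could serve as "most bothersome" titration outcomes is configurable because
the protocol leaves it open.
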