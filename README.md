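# mdri

Scoring, responder classification, dose-titration logic and longitudinal
statistics for an open-label phase 1/2 trial of daily anakinra
(interleukin-1 receptor antagonist) in Sanfilippo syndrome (MPS III) — built
as a reusable, tested R package plus a numbered analysis workflow, runnable
end to end on a synthetic cohort that emulates the trial's data structure.

Sanfilippo syndrome is a fatal childhood neurodegenerative disease whose
most burdensome symptoms — disordered sleep, pain, challenging behavior,
disordered movement, caregiver strain — vary widely between children. A
single primary scale would miss most of the action, so the trial measured
response with a **multi-domain responder index (MDRI)**: six caregiver
instruments (CSHQ sleep, SBRS behavior, NCCPC-R pain, PROMIS fatigue, APSI
parenting stress, a 7-day movement log), each compared with its **minimal
clinically important difference (MCID)**. With change Δ from day 1 and MCID
m, a domain is *improved* if Δ < −m, *worsened* if Δ > +m, else *no change*;
a participant responds when ≥ 1 of the 6 domains improves. The same MCIDs
drive **dose titration**: at week 8 (or 16) the daily dose rises from 100 to
200 mg (capped at 8 mg/kg) unless both caregiver-selected "most bothersome"
outcomes improved by at least one MCID, and lab/AE safety triggers step the
dose down 50 mg, stop, restart at half dose, or discontinue. Longitudinal
change is estimated with a **mixed model for repeated measures** (categorical
time, unstructured within-participant covariance, REML) reported as
least-squares means with 95% CIs and Wald contrasts at 23 df, with LOCF and
Wilcoxon signed-rank sensitivity analyses, and adverse events are tabulated
into incidence and per-participant event rates.

## Layout

- `R/` — the package: instrument scorers, MCID registry and MDRI, titration
  state machine and eligibility gate, MMRM/LOCF/Wilcoxon/Spearman,
  safety tables, synthetic cohort generator, pipeline.
- `analysis/01_simulate.R … 06_safety_immuno.R` — numbered drivers that run
  each stage on the synthetic cohort and write tables under `results/`.
- `tests/testthat/` — unit, property and acceptance tests.
- `vignettes/mdri-methods.Rmd` — the methods write-up: models, assumptions,
  parameter choices, generator design, limitations.

## Worked example

```r
library(mdri)

cohort <- generate_cohort(cohort_config(), seed = 2026)
pl <- run_pipeline(cohort)
pl
#> <MDRI pipeline run>
#>   enrolled 23; assessable at week 8: 22
#>   week  8: 19/22 (86%) improved on >= 1 MDRI domain
#>   week 16: 16/17 (94%) improved on >= 1 MDRI domain
#>   week 36: 13/13 (100%) improved on >= 1 MDRI domain
#>   escalated: 16/21 (76%) at week 8; 18/21 (86%) at week 8 or 16
#>   movement-log MCID (half_sd, n = 23): 0.147

lsmean_contrast(pl$lsmeans$ICR$observed, 0, 8)[c("estimate", "ci_low", "ci_high")]
#> $estimate [1] -1.982  $ci_low [1] -3.408  $ci_high [1] -0.557
```

Reading: on this simulated cohort, 19 of the 22 participants still
assessable at week 8 improved beyond the MCID on at least one of the six
domains; 16 of the 21 on treatment at week 8 met the escalation rule; the
movement-log MCID derived from the pre-treatment observation period is
0.147; and the individual clinical response (0–20 caregiver score) dropped
by an estimated 2.0 points from day 1 to week 8 (95% CI −3.4 to −0.6) in the
repeated-measures model. The numbered scripts print these narratives stage
by stage and write the corresponding CSVs:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

Single operations work standalone:

```r
score_movement_log(duration = c(1, 2, 1, 1, 3, 1, 1), severity = rep(2, 7))$total
#> [1] 1.714286
classify_change(baseline = 40, followup = 36, mcid = 3.2)
#> [1] "IMPROVED"
event_rate(408, 23)
#> [1] 17.74
```

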