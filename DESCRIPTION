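Package: mdri
Title: Multi-Domain Responder Index Analysis for a Dose-Titration Trial in Sanfilippo Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scoring, responder classification and longitudinal statistics for
    an open-label dose-titration trial of daily anakinra in Sanfilippo syndrome
    (mucopolysaccharidosis type III). Provides scorers for the six caregiver
    instruments entering the multi-domain responder index (CSHQ, SBRS, NCCPC-R,
    PROMIS Fatigue Parent Proxy raw sum, APSI, 7-day disordered-movement log)
    plus the individual clinical response and the Vineland functional-age
    screening ratio; MCID-based improved/no change/worsened classification and
    cohort responder summaries; the MCID-driven dose-titration state machine
    (escalation at weeks 8/16, lab- and AE-driven de-escalation, stop/restart)
    and the screening eligibility gate; mixed-model repeated-measures
    least-squares means with Wald contrasts, LOCF sensitivity imputation, exact
    Wilcoxon signed-rank tests and Spearman rank correlations for the
    immunophenotype analysis; adverse-event incidence and event-rate tables;
    and a synthetic cohort generator emulating the trial's visit schedule,
    dropout and adverse-event structure so the whole pipeline runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
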