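#!/usr/bin/env Rscript
# Stage 6: safety tabulation and the immunophenotype post-hoc analysis.
# Adverse events are tabulated by coded term and phase into incidence and
# per-participant event rates (terms below 5% incidence stay in the full
# listing only), and 16-week immune-cell changes are correlated with each
# participant's count of improved / worsened MDRI domains.

library(mdri)

SEED <- 2026
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(cohort_config(), seed = SEED)
pl <- run_pipeline(cohort)

write.csv(pl$safety$table, file.path(out, "safety_table.csv"), row.names = FALSE)
write.csv(pl$safety$full, file.path(out, "safety_full_listing.csv"), row.names = FALSE)
write.csv(pl$safety$any, file.path(out, "safety_any_rows.csv"), row.names = FALSE)

any_on <- pl$safety$any
any_on <- any_on[any_on$term == "any_ae" & any_on$phase == "ON_TREATMENT", ]
cat(sprintf(
  "on treatment: %d of %d participants (%d%%) with any AE; %d events, rate %.2f/participant\n",
  any_on$incidence_n, pl$disposition$enrolled, any_on$incidence_pct,
  any_on$event_n, any_on$event_rate
))
inj <- pl$safety$full[grepl("injection_site", pl$safety$full$term) &
  pl$safety$full$phase == "ON_TREATMENT", ]
cat(sprintf(
  "injection-site terms dominate: %d events across %d coded terms\n",
  sum(inj$event_n), nrow(inj)
))

write.csv(pl$immuno_correlations, file.path(out, "immuno_mdri_correlations.csv"),
  row.names = FALSE
)
ic <- pl$immuno_correlations
for (i in seq_len(nrow(ic))) {
  cat(sprintf(
    "%-8s vs n %s: rho = %+.2f (p = %.3f)%s\n",
    ic$population[i], ic$response_definition[i], ic$rho[i], ic$p[i],
    if (!is.na(ic$p[i]) && ic$p[i] < 0.05) " *" else ""
  ))
}

write.csv(pl$disposition, file.path(out, "disposition.csv"), row.names = FALSE)
cat(sprintf(
  "disposition: %d enrolled, %d on treatment at week 8, %d completed treatment\n",
  pl$disposition$enrolled, pl$disposition$on_treatment_week8,
  pl$disposition$completed_treatment
))
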