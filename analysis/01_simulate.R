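#!/usr/bin/env Rscript
# Stage 1: generate the synthetic trial cohort.
#
# Every later stage regenerates this cohort from the same seed (the run is
# deterministic), and this stage additionally writes the data as CSV so the
# dataset can be inspected or fed to the pipeline file-first. The truth
# sidecar is written with a `_truth` suffix and is never read by any
# analysis stage.

library(mdri)

SEED <- 2026
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(cohort_config(), seed = SEED)

write.csv(cohort$visits, file.path(out, "visits_scored.csv"), row.names = FALSE, na = "")
write.csv(cohort$weights, file.path(out, "weights.csv"), row.names = FALSE)
write.csv(cohort$labs, file.path(out, "labs.csv"), row.names = FALSE)
write.csv(cohort$aes, file.path(out, "adverse_events.csv"), row.names = FALSE)
write.csv(cohort$immuno, file.path(out, "immunophenotype.csv"), row.names = FALSE)
write.csv(cohort$bothersome, file.path(out, "bothersome_selections.csv"), row.names = FALSE)
write.csv(cohort$treatment_stop, file.path(out, "treatment_stop.csv"), row.names = FALSE)
write.csv(cohort$truth, file.path(out, "cohort_truth.csv"), row.names = FALSE)

n8 <- length(unique(cohort$visits$participant_id[cohort$visits$week == 8]))
n36 <- length(unique(cohort$visits$participant_id[cohort$visits$week == 36]))
cat(sprintf(
  "generated %d participants (seed %d): %d assessable at week 8, %d at week 36\n",
  cohort$config$n_participants, SEED, n8, n36
))
cat(sprintf("%d scores clipped to instrument ranges\n", cohort$clip_log))
cat(sprintf("%d adverse events simulated\n", nrow(cohort$aes)))
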