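# Shared fixture builders. Everything is generated in code; no stored data.

`%inrange%` <- function(x, r) x >= r[1] & x <= r[2]

# a small long-format series data frame
make_series <- function(values_by_week, ids = NULL) {
  weeks <- as.numeric(names(values_by_week))
  n <- length(values_by_week[[1]])
  ids <- ids %||% sprintf("S%02d", seq_len(n))
  do.call(rbind, lapply(seq_along(weeks), function(i) {
    data.frame(
      participant_id = ids, week = weeks[i],
      value = values_by_week[[i]], stringsAsFactors = FALSE
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# complete balanced Gaussian series with per-week means
balanced_series <- function(n, week_means, sd = 1) {
  weeks <- as.numeric(names(week_means))
  vals <- lapply(seq_along(weeks), function(i) rnorm(n, week_means[[i]], sd))
  names(vals) <- names(week_means)
  make_series(vals)
}

# a random but valid titration participant record
random_titration_record <- function(id = "R1") {
  n_ae <- rpois(1, 1)
  mk_change <- function(from, to) {
    ins <- sample(mdri_instruments(), 1)
    if (ins == "MOVEMENT_LOG") {
      list(
        instrument = ins,
        delta_duration = round(runif(1, -1.5, 1.5), 2),
        delta_severity = round(runif(1, -1, 1), 2)
      )
    } else {
      list(instrument = ins, delta = round(rnorm(1, -1, 4), 2))
    }
  }
  lab_days <- seq(0, 252, by = 14)
  anc <- pmax(300, rnorm(length(lab_days), sample(c(3000, 1100), 1, prob = c(0.8, 0.2)), 400))
  list(
    participant_id = id,
    weight_kg = runif(1, 15, 80),
    changes_week8 = list(mk_change(0, 8), mk_change(0, 8)),
    changes_week16 = list(mk_change(8, 16), mk_change(8, 16)),
    labs = data.frame(day = lab_days, analyte = "anc", value = anc),
    aes = if (n_ae > 0) {
      onset <- runif(n_ae, 0, 250)
      data.frame(
        onset_day = onset, resolved_day = onset + sample(c(7, 30), n_ae, TRUE),
        grade = sample(1:3, n_ae, TRUE, prob = c(0.7, 0.2, 0.1)),
        hypersensitivity = runif(n_ae) < 0.2
      )
    } else {
      NULL
    },
    withdrawal_week = if (runif(1) < 0.15) sample(c(4, 12, 20, 30), 1) else Inf
  )
}

# an eligible-by-default screening record that tests then perturb
base_screening <- function() {
  list(
    genotype_confirmed = TRUE, age_years = 9, stable_concomitant_meds = TRUE,
    cshq_total = 45, sbrs_ge_minus2sd = FALSE, cns_impairment = FALSE,
    nccpc_total = 8, seizure_disorder = FALSE, movement_disorder = FALSE,
    prior_trial_participation = FALSE, prior_trial_exclusion = FALSE,
    vineland_ratio = 0.8,
    anc = 3000, ast_uln_ratio = 1, alt_uln_ratio = 1, bilirubin_uln_ratio = 1,
    creatinine_clearance = 90, active_infection = FALSE, tb_evidence = FALSE,
    malignancy_history = FALSE, pregnant = FALSE, other_trial = FALSE,
    prior_il1_inhibitor = FALSE, hypersensitivity_ecoli = FALSE
  )
}
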