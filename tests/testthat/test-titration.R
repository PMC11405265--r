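# Dose-titration state machine and screening eligibility.

chg <- function(instrument, delta) list(instrument = instrument, delta = delta)

test_that("week-8 escalation triggers when a bothersome outcome fails the MCID", {
  reg <- mcid_registry()
  st <- dose_state("P1", 40)

  # both improved by >= MCID: dose stays 100
  s1 <- escalation_decision(st, 8, list(chg("APSI", -0.5), chg("CSHQ", -3.2)), reg)
  expect_equal(s1$dose, 100)
  expect_false(s1$escalated)

  # one improved, one unchanged: escalate to 200
  s2 <- escalation_decision(st, 8, list(chg("APSI", -2), chg("CSHQ", 0)), reg)
  expect_equal(s2$dose, 200)
  expect_equal(s2$escalated_week, 8L)

  # titration uses the inclusive rule: exactly one MCID improvement passes
  s3 <- escalation_decision(st, 8, list(chg("APSI", -0.5), chg("NCCPC_R", -4.6)), reg)
  expect_false(s3$escalated)
  # strict alternative escalates on the same data
  s4 <- escalation_decision(st, 8, list(chg("APSI", -0.5), chg("NCCPC_R", -4.6)),
    reg,
    rule = "gt"
  )
  expect_true(s4$escalated)
})

test_that("the 8 mg/kg/day cap limits the escalation target", {
  st <- dose_state("P1", 20) # cap 160
  s <- escalation_decision(st, 8, list(chg("APSI", 2), chg("CSHQ", 2)), mcid_registry())
  expect_equal(s$dose, 160)
})

test_that("movement log escalates on worsening or no change in either rating", {
  reg <- mcid_registry()
  st <- dose_state("P1", 40)
  mv <- function(dd, ds) {
    list(instrument = "MOVEMENT_LOG", delta_duration = dd, delta_severity = ds)
  }
  expect_false(escalation_decision(st, 8, list(mv(-0.3, -0.2), chg("APSI", -1)), reg)$escalated)
  expect_true(escalation_decision(st, 8, list(mv(-0.3, 0), chg("APSI", -1)), reg)$escalated)
  expect_true(escalation_decision(st, 8, list(mv(0.1, -0.5), chg("APSI", -1)), reg)$escalated)
})

test_that("week 16 escalates on week-8-to-16 worsening after a good week 8", {
  reg <- mcid_registry()
  st <- dose_state("P1", 40)
  st <- escalation_decision(st, 8, list(chg("APSI", -2), chg("CSHQ", -4)), reg)
  expect_false(st$escalated)
  s <- escalation_decision(st, 16, list(chg("APSI", 0.6), chg("CSHQ", 1)), reg)
  expect_true(s$escalated)
  expect_equal(s$escalated_week, 16L)
  # conjunctive mode requires both to worsen
  s2 <- escalation_decision(st, 16, list(chg("APSI", 0.6), chg("CSHQ", 1)),
    reg,
    week16_mode = "both"
  )
  expect_false(s2$escalated)
})

test_that("missing both bothersome outcomes leaves the dose and flags review", {
  reg <- mcid_registry()
  st <- dose_state("P1", 40)
  s <- escalation_decision(st, 8, list(chg("APSI", NA), chg("CSHQ", NA)), reg)
  expect_equal(s$dose, 100)
  expect_equal(s$undecidable_weeks, 8)
})

test_that("persistent lab triggers step the dose down, stop, restart and discontinue", {
  st <- dose_state("P1", 40)
  st$dose <- 200
  # ANC below 1,200 for 15 days
  labs <- data.frame(
    day = c(0, 7, 14, 21, 28),
    analyte = "anc", value = c(3000, 1100, 1050, 1100, 1150)
  )
  aes <- data.frame(
    onset_day = numeric(), resolved_day = numeric(),
    grade = numeric(), hypersensitivity = logical()
  )
  s <- safety_dose_adjustment(st, labs, aes, day = 22)
  expect_equal(s$dose, 150)
  expect_equal(s$safety_phase, "decreased")

  # unresolved 14 days after the decrease: stop
  s2 <- safety_dose_adjustment(s, labs, aes, day = 36)
  expect_equal(s2$dose, 0)
  expect_false(s2$on_treatment)
  expect_equal(s2$last_admin_dose, 150)

  # resolution: restart at half the last administered dose
  labs_ok <- rbind(labs, data.frame(day = 42, analyte = "anc", value = 2500))
  s3 <- safety_dose_adjustment(s2, labs_ok, aes, day = 43)
  expect_equal(s3$dose, 75)
  expect_true(s3$on_treatment)

  # recurrence after restart: discontinue
  labs_bad <- rbind(labs_ok, data.frame(
    day = c(50, 64), analyte = "anc",
    value = c(1000, 900)
  ))
  s4 <- safety_dose_adjustment(s3, labs_bad, aes, day = 64)
  expect_equal(s4$dose, 0)
  expect_equal(s4$safety_phase, "discontinued")
})

test_that("a decrease below 50 mg stops drug instead", {
  st <- dose_state("P1", 40)
  st$dose <- 50
  labs <- data.frame(day = c(0, 14), analyte = "platelets", value = c(40, 35))
  s <- safety_dose_adjustment(st, labs, data.frame(
    onset_day = numeric(), resolved_day = numeric(),
    grade = numeric(), hypersensitivity = logical()
  ), day = 14)
  expect_equal(s$dose, 0)
  expect_equal(s$safety_phase, "stopped")
})

test_that("grade 3 and hypersensitivity AEs trigger a decrease; the threshold amendment is configurable", {
  st <- dose_state("P1", 40)
  aes <- data.frame(onset_day = 10, resolved_day = 40, grade = 3, hypersensitivity = FALSE)
  labs <- data.frame(day = numeric(), analyte = character(), value = numeric())
  s <- safety_dose_adjustment(st, labs, aes, day = 12)
  expect_equal(s$dose, 50)

  # ANC 1,300: below the pre-amendment 1,500 threshold only
  labs2 <- data.frame(day = c(0, 15), analyte = "anc", value = c(1300, 1350))
  expect_equal(safety_dose_adjustment(dose_state("P2", 40), labs2, aes[0, ], 16)$dose, 100)
  expect_equal(
    safety_dose_adjustment(dose_state("P2", 40), labs2, aes[0, ], 16,
      anc_threshold = 1500
    )$dose, 50
  )
})

test_that("full replay produces valid, deterministic dose paths", {
  set.seed(23)
  for (i in 1:400) {
    rec <- random_titration_record(sprintf("R%03d", i))
    s1 <- run_titration(rec)
    s2 <- run_titration(rec)
    expect_identical(s1$history, s2$history) # determinism
    doses <- s1$history$dose_after
    cap <- min(200, 8 * rec$weight_kg)
    expect_true(all(doses <= cap + 1e-9))
    expect_true(all(doses >= 0))
    expect_lte(sum(s1$history$kind == "ESCALATE"), 1)
    # STOP never followed by ESCALATE
    kinds <- s1$history$kind
    stop_at <- which(kinds == "STOP")
    if (length(stop_at)) {
      expect_false("ESCALATE" %in% kinds[seq(min(stop_at) + 1, length(kinds))])
    }
    # doses are reachable by the titration arithmetic: start/escalation
    # levels, -50 mg steps, halving on restart, all under the cap
    reachable <- unique(c(
      0, 100, 200, cap,
      seq(0, 200, by = 50), cap - c(50, 100, 150),
      0.5 * c(50, 100, 150, 200, cap, cap - 50)
    ))
    expect_true(all(vapply(
      doses,
      function(d) any(abs(d - reachable) < 1e-9), logical(1)
    )))
  }
})

test_that("a perfectly improving participant records only start and scheduled stop", {
  rec <- list(
    participant_id = "P1", weight_kg = 40,
    changes_week8 = list(chg("APSI", -5), chg("CSHQ", -8)),
    changes_week16 = list(chg("APSI", -1), chg("CSHQ", -2)),
    labs = NULL, aes = NULL
  )
  s <- run_titration(rec)
  expect_equal(s$history$kind, c("START", "STOP"))
  expect_false(s$escalated_any)
})

test_that("worsening a trajectory never cancels an escalation", {
  reg <- mcid_registry()
  set.seed(31)
  for (i in 1:200) {
    d1 <- rnorm(1, -1, 3)
    d2 <- rnorm(1, -1, 3)
    st <- dose_state("P", 40)
    base <- escalation_decision(st, 8, list(chg("APSI", d1), chg("CSHQ", d2)), reg)
    worse <- escalation_decision(
      st, 8,
      list(chg("APSI", d1 + abs(rnorm(1))), chg("CSHQ", d2 + abs(rnorm(1)))), reg
    )
    if (base$escalated) expect_true(worse$escalated)
  }
})

test_that("eligibility follows the two-of-severity or one-alternate rule", {
  s <- base_screening() # CSHQ 45 + NCCPC-R 8, no exclusions
  expect_true(check_eligibility(s)$eligible)

  only_one <- modifyList(s, list(nccpc_total = 3))
  r <- check_eligibility(only_one)
  expect_false(r$eligible)

  # alternate pathway rescues it
  expect_true(check_eligibility(modifyList(only_one, list(vineland_ratio = 0.4)))$eligible)
  expect_true(check_eligibility(modifyList(only_one, list(prior_trial_exclusion = TRUE)))$eligible)

  # screening neutropenia excludes
  expect_false(check_eligibility(modifyList(s, list(anc = 1100)))$eligible)
  expect_true("neutropenia" %in% check_eligibility(modifyList(s, list(anc = 1100)))$violated)

  # liver rule: >3x ULN alone passes, with bilirubin >2x it excludes
  expect_true(check_eligibility(modifyList(s, list(ast_uln_ratio = 4)))$eligible)
  expect_false(check_eligibility(modifyList(
    s,
    list(ast_uln_ratio = 4, bilirubin_uln_ratio = 2.5)
  ))$eligible)

  # washout windows
  w <- modifyList(s, list(days_since_medication = c(rituximab = 100)))
  expect_false(check_eligibility(w)$eligible)
  expect_true(check_eligibility(modifyList(
    s,
    list(days_since_medication = c(rituximab = 200))
  ))$eligible)

  # missing fields give an indeterminate status listing them
  miss <- s
  miss$anc <- NULL
  r2 <- check_eligibility(miss)
  expect_equal(r2$status, "indeterminate")
  expect_true("anc" %in% r2$missing_fields)
})

test_that("eligibility matches a brute-force evaluation on random screenings", {
  set.seed(37)
  for (i in 1:300) {
    s <- base_screening()
    s$cshq_total <- sample(30:60, 1)
    s$nccpc_total <- sample(0:15, 1)
    s$sbrs_ge_minus2sd <- runif(1) < 0.3
    s$cns_impairment <- runif(1) < 0.3
    s$seizure_disorder <- runif(1) < 0.2
    s$movement_disorder <- runif(1) < 0.3
    s$prior_trial_participation <- runif(1) < 0.1
    s$vineland_ratio <- runif(1, 0.2, 1)
    s$anc <- sample(c(900, 1500, 3000), 1)
    s$age_years <- sample(2:20, 1)
    s$active_infection <- runif(1) < 0.1

    sev <- sum(
      s$cshq_total >= 41, s$sbrs_ge_minus2sd, s$cns_impairment,
      s$nccpc_total >= 7, s$seizure_disorder, s$movement_disorder
    )
    alt <- s$prior_trial_participation || s$prior_trial_exclusion ||
      s$vineland_ratio <= 0.5
    oracle <- s$genotype_confirmed && s$age_years >= 4 &&
      s$stable_concomitant_meds && (sev >= 2 || alt) &&
      s$anc >= 1200 && !s$active_infection
    expect_equal(check_eligibility(s)$eligible, oracle)
  }
})
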