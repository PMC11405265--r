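# MCID registry, change classification, MDRI aggregation, movement-log MCID.

test_that("the default registry carries the six MDRI instruments", {
  reg <- mcid_registry()
  expect_setequal(reg$instrument, mdri_instruments())
  expect_equal(reg$mcid[reg$instrument == "CSHQ"], 3.2)
  expect_equal(reg$mcid[reg$instrument == "SBRS"], 0.57)
  expect_equal(reg$mcid[reg$instrument == "NCCPC_R"], 4.6)
  expect_equal(reg$mcid[reg$instrument == "PROMIS_FATIGUE"], 2.2)
  expect_equal(reg$mcid[reg$instrument == "APSI"], 0.5)
  expect_equal(reg$mcid[reg$instrument == "MOVEMENT_LOG"], 0.14)
  expect_true(all(reg$direction == "decrease"))
  expect_error(mcid_registry(overrides = c(BOGUS = 1)), class = "mdri_config_error")
})

test_that("change classification applies strict MCID inequalities", {
  expect_equal(classify_change(40, 36, 3.2), "IMPROVED")
  expect_equal(classify_change(10, 10, 3.2), "NO_CHANGE")
  # a change of exactly one MCID is unassigned by the rule: NO_CHANGE
  expect_equal(classify_change(10, 13.2, 3.2), "NO_CHANGE")
  expect_equal(classify_change(10, 6.8, 3.2), "NO_CHANGE")
  expect_equal(classify_change(10, 14, 3.2), "WORSENED")
  expect_equal(classify_change(NA, 14, 3.2), "MISSING")
  expect_equal(classify_change(10, NA, 3.2), "MISSING")
  expect_error(classify_change(Inf, 1, 3.2), class = "mdri_validation_error")
  expect_error(classify_change(1, 2, -1), class = "mdri_validation_error")
})

test_that("classification is antisymmetric and scale equivariant", {
  set.seed(7)
  for (i in 1:200) {
    b <- rnorm(1, 50, 10)
    f <- rnorm(1, 50, 10)
    m <- runif(1, 0.1, 6)
    cls <- classify_change(b, f, m)
    swapped <- classify_change(f, b, m)
    expect_equal(
      swapped,
      switch(cls, IMPROVED = "WORSENED", WORSENED = "IMPROVED", cls)
    )
    k <- runif(1, 0.2, 9)
    expect_equal(classify_change(k * b, k * f, k * m), cls)
  }
})

test_that("MDRI counts conserve and any_improved means at least one", {
  reg <- mcid_registry()
  base <- c(
    CSHQ = 50, SBRS = 3, NCCPC_R = 20, PROMIS_FATIGUE = 30,
    APSI = 40, MOVEMENT_LOG = 2
  )
  fup <- c(
    CSHQ = 45, SBRS = 3.1, NCCPC_R = 26, PROMIS_FATIGUE = 30.5,
    APSI = 38, MOVEMENT_LOG = NA
  )
  r <- evaluate_mdri(base, fup, reg, "P1", 8)
  expect_equal(unname(r$classifications["CSHQ"]), "IMPROVED")
  expect_equal(unname(r$classifications["NCCPC_R"]), "WORSENED")
  expect_equal(unname(r$classifications["MOVEMENT_LOG"]), "MISSING")
  expect_equal(r$n_assessed, 5)
  expect_equal(r$n_improved + r$n_worsened + r$n_no_change, r$n_assessed)
  expect_true(r$any_improved)

  flat <- evaluate_mdri(base, base, reg)
  expect_false(flat$any_improved)
  expect_equal(flat$n_no_change, 6)

  expect_error(
    evaluate_mdri(base, base * NA, reg),
    class = "mdri_insufficient_data_error"
  )
})

test_that("conservation holds on random cohorts and fractions match a recount", {
  set.seed(11)
  reg <- mcid_registry()
  results <- list()
  for (p in 1:40) {
    base <- c(
      CSHQ = runif(1, 40, 80), SBRS = runif(1, 1, 5), NCCPC_R = runif(1, 5, 50),
      PROMIS_FATIGUE = runif(1, 15, 45), APSI = runif(1, 20, 70),
      MOVEMENT_LOG = runif(1, 1, 3)
    )
    fup <- base + rnorm(6, 0, 3)
    fup[sample(6, rbinom(1, 2, 0.2))] <- NA
    results[[p]] <- evaluate_mdri(base, fup, reg, sprintf("P%02d", p), 8)
  }
  for (r in results) {
    expect_equal(r$n_improved + r$n_worsened + r$n_no_change, r$n_assessed)
  }
  s <- summarize_mdri_cohort(results)
  # independent brute-force recount per instrument
  for (ins in mdri_instruments()) {
    cls <- vapply(results, function(r) r$classifications[[ins]], character(1))
    n <- sum(cls != "MISSING")
    row <- s$by_instrument[s$by_instrument$instrument == ins, ]
    expect_equal(row$n_assessed, n)
    expect_equal(row$pct_improved, 100 * sum(cls == "IMPROVED") / n)
  }
  any_hand <- mean(vapply(results, `[[`, logical(1), "any_improved"))
  expect_equal(s$any_improved$pct_any_improved, 100 * any_hand)
})

test_that("an instrument missing for everyone is reported as not assessable", {
  reg <- mcid_registry()
  base <- c(CSHQ = 50, SBRS = 3)
  results <- lapply(1:10, function(i) {
    evaluate_mdri(base, c(CSHQ = 50 - i, SBRS = NA), reg, paste0("P", i), 8)
  })
  s <- summarize_mdri_cohort(results)
  sbrs_row <- s$by_instrument[s$by_instrument$instrument == "SBRS", ]
  expect_equal(sbrs_row$n_assessed, 0)
  expect_true(is.na(sbrs_row$pct_improved))
  cshq_row <- s$by_instrument[s$by_instrument$instrument == "CSHQ", ]
  expect_equal(cshq_row$pct_improved, 70) # changes -1..-10: seven exceed MCID 3.2
})

test_that("under pure noise the improved fraction approaches Phi(-MCID/sigma)", {
  set.seed(19)
  sigma <- 2
  mcid <- 3.2
  n <- 4000
  base <- rnorm(n, 60, 8)
  fup <- base + rnorm(n, 0, sigma)
  improved <- vapply(
    seq_len(n),
    function(i) classify_change(base[i], fup[i], mcid) == "IMPROVED", logical(1)
  )
  p_hat <- mean(improved)
  p_theory <- pnorm(-mcid / sigma)
  se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(p_hat - p_theory), 3 * se)
})

test_that("movement-log MCID derivation matches hand-computed values", {
  x <- c(0.2, -0.2, 0.3, -0.3)
  expect_equal(as.numeric(derive_movement_mcid(x)), 0.5 * sd(x))
  expect_equal(round(as.numeric(derive_movement_mcid(x)), 3), 0.147)
  expect_equal(
    as.numeric(derive_movement_mcid(c(0.1, 0.1, 0.3, 0.3), method = "mean_abs")),
    0.2
  )
  expect_error(derive_movement_mcid(rep(0.2, 5)), class = "mdri_degenerate_error")
  expect_error(derive_movement_mcid(0.1), class = "mdri_insufficient_data_error")
  expect_equal(attr(derive_movement_mcid(x), "method"), "half_sd")
})

test_that("bothersome selections are two distinct outcomes and immutable", {
  sel <- track_bothersome(c("APSI", "NCCPC_R"))
  expect_s3_class(sel, "bothersome_selection")
  expect_error(track_bothersome(c("APSI", "APSI")), class = "mdri_validation_error")
  expect_error(track_bothersome(c("APSI", "pain")), class = "mdri_validation_error")
  expect_silent(track_bothersome(c("APSI", "pain"), allow_icr_items = TRUE))
  later <- sel
  expect_identical(later, sel)
})
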