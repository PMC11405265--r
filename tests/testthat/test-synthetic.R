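# Synthetic cohort generator: determinism, degenerate configurations, and
# the analytic responder-fraction property.

test_that("the generator is deterministic under a fixed seed", {
  a <- generate_cohort(seed = 101)
  b <- generate_cohort(seed = 101)
  expect_identical(a$visits, b$visits)
  expect_identical(a$aes, b$aes)
  expect_identical(a$labs, b$labs)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(seed = 102)
  expect_false(identical(a$visits$total, c2$visits$total))
})

test_that("zero effect and zero noise yield flat series and all NO_CHANGE", {
  cfg <- cohort_config()
  cfg$instruments$effect36 <- rep(0, 7)
  cfg$instruments$noise_sd <- rep(0, 7)
  cfg$instruments$baseline_sd <- rep(0, 7)
  cfg$latent_sd <- 0
  cfg$withdraw_hazard <- c("8" = 0)
  cfg$stop_drug_hazard <- c("8" = 0)
  co <- generate_cohort(cfg, seed = 103)
  spread <- tapply(co$visits$total, co$visits$instrument, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  pl <- run_pipeline(co, derive_movement = FALSE)
  cls <- unlist(lapply(pl$mdri, function(r) r$classifications))
  expect_true(all(cls == "NO_CHANGE"))
})

test_that("an infeasible effect size is rejected", {
  expect_error(
    {
      cfg <- cohort_config()
      cfg$instruments$effect36[cfg$instruments$instrument == "SBRS"] <- -10
      cohort_config(instruments = cfg$instruments)
    },
    class = "mdri_config_error"
  )
})

test_that("improved fractions match the analytic normal-theory value", {
  # change between two visits is Normal(delta, 2 * noise_sd^2) when the
  # latent heterogeneity and cross-instrument correlation are switched off
  cfg <- cohort_config(
    n_participants = 1000,
    latent_sd = 0, noise_correlation = 0,
    withdraw_hazard = c("8" = 0), stop_drug_hazard = c("8" = 0)
  )
  co <- generate_cohort(cfg, seed = 104)
  reg <- mcid_registry()
  for (ins in c("APSI", "NCCPC_R", "PROMIS_FATIGUE")) {
    row <- cfg$instruments[cfg$instruments$instrument == ins, ]
    delta <- row$effect36 * (1 - exp(-8 / cfg$onset_tau))
    sigma <- sqrt(2) * row$noise_sd
    p_theory <- pnorm((-get_mcid(reg, ins) - delta) / sigma)
    v <- co$visits[co$visits$instrument == ins, ]
    chg <- v$total[v$week == 8] - v$total[v$week == 0]
    p_hat <- mean(chg < -get_mcid(reg, ins))
    se <- sqrt(p_theory * (1 - p_theory) / length(chg))
    expect_lt(abs(p_hat - p_theory), 3 * se)
  }
})

test_that("strong benefit with small noise drives the improved fraction to one", {
  cfg <- cohort_config(
    n_participants = 400, latent_sd = 0, noise_correlation = 0,
    withdraw_hazard = c("8" = 0), stop_drug_hazard = c("8" = 0)
  )
  cfg$instruments$effect36[cfg$instruments$instrument == "APSI"] <- -10
  cfg$instruments$noise_sd[cfg$instruments$instrument == "APSI"] <- 1
  co <- generate_cohort(cfg, seed = 105)
  v <- co$visits[co$visits$instrument == "APSI", ]
  chg <- v$total[v$week == 8] - v$total[v$week == 0]
  expect_gt(mean(chg < -0.5), 0.9)
})

test_that("adverse-event streams follow the configured intensities", {
  cfg <- cohort_config(n_participants = 200)
  set.seed(106)
  aes <- simulate_aes(cfg, sprintf("P%03d", 1:200))
  ery <- aes[aes$term == "injection_site_erythema" & aes$phase == "ON_TREATMENT", ]
  lambda <- cfg$ae_intensity$on_treatment[cfg$ae_intensity$term == "injection_site_erythema"]
  rate <- nrow(ery) / 200
  expect_lt(abs(rate - lambda), 3 * sqrt(lambda / 200))

  # zero intensity produces an empty stream
  cfg0 <- cohort_config()
  cfg0$ae_intensity$on_treatment[] <- 0
  cfg0$ae_intensity$post_treatment[] <- 0
  set.seed(107)
  expect_equal(nrow(simulate_aes(cfg0, sprintf("P%02d", 1:23))), 0)

  # degenerate grade distribution
  cfg1 <- cohort_config(ae_grade_probs = c(1, 0, 0))
  set.seed(108)
  aes1 <- simulate_aes(cfg1, sprintf("P%02d", 1:23))
  expect_true(all(aes1$grade == 1))
})

test_that("immunophenotype coupling has the configured signs and a null B cell", {
  cfg <- cohort_config(n_participants = 400, immuno_noise_sd = 0.01)
  set.seed(109)
  latent <- rnorm(400, 1, 0.5)
  im <- simulate_immunophenotype(cfg, sprintf("P%03d", 1:400), latent)
  rho_of <- function(pop) {
    x <- im$change_pct[im$population == pop]
    spearman_corr(x, latent)$rho
  }
  expect_gt(rho_of("CD4_T"), 0.99) # near-noiseless monotone limit
  expect_lt(rho_of("CD8_T"), -0.99)
  expect_lt(rho_of("MONOCYTE"), -0.99)
  expect_lt(abs(rho_of("B_CELL")), 0.15) # uncoupled

  # zero coupling: CD4 correlation centered at zero
  cfg0 <- cohort_config(n_participants = 400, immuno_coupling = 0)
  set.seed(110)
  im0 <- simulate_immunophenotype(cfg0, sprintf("P%03d", 1:400), latent)
  x0 <- im0$change_pct[im0$population == "CD4_T"]
  expect_lt(abs(spearman_corr(x0, latent)$rho), 0.15)
})

test_that("item-level mode round-trips through the scorers", {
  cfg <- cohort_config(n_participants = 6, noise_model = "items")
  co <- generate_cohort(cfg, seed = 111)
  expect_false(is.null(co$raw_items))
  scored <- score_visits(co$raw_items)
  # discretization moves totals by less than one scale point
  m <- merge(co$visits, scored,
    by = c("participant_id", "week", "instrument"),
    suffixes = c("_target", "_scored")
  )
  expect_true(all(abs(m$total_target - m$total_scored) <= 1 + 1e-9))
  # ICR item sets are per-participant stable, so scoring succeeds cohort-wide
  expect_setequal(unique(scored$instrument), c(mdri_instruments(), "ICR"))
})

test_that("analysis outputs do not depend on the truth sidecar", {
  co <- generate_cohort(seed = 112)
  pl1 <- run_pipeline(co)
  co$truth <- NULL
  pl2 <- run_pipeline(co)
  expect_equal(pl1$mdri_summary, pl2$mdri_summary)
  expect_equal(pl1$titration, pl2$titration)
})
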