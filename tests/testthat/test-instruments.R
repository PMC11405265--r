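# Scorers for the caregiver instruments: fixed examples, validation errors,
# and range/permutation properties.

test_that("sum-scored instruments reproduce forced totals and extremes", {
  expect_equal(score_cshq(rep(1, 33))$total, 33)
  expect_equal(score_cshq(rep(3, 33))$total, 99)
  expect_equal(score_cshq(c(rep(2, 5), rep(1, 28)))$total, 38)

  expect_equal(score_nccpc(rep(0, 30))$total, 0)
  expect_equal(score_nccpc(c(3, rep(0, 29)))$total, 3)
  expect_equal(score_nccpc(c(3, 2, 1))$total, 6) # 3-item toy form

  expect_equal(score_promis_fatigue(rep(1, 10))$total, 10)
  expect_equal(score_promis_fatigue(rep(5, 10))$total, 50)
  expect_equal(score_promis_fatigue(c(1:5, 1:5))$total, 30)

  expect_equal(score_apsi(rep(0, 13))$total, 0)
  expect_equal(score_apsi(c(5, 5, 5))$total, 15)
  expect_equal(score_apsi(0:3)$total, 6)
})

test_that("item validation names the offending index and rejects bad lengths", {
  items <- rep(2, 33)
  items[17] <- 4
  expect_error(score_cshq(items), "17", class = "mdri_validation_error")
  expect_error(score_cshq(rep(2, 32)), class = "mdri_length_error")
  expect_error(score_promis_fatigue(rep(0, 10)), class = "mdri_validation_error")
  expect_error(score_nccpc(rep(4, 30)), class = "mdri_validation_error")
})

test_that("missing items error by default and prorate only on request", {
  items <- rep(2, 33)
  items[5] <- NA
  expect_error(score_cshq(items), class = "mdri_missing_items_error")
  pro <- score_cshq(items, prorate = TRUE)
  expect_equal(pro$total, 2 * 33) # mean of present items times form length
  expect_equal(pro$n_items_used, 32)
})

test_that("SBRS means follow the domain structure", {
  expect_equal(score_sbrs(rep(0, 68))$total_mean, 0)
  p <- score_sbrs(rep(3, 68))
  expect_equal(p$total_mean, 3)
  expect_true(all(p$domain_means == 3))
  expect_true(all(p$cluster_means == 3))

  # two-domain toy form, hand-computed: A = mean(2,2,4,4) = 3, B = mean(0,6) = 3
  toy_map <- list(
    domains = list(A = 1:4, B = 5:6),
    clusters = list(only = c("A", "B"))
  )
  toy <- score_sbrs(c(2, 2, 4, 4, 0, 6), map = toy_map)
  expect_equal(unname(toy$domain_means), c(3, 3))
  expect_equal(toy$total_mean, 3)
})

test_that("SBRS standardizes against a supplied reference table", {
  ref <- list(
    mean = c(total = 2, Movements = 3),
    sd = c(total = 0.5, Movements = 1.5)
  )
  p <- score_sbrs(rep(3, 68), reference = ref)
  expect_equal(unname(p$z_scores["total"]), (3 - 2) / 0.5)
  expect_equal(unname(p$z_scores["Movements"]), 0)
  bad_ref <- list(mean = c(total = 2), sd = c(total = 0))
  expect_error(score_sbrs(rep(3, 68), reference = bad_ref), class = "mdri_config_error")
})

test_that("SBRS map validation rejects gaps and unknown cluster members", {
  gap_map <- list(domains = list(A = 1:60), clusters = list(c1 = "A"))
  expect_error(score_sbrs(rep(1, 68), map = gap_map), class = "mdri_config_error")
  bad_cluster <- list(domains = list(A = 1:6), clusters = list(c1 = "Z"))
  expect_error(score_sbrs(rep(1, 6), map = bad_cluster), class = "mdri_config_error")
})

test_that("movement log averages duration and severity over present days", {
  expect_equal(score_movement_log(rep(1, 7), rep(2, 7))$total, 1.5)
  expect_equal(score_movement_log(rep(4, 7), rep(3, 7))$total, 3.5)
  s <- score_movement_log(c(1, 2, 1, 1, 3, 1, 1), rep(2, 7))
  expect_equal(s$total, (10 / 7 + 2) / 2)
  expect_error(
    score_movement_log(rep(NA_real_, 7), rep(NA_real_, 7)),
    class = "mdri_insufficient_data_error"
  )
  # missing days excluded from both averages
  dur <- c(2, NA, 2, 2, NA, 2, 2)
  sev <- c(3, NA, 3, 3, NA, 3, 3)
  expect_equal(score_movement_log(dur, sev)$total, 2.5)
  expect_equal(score_movement_log(dur, sev)$n_items_used, 5)
})

test_that("movement log matches a brute-force day-listing oracle", {
  set.seed(41)
  for (i in 1:50) {
    dur <- sample(1:4, 7, replace = TRUE)
    sev <- sample(1:3, 7, replace = TRUE)
    oracle <- (sum(dur) / 7 + sum(sev) / 7) / 2
    expect_equal(score_movement_log(dur, sev)$total, oracle)
  }
})

test_that("ICR scores the five chosen items and enforces the menu", {
  menu5 <- icr_item_menu()[1:5]
  expect_equal(score_icr(menu5, rep(0, 5))$total, 0)
  expect_equal(score_icr(menu5, rep(4, 5))$total, 20)
  expect_equal(score_icr(menu5, c(2, 3, 1, 0, 4))$total, 10)
  expect_error(score_icr(c(menu5[1:4], menu5[1]), rep(1, 5)), class = "mdri_validation_error")
  expect_error(score_icr(c(menu5[1:4], "not_a_symptom"), rep(1, 5)), class = "mdri_validation_error")
})

test_that("Vineland ratio and flag follow the screening rule", {
  r <- vineland_ratio(rep(48, 4), 120)
  expect_equal(r$ratio, 0.4)
  expect_true(r$below_half)
  expect_false(vineland_ratio(rep(120, 3), 120)$below_half)
  expect_equal(vineland_ratio(c(24, 36, 30), 100)$ratio, 0.3)
  # boundary: inclusion wording is <= 0.5; strict mode flips it
  expect_true(vineland_ratio(60, 120)$below_half)
  expect_false(vineland_ratio(60, 120, strict = TRUE)$below_half)
  expect_error(vineland_ratio(c(10, -2), 100), class = "mdri_validation_error")
  expect_error(vineland_ratio(10, 0), class = "mdri_validation_error")
})

test_that("every scorer stays inside its declared range on random valid input", {
  set.seed(42)
  for (i in 1:100) {
    expect_true(all(score_cshq(sample(1:3, 33, TRUE))$total %inrange% c(33, 99)))
    expect_true(all(score_promis_fatigue(sample(1:5, 10, TRUE))$total %inrange% c(10, 50)))
    expect_true(all(score_nccpc(sample(0:3, 30, TRUE))$total %inrange% c(0, 99)))
    expect_true(all(score_apsi(sample(0:5, 13, TRUE))$total %inrange% c(0, 99)))
    expect_true(all(score_sbrs(sample(0:6, 68, TRUE))$total_mean %inrange% c(0, 6)))
    expect_true(all(
      score_movement_log(sample(1:4, 7, TRUE), sample(1:3, 7, TRUE))$total %inrange% c(1, 3.5)
    ))
    expect_true(all(
      score_icr(sample(icr_item_menu(), 5), sample(0:4, 5, TRUE))$total %inrange% c(0, 20)
    ))
  }
})

test_that("sum scorers are permutation invariant and SBRS is within domains", {
  set.seed(43)
  items <- sample(1:3, 33, TRUE)
  expect_equal(score_cshq(items)$total, score_cshq(rev(items))$total)
  sb <- sample(0:6, 68, TRUE)
  map <- sbrs_default_map()
  shuffled <- sb
  for (d in map$domains) shuffled[d] <- sample(sb[d]) # permute within domains
  expect_equal(score_sbrs(sb)$total_mean, score_sbrs(shuffled)$total_mean)
  expect_equal(score_sbrs(sb)$cluster_means, score_sbrs(shuffled)$cluster_means)
})
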