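# Scorers for the caregiver-reported instruments used in the trial.
#
# All six MDRI instruments are scored so that HIGHER totals mean MORE symptom
# burden; the direction of benefit is a decrease for every one of them.

#' Identifiers of the instruments handled by the package
#'
#' The six instruments composing the multi-domain responder index, plus the
#' individual clinical response (ICR) and the Vineland screening ratio.
#'
#' @return character vector of instrument identifiers.
#' @export
instrument_ids <- function() {
  c(
    "CSHQ", "SBRS", "NCCPC_R", "PROMIS_FATIGUE", "APSI", "MOVEMENT_LOG",
    "ICR", "VINELAND"
  )
}

#' Instruments entering the multi-domain responder index
#' @return character vector of the six MDRI instrument identifiers.
#' @export
mdri_instruments <- function() {
  c("CSHQ", "SBRS", "NCCPC_R", "PROMIS_FATIGUE", "APSI", "MOVEMENT_LOG")
}

#' Score the Children's Sleep Habits Questionnaire (CSHQ)
#'
#' 33 items, each rated 1--3; the total sleep-disturbance score is the item
#' sum and ranges 33--99. Higher scores indicate more frequent or severe sleep
#' problems.
#'
#' @param items integer vector of length 33 with values in 1..3. `NA` marks a
#'   missing item.
#' @param subscale_map optional named list mapping subscale name to item
#'   indices; subscale sums are reported when supplied.
#' @param prorate if `TRUE`, a form with missing items is scored as
#'   mean-of-present times 33; by default missing items are an error, because
#'   silent proration biases totals in a cohort of two dozen participants.
#' @return an `instrument_score` with `total` in 33..99.
#' @export
#' @examples
#' score_cshq(rep(2, 33))$total # 66
score_cshq <- function(items, subscale_map = NULL, prorate = FALSE) {
  s <- sum_score(items, 33, 1, 3, "CSHQ", prorate)
  subs <- subscale_sums(items, subscale_map, "CSHQ")
  new_instrument_score("CSHQ", s$total, s$n_items_used, subs)
}

#' Score the Non-Communicating Children's Pain Checklist -- Revised (NCCPC-R)
#'
#' Items are rated 0--3 across seven indicator scales (vocal, social, facial,
#' activity, body/limbs, physiological, eating/sleeping); the total pain score
#' is the item sum, with a stated range of 0--99.
#'
#' @param items integer vector with values in 0..3; length is the configured
#'   form length (`n_items`).
#' @param n_items form length; defaults to `length(items)`.
#' @param subscale_map optional named list of item-index vectors.
#' @inheritParams score_cshq
#' @return an `instrument_score`; total validated against 0..99.
#' @export
score_nccpc <- function(items, n_items = length(items), subscale_map = NULL,
                        prorate = FALSE) {
  s <- sum_score(items, n_items, 0, 3, "NCCPC-R", prorate)
  if (s$total > 99) {
    abort_mdri("NCCPC-R: total exceeds stated maximum of 99", "mdri_validation_error")
  }
  new_instrument_score(
    "NCCPC_R", s$total, s$n_items_used,
    subscale_sums(items, subscale_map, "NCCPC-R")
  )
}

#' Score the PROMIS Fatigue Parent Proxy custom short form (raw sum)
#'
#' Ten items rated 1--5; the raw total ranges 10--50. The trial's T-score
#' conversion used an external scoring service and is out of scope here; only
#' the raw sum is computed.
#'
#' @param items integer vector of length 10 with values in 1..5.
#' @inheritParams score_cshq
#' @return an `instrument_score` with `total` in 10..50.
#' @export
score_promis_fatigue <- function(items, prorate = FALSE) {
  s <- sum_score(items, 10, 1, 5, "PROMIS fatigue", prorate)
  new_instrument_score("PROMIS_FATIGUE", s$total, s$n_items_used)
}

#' Score the Autism Parenting Stress Index (APSI)
#'
#' Items rated 0--5; total is the item sum, with a stated range of 0--99.
#'
#' @param items integer vector with values in 0..5.
#' @param n_items form length; defaults to `length(items)`.
#' @inheritParams score_cshq
#' @return an `instrument_score`; total validated against 0..99.
#' @export
score_apsi <- function(items, n_items = length(items), prorate = FALSE) {
  s <- sum_score(items, n_items, 0, 5, "APSI", prorate)
  if (s$total > 99) {
    abort_mdri("APSI: total exceeds stated maximum of 99", "mdri_validation_error")
  }
  new_instrument_score("APSI", s$total, s$n_items_used)
}

#' Score the 7-day disordered-movement log
#'
#' Caregivers log, for each of 7 days, the duration of abnormal movement
#' (1 = occasional <25% of the time ... 4 = constant >75%) and its severity
#' relative to daily activities (1 = interfered less, 2 = no change,
#' 3 = interfered more). The total is the average of the 7-day mean duration
#' and the 7-day mean severity. Days missing both ratings are excluded from
#' the averages; at least one complete day is required.
#'
#' @param duration integer vector of length 7 (values 1..4, `NA` = missing day).
#' @param severity integer vector of length 7 (values 1..3, `NA` = missing day).
#' @return an `instrument_score` with `total = (mean(duration) + mean(severity)) / 2`
#'   and subscales `duration_mean` / `severity_mean`. Under this rule the
#'   arithmetic range is 1--3.5.
#' @export
#' @examples
#' score_movement_log(rep(1, 7), rep(2, 7))$total # 1.5
score_movement_log <- function(duration, severity) {
  check_length(duration, 7, "movement log (duration)")
  check_length(severity, 7, "movement log (severity)")
  check_item_range(duration, 1, 4, "movement log duration")
  check_item_range(severity, 1, 3, "movement log severity")
  ok <- !is.na(duration) & !is.na(severity)
  if (!any(ok)) {
    abort_mdri("movement log: all 7 days missing", "mdri_insufficient_data_error")
  }
  dmean <- mean(duration[ok])
  smean <- mean(severity[ok])
  new_instrument_score(
    "MOVEMENT_LOG", (dmean + smean) / 2, sum(ok),
    subscales = list(duration_mean = dmean, severity_mean = smean)
  )
}

#' The 15-item menu for the individual clinical response (ICR)
#'
#' Caregivers choose, at screening, the five symptoms most impactful to their
#' family from this menu, and rate those same five at every visit.
#'
#' @return character vector of the 15 menu items.
#' @export
icr_item_menu <- function() {
  c(
    "sleep_disturbances", "hyperactivity", "frustration_impulse_aggression",
    "feeding", "anxiety", "unhappiness", "communication", "social_deficits",
    "digestive_toileting", "pain", "illness_vulnerability", "fatigue",
    "seizure", "mobility", "gait"
  )
}

#' Score the individual clinical response (ICR)
#'
#' Five caregiver-selected items, each rated 0 (not stressful) to 4 (so
#' stressful sometimes we feel we cannot cope); the total ranges 0--20.
#'
#' @param chosen_items character vector of 5 distinct identifiers from
#'   [icr_item_menu()].
#' @param ratings integer vector of 5 values in 0..4, in the same order.
#' @return an `instrument_score` with the item set attached as attribute
#'   `items` (used for longitudinal-consistency checks).
#' @export
score_icr <- function(chosen_items, ratings) {
  check_length(chosen_items, 5, "ICR item set")
  if (anyDuplicated(chosen_items)) {
    abort_mdri("ICR: duplicate item selection", "mdri_validation_error")
  }
  bad <- setdiff(chosen_items, icr_item_menu())
  if (length(bad)) {
    abort_mdri(
      paste0("ICR: item(s) not on the 15-item menu: ", paste(bad, collapse = ", ")),
      "mdri_validation_error"
    )
  }
  check_length(ratings, 5, "ICR ratings")
  check_item_range(ratings, 0, 4, "ICR")
  if (anyNA(ratings)) {
    abort_mdri("ICR: missing rating", "mdri_missing_items_error")
  }
  out <- new_instrument_score("ICR", sum(ratings), 5L)
  attr(out, "items") <- sort(chosen_items)
  out
}

#' Vineland functional-age screening ratio
#'
#' The mean of all Vineland subdomain age equivalents divided by chronological
#' age. The trial's alternate inclusion pathway is met when functional age is
#' at most half of chronological age.
#'
#' @param age_equivalents_months positive numeric vector of subdomain
#'   age-equivalent scores, in months.
#' @param chronological_age_months positive scalar chronological age in months.
#' @param strict if `TRUE`, the flag uses a strict `< 0.5` comparison instead
#'   of the default `<= 0.5`.
#' @return list with `ratio` and logical `below_half`.
#' @export
#' @examples
#' vineland_ratio(c(24, 36, 30), 100) # ratio 0.3, below_half TRUE
vineland_ratio <- function(age_equivalents_months, chronological_age_months,
                           strict = FALSE) {
  if (!length(age_equivalents_months) ||
    any(!is.finite(age_equivalents_months)) ||
    any(age_equivalents_months <= 0)) {
    abort_mdri("Vineland: age equivalents must be positive", "mdri_validation_error")
  }
  if (!is.finite(chronological_age_months) || chronological_age_months <= 0) {
    abort_mdri("Vineland: chronological age must be positive", "mdri_validation_error")
  }
  ratio <- mean(age_equivalents_months) / chronological_age_months
  list(
    ratio = ratio,
    below_half = if (strict) ratio < 0.5 else ratio <= 0.5
  )
}

subscale_sums <- function(items, map, instrument) {
  if (is.null(map)) {
    return(NULL)
  }
  idx <- unlist(map)
  if (any(idx < 1 | idx > length(items))) {
    abort_mdri(
      sprintf("%s: subscale map indexes outside the form", instrument),
      "mdri_config_error"
    )
  }
  lapply(map, function(i) sum(items[i]))
}

#' Declared total-score range per instrument
#'
#' @param instrument_id one of [instrument_ids()].
#' @return numeric length-2 vector `c(min, max)` of the instrument's stated
#'   total range. The movement log is reported on its stated 1--7 range even
#'   though the averaging rule's arithmetic maximum is 3.5.
#' @export
instrument_range <- function(instrument_id) {
  switch(instrument_id,
    CSHQ = c(33, 99),
    SBRS = c(0, 6),
    NCCPC_R = c(0, 99),
    PROMIS_FATIGUE = c(10, 50),
    APSI = c(0, 99),
    MOVEMENT_LOG = c(1, 7),
    ICR = c(0, 20),
    abort_mdri(paste0("unknown instrument: ", instrument_id), "mdri_config_error")
  )
}
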