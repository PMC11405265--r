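# Dose-titration state machine: start at 100 mg daily, a single MCID-driven
# escalation to 200 mg at week 8 or week 16 (capped at 8 mg/kg/day), and
# lab/AE-driven de-escalation in -50 mg steps with stop, half-dose restart
# and discontinuation on recurrence.

DAYS_PER_WEEK <- 7L

#' Create a participant dose state
#'
#' Treatment starts on day 1 at 100 mg subcutaneously once daily; the dose may
#' never exceed `min(200, 8 * weight_kg)` mg/day.
#'
#' @param participant_id identifier.
#' @param weight_kg positive body weight; sets the 8 mg/kg/day cap.
#' @param start_dose_mg starting daily dose (default 100).
#' @return object of class `dose_state`.
#' @export
dose_state <- function(participant_id, weight_kg, start_dose_mg = 100) {
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    abort_mdri("weight must be positive", "mdri_validation_error")
  }
  cap <- 8 * weight_kg
  st <- structure(
    list(
      participant_id = participant_id,
      dose = min(start_dose_mg, cap),
      weight_kg = weight_kg,
      cap_mg = cap,
      on_treatment = TRUE,
      escalated = FALSE,
      escalated_week = NA_integer_,
      undecidable_weeks = integer(),
      safety_phase = "none", # none -> decreased -> stopped -> restarted -> discontinued
      decrease_day = NA_real_,
      last_admin_dose = NA_real_,
      history = data.frame(
        week = 0, kind = "START", reason = "day 1 start",
        dose_after = min(start_dose_mg, cap), stringsAsFactors = FALSE
      )
    ),
    class = "dose_state"
  )
  st
}

#' @export
print.dose_state <- function(x, ...) {
  cat(sprintf(
    "<dose state> %s: %g mg/day (cap %g), %s%s\n",
    x$participant_id, x$dose, min(200, x$cap_mg),
    if (x$on_treatment) "on treatment" else "off treatment",
    if (x$escalated) sprintf(", escalated at week %d", x$escalated_week) else ""
  ))
  invisible(x)
}

record_event <- function(state, week, kind, reason, dose_after) {
  state$history <- rbind(
    state$history,
    data.frame(
      week = week, kind = kind, reason = reason, dose_after = dose_after,
      stringsAsFactors = FALSE
    )
  )
  state$dose <- dose_after
  state
}

# Did one bothersome outcome "improve by >= the MCID"? Titration uses the
# inclusive comparison (improved iff delta <= -mcid), unlike the MDRI's
# strict one; `rule = "gt"` switches to the strict alternative. The movement
# log has no MCID at decision time: it counts as improved only when BOTH the
# duration and the severity rating decreased (the protocol escalates on
# worsening or no change in either rating).
outcome_improved <- function(change, registry, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  if (identical(change$instrument, "MOVEMENT_LOG") &&
    !is.null(change$delta_duration)) {
    dd <- change$delta_duration
    ds <- change$delta_severity
    if (is.na(dd) || is.na(ds)) {
      return(NA)
    }
    return(dd < 0 && ds < 0)
  }
  if (is.null(change$delta) || is.na(change$delta)) {
    return(NA)
  }
  mcid <- get_mcid(registry, change$instrument)
  if (rule == "ge") change$delta <= -mcid else change$delta < -mcid
}

outcome_worsened <- function(change, registry, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  if (identical(change$instrument, "MOVEMENT_LOG") &&
    !is.null(change$delta_duration)) {
    dd <- change$delta_duration
    ds <- change$delta_severity
    if (is.na(dd) || is.na(ds)) {
      return(NA)
    }
    return(dd >= 0 || ds >= 0)
  }
  if (is.null(change$delta) || is.na(change$delta)) {
    return(NA)
  }
  mcid <- get_mcid(registry, change$instrument)
  if (rule == "ge") change$delta >= mcid else change$delta > mcid
}

#' Dose-escalation decision at week 8 or week 16
#'
#' At week 8 the dose is raised from 100 to 200 mg/day (capped at 8 mg/kg) if
#' at least one of the two caregiver-selected "most bothersome" outcomes has
#' not improved by at least its MCID between day 1 and week 8. A participant
#' who improved at week 8 is re-evaluated at week 16: the dose is raised then
#' if a bothersome outcome worsened from week 8 to week 16 (by at least one
#' MCID; either outcome suffices by default).
#'
#' @param state a `dose_state`.
#' @param week 8 or 16.
#' @param changes list of two elements, one per bothersome outcome; each is
#'   `list(instrument =, delta =)` (follow-up minus reference) or, for the
#'   movement log, `list(instrument = "MOVEMENT_LOG", delta_duration =,
#'   delta_severity =)`. At week 8 the reference is day 1; at week 16 it is
#'   week 8.
#' @param registry an [mcid_registry()].
#' @param rule `"ge"` (protocol: improved by >= MCID) or `"gt"`.
#' @param week16_mode `"either"` (default: worsening of either outcome
#'   triggers escalation) or `"both"`.
#' @return updated `dose_state`. If both outcomes are unobservable at the
#'   decision visit the dose is left unchanged and the week is recorded in
#'   `undecidable_weeks` for manual review.
#' @export
escalation_decision <- function(state, week, changes, registry = mcid_registry(),
                                rule = c("ge", "gt"),
                                week16_mode = c("either", "both")) {
  rule <- match.arg(rule)
  week16_mode <- match.arg(week16_mode)
  if (!week %in% c(8, 16)) {
    abort_mdri("escalation decisions occur at week 8 or 16 only", "mdri_validation_error")
  }
  if (!state$on_treatment || state$escalated) {
    return(state)
  }
  if (length(changes) != 2) {
    abort_mdri("exactly two bothersome-outcome changes required", "mdri_validation_error")
  }

  if (week == 8) {
    improved <- vapply(changes, outcome_improved, logical(1),
      registry = registry, rule = rule
    )
    if (all(is.na(improved))) {
      state$undecidable_weeks <- c(state$undecidable_weeks, week)
      return(state)
    }
    escalate <- any(!improved, na.rm = TRUE)
  } else {
    worse <- vapply(changes, outcome_worsened, logical(1),
      registry = registry, rule = rule
    )
    if (all(is.na(worse))) {
      state$undecidable_weeks <- c(state$undecidable_weeks, week)
      return(state)
    }
    escalate <- if (week16_mode == "either") {
      any(worse, na.rm = TRUE)
    } else {
      all(worse, na.rm = TRUE) && !all(is.na(worse))
    }
  }

  if (escalate) {
    target <- min(200, state$cap_mg)
    state <- record_event(
      state, week, "ESCALATE",
      sprintf("bothersome outcome(s) not improved by >= MCID at week %d", week),
      target
    )
    state$escalated <- TRUE
    state$escalated_week <- as.integer(week)
  }
  state
}

# A lab analyte is "persistently low" at `day` when every measurement over a
# span of >= 14 days ending at the latest measurement <= day is below the
# threshold, with at least two such measurements.
lab_persistently_low <- function(labs, analyte, threshold, day,
                                 min_days = 14, min_measurements = 2) {
  l <- labs[labs$analyte == analyte & labs$day <= day, , drop = FALSE]
  if (nrow(l) < min_measurements) {
    return(FALSE)
  }
  l <- l[order(l$day), , drop = FALSE]
  below <- l$value < threshold
  if (!below[nrow(l)]) {
    return(FALSE)
  }
  # start of the trailing run of below-threshold measurements
  run_start <- max(c(0, which(!below))) + 1
  run <- l[run_start:nrow(l), , drop = FALSE]
  nrow(run) >= min_measurements && diff(range(run$day)) >= min_days
}

safety_trigger_active <- function(labs, aes, day, anc_threshold) {
  anc <- lab_persistently_low(labs, "anc", anc_threshold, day)
  plt <- lab_persistently_low(labs, "platelets", 50, day)
  ae_active <- FALSE
  if (nrow(aes)) {
    res <- ifelse(is.na(aes$resolved_day), Inf, aes$resolved_day)
    open <- aes$onset_day <= day & res > day
    hyper <- open & isTRUE_vec(aes$hypersensitivity) & aes$grade <= 2
    g3 <- open & aes$grade == 3
    ae_active <- any(hyper | g3)
  }
  anc || plt || ae_active
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Safety-driven dose adjustment
#'
#' Evaluated at any time on treatment. Triggers: absolute neutrophil count
#' below threshold (default 1,200 cells/uL; the protocol's pre-amendment
#' value of 1,500 is configurable) persistent for >= 2 weeks; platelets
#' < 50 x 10^9/L persistent for >= 2 weeks; an active mild/moderate
#' hypersensitivity reaction; or an active grade 3 adverse event. A trigger
#' causes a single -50 mg step (a step that would fall below 50 mg stops drug
#' instead). If the trigger is still present 14 days after the decrease the
#' drug is stopped; once it resolves, drug restarts at half the last
#' administered dose; recurrence after restart discontinues drug.
#'
#' @param state a `dose_state`.
#' @param labs data frame `day`, `analyte` (`"anc"` in cells/uL,
#'   `"platelets"` in 1e9/L), `value`.
#' @param aes data frame `onset_day`, `resolved_day` (`NA` = ongoing),
#'   `grade`, `hypersensitivity` (logical).
#' @param day evaluation day (integer days from day 1).
#' @param anc_threshold neutropenia threshold, cells/uL.
#' @return updated `dose_state`.
#' @export
safety_dose_adjustment <- function(state, labs, aes, day, anc_threshold = 1200) {
  if (identical(state$safety_phase, "discontinued")) {
    return(state)
  }
  week <- day / DAYS_PER_WEEK
  active <- safety_trigger_active(labs, aes, day, anc_threshold)

  if (state$safety_phase == "none") {
    if (active && state$on_treatment) {
      if (state$dose - 50 < 50) {
        state <- record_event(state, week, "STOP", "trigger at minimum dose", 0)
        state$last_admin_dose <- state$history$dose_after[nrow(state$history) - 1]
        state$on_treatment <- FALSE
        state$safety_phase <- "stopped"
      } else {
        state <- record_event(state, week, "DECREASE", "safety trigger", state$dose - 50)
        state$safety_phase <- "decreased"
        state$decrease_day <- day
      }
    }
  } else if (state$safety_phase == "decreased") {
    if (!active) {
      state$safety_phase <- "none" # resolved; a later trigger starts a new step
      state$decrease_day <- NA_real_
    } else if (day - state$decrease_day >= 14) {
      state$last_admin_dose <- state$dose
      state <- record_event(state, week, "STOP", "trigger unresolved 2 weeks after decrease", 0)
      state$on_treatment <- FALSE
      state$safety_phase <- "stopped"
    }
  } else if (state$safety_phase == "stopped") {
    if (!active) {
      restart <- 0.5 * state$last_admin_dose
      if (restart >= 50) { # below the 50 mg minimum dose there is no restart
        state <- record_event(state, week, "RESTART", "trigger resolved", restart)
        state$on_treatment <- TRUE
        state$safety_phase <- "restarted"
      }
    }
  } else if (state$safety_phase == "restarted") {
    if (active) {
      state <- record_event(state, week, "DISCONTINUE", "trigger recurred after restart", 0)
      state$on_treatment <- FALSE
      state$safety_phase <- "discontinued"
    }
  }
  state
}

#' Replay a participant's full titration history
#'
#' Deterministically replays safety evaluations (weekly from day 1 through
#' week 36 or withdrawal) and the week-8/week-16 escalation decisions in
#' chronological order.
#'
#' @param record list with `participant_id`, `weight_kg`, `changes_week8` and
#'   `changes_week16` (see [escalation_decision()]; `NULL` when the visit was
#'   not reached), `labs`, `aes` (possibly zero-row data frames), optional
#'   `withdrawal_week` (investigator/caregiver withdrawal is an input, not a
#'   computed outcome).
#' @param registry an [mcid_registry()].
#' @param anc_threshold neutropenia trigger threshold, cells/uL.
#' @param rule,week16_mode passed to [escalation_decision()].
#' @return a `dose_state` whose `history` is the full event log, plus summary
#'   fields `escalated_at_8`, `escalated_at_16`, `escalated_any`.
#' @export
run_titration <- function(record, registry = mcid_registry(),
                          anc_threshold = 1200, rule = "ge",
                          week16_mode = "either") {
  labs <- record$labs %||% data.frame(day = numeric(), analyte = character(), value = numeric())
  aes <- record$aes %||% data.frame(
    onset_day = numeric(), resolved_day = numeric(),
    grade = numeric(), hypersensitivity = logical()
  )
  wd_week <- record$withdrawal_week %||% Inf
  end_day <- min(36, wd_week) * DAYS_PER_WEEK

  state <- dose_state(record$participant_id, record$weight_kg)
  for (day in seq(7, 36 * DAYS_PER_WEEK, by = 7)) {
    if (day > end_day) break
    state <- safety_dose_adjustment(state, labs, aes, day, anc_threshold)
    wk <- day / DAYS_PER_WEEK
    # no MCID escalation while a safety trigger chain is open or after a stop
    if (wk %in% c(8, 16) && state$on_treatment && !state$escalated &&
      state$safety_phase == "none") {
      changes <- if (wk == 8) record$changes_week8 else record$changes_week16
      if (!is.null(changes)) {
        state <- escalation_decision(state, wk, changes, registry,
          rule = rule, week16_mode = week16_mode
        )
      }
    }
  }
  if (is.finite(wd_week) && wd_week <= 36 && state$on_treatment) {
    state <- record_event(state, wd_week, "DISCONTINUE", "withdrawal (input flag)", 0)
    state$on_treatment <- FALSE
  } else if (state$on_treatment) {
    state <- record_event(state, 36, "STOP", "scheduled end of treatment at week 36", 0)
    state$on_treatment <- FALSE
  }
  state$escalated_at_8 <- isTRUE(state$escalated_week == 8)
  state$escalated_at_16 <- isTRUE(state$escalated_week == 16)
  state$escalated_any <- state$escalated
  state
}
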