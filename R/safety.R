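# Adverse-event tabulation: phase classification, incidence and
# per-participant event rates in the style of a trial safety table.

#' Classify an adverse event into a treatment phase
#'
#' Events with onset inside the participant's treatment interval (closed on
#' both ends, so an event on the stop day counts as on-treatment) are
#' `ON_TREATMENT`; events after the stop are `POST_TREATMENT`. Events before
#' day 1 belong to the pre-treatment observation period and are excluded from
#' the treatment tabulation with a warning.
#'
#' @param onset_week event onset, in weeks from day 1.
#' @param start_week,stop_week the participant's treatment interval (start
#'   defaults to 0; stop is week 36 or the early-discontinuation week).
#' @return `"ON_TREATMENT"`, `"POST_TREATMENT"`, or `NA` (with a warning) for
#'   pre-treatment onsets.
#' @export
classify_ae_phase <- function(onset_week, start_week = 0, stop_week = 36) {
  out <- ifelse(
    onset_week < start_week, NA_character_,
    ifelse(onset_week <= stop_week, "ON_TREATMENT", "POST_TREATMENT")
  )
  if (anyNA(out)) {
    warning("adverse event(s) with onset before day 1 excluded from treatment tabulation")
  }
  out
}

#' Per-participant event rate
#'
#' Events divided by the population size, rounded half-up to two decimals --
#' the arithmetic used in the published safety table (e.g. 408 events among
#' 23 treated participants is 17.74).
#'
#' @param event_count non-negative integer number of events.
#' @param population_n positive population size.
#' @return the rounded rate.
#' @export
#' @examples
#' event_rate(408, 23) # 17.74
event_rate <- function(event_count, population_n) {
  if (population_n < 1) abort_mdri("population must be >= 1", "mdri_validation_error")
  if (event_count < 0) abort_mdri("event count must be >= 0", "mdri_validation_error")
  round_half_up(event_count / population_n, 2)
}

#' Incidence and event-rate table by term and phase
#'
#' Counts, per coded AE term and phase, the distinct participants affected
#' (incidence) and the total events, then derives the percent incidence and
#' the per-participant event rate. A synthetic `"any"` row aggregates all
#' terms. The published table's arithmetic divides both percents and rates by
#' the full safety population in every phase (its post-treatment "any AE" row
#' prints 15/23 = 65% and 52/23 = 2.26 even under an "n = 16" column
#' header); that is the default, with the phase-population convention for
#' percents available via `pct_denominator = "phase"`.
#'
#' @param events data frame with columns `participant_id`, `term`, `phase`
#'   (`"ON_TREATMENT"`/`"POST_TREATMENT"`), optional `serious` (logical).
#' @param population_n safety population size (all participants who received
#'   at least one dose).
#' @param phase_n optional named vector of per-phase population sizes, used
#'   only when `pct_denominator = "phase"`.
#' @param min_fraction retain terms whose incidence fraction reaches this
#'   value in at least one phase (default 0.05, the published table's
#'   threshold); the unfiltered listing is also returned.
#' @param pct_denominator `"safety"` (default) or `"phase"`.
#' @return list with `table` (filtered; columns `term`, `phase`,
#'   `incidence_n`, `incidence_pct`, `event_n`, `event_rate`), `full`
#'   (unfiltered), and `any` (the any-AE and any-SAE summary rows).
#' @export
incidence_table <- function(events, population_n, phase_n = NULL,
                            min_fraction = 0.05,
                            pct_denominator = c("safety", "phase")) {
  pct_denominator <- match.arg(pct_denominator)
  if (population_n < 1) abort_mdri("population must be >= 1", "mdri_validation_error")

  pct_n <- function(phase) {
    if (pct_denominator == "phase" && !is.null(phase_n) && phase %in% names(phase_n)) {
      phase_n[[phase]]
    } else {
      population_n
    }
  }

  summarize <- function(ev) {
    do.call(rbind, lapply(split(ev, ev$phase, drop = TRUE), function(g) {
      data.frame(
        phase = g$phase[1],
        incidence_n = length(unique(g$participant_id)),
        incidence_pct = round_half_up(
          100 * length(unique(g$participant_id)) / pct_n(g$phase[1])
        ),
        event_n = nrow(g),
        event_rate = event_rate(nrow(g), population_n)
      )
    }))
  }

  full <- do.call(rbind, lapply(split(events, events$term), function(g) {
    cbind(term = g$term[1], summarize(g))
  }))
  rownames(full) <- NULL

  keep <- vapply(split(full, full$term), function(rows) {
    any(rows$incidence_n / population_n >= min_fraction)
  }, logical(1))
  tab <- full[full$term %in% names(keep)[keep], , drop = FALSE]

  any_rows <- cbind(term = "any_ae", summarize(events))
  if (!is.null(events$serious) && any(isTRUE_vec(events$serious))) {
    any_rows <- rbind(
      any_rows,
      cbind(term = "any_sae", summarize(events[isTRUE_vec(events$serious), , drop = FALSE]))
    )
  }
  rownames(any_rows) <- NULL

  list(table = tab, full = full, any = any_rows)
}

#' Rebuild an adverse-event stream from published count summaries
#'
#' Safety tables publish, per term and phase, the number of affected
#' participants and the number of events. This utility constructs a minimal
#' event stream consistent with such counts (each affected participant gets
#' one event, and the remaining events are assigned to the first
#' participant), so that tabulation arithmetic can be recomputed from a
#' printed table alone.
#'
#' @param counts data frame with columns `term`, `phase`, `incidence_n`,
#'   `event_n`, optional `serious`.
#' @param participant_ids pool of identifiers to draw affected participants
#'   from (first `incidence_n` are used per row).
#' @return data frame `participant_id`, `term`, `phase`, `serious`.
#' @export
ae_stream_from_counts <- function(counts, participant_ids) {
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    if (r$incidence_n > length(participant_ids)) {
      abort_mdri("incidence exceeds participant pool", "mdri_validation_error")
    }
    if (r$event_n < r$incidence_n) {
      abort_mdri("events cannot be fewer than affected participants", "mdri_validation_error")
    }
    ids <- c(
      participant_ids[seq_len(r$incidence_n)],
      rep(participant_ids[1], r$event_n - r$incidence_n)
    )
    data.frame(
      participant_id = ids, term = r$term, phase = r$phase,
      serious = if ("serious" %in% names(r)) r$serious else FALSE,
      stringsAsFactors = FALSE
    )
  }))
}
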