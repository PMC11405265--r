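# MCID registry, per-instrument change classification, and the
# multi-domain responder index (MDRI).

#' Default MCID registry
#'
#' One minimal clinically important difference (MCID) per MDRI instrument, on
#' the instrument's own total-score scale. Benefit is a score decrease for all
#' six. Five MCIDs come from the literature; the movement-log MCID was derived
#' from the pre-treatment observation period of the study itself (see
#' [derive_movement_mcid()]), with 0.14 as the study's published value.
#'
#' @param overrides optional named numeric vector of replacement MCIDs.
#' @return data frame of class `mcid_registry` with columns `instrument`,
#'   `mcid`, `direction` (all `"decrease"`) and `source`.
#' @export
#' @examples
#' mcid_registry()
mcid_registry <- function(overrides = NULL) {
  reg <- data.frame(
    instrument = mdri_instruments(),
    mcid = c(3.2, 0.57, 4.6, 2.2, 0.5, 0.14),
    direction = "decrease",
    source = c(rep("literature", 5), "study-derived"),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), reg$instrument)
    if (length(bad)) {
      abort_mdri(
        paste0("MCID override for unknown instrument: ", paste(bad, collapse = ", ")),
        "mdri_config_error"
      )
    }
    reg$mcid[match(names(overrides), reg$instrument)] <- unname(overrides)
  }
  if (any(reg$mcid <= 0)) {
    abort_mdri("MCIDs must be positive", "mdri_config_error")
  }
  class(reg) <- c("mcid_registry", "data.frame")
  reg
}

get_mcid <- function(registry, instrument) {
  i <- match(instrument, registry$instrument)
  if (is.na(i)) {
    abort_mdri(paste0("no MCID registered for ", instrument), "mdri_config_error")
  }
  registry$mcid[i]
}

#' Classify change in one instrument against its MCID
#'
#' With benefit defined as a decrease and change `delta = followup - baseline`:
#' `delta < -mcid` is `IMPROVED`, `delta > mcid` is `WORSENED`, and anything
#' in between -- including a change of exactly one MCID, which the responder
#' definition leaves unassigned -- is `NO_CHANGE`, so that the three states
#' partition all observed changes. A missing score on either side is
#' `MISSING`.
#'
#' @param baseline,followup scores on the same instrument scale (`NA` allowed).
#' @param mcid positive MCID on that scale.
#' @param direction direction of benefit; only `"decrease"` is used by the
#'   trial's instruments, `"increase"` mirrors the rule.
#' @return one of `"IMPROVED"`, `"NO_CHANGE"`, `"WORSENED"`, `"MISSING"`.
#' @export
#' @examples
#' classify_change(40, 36, 3.2) # IMPROVED
#' classify_change(10, 13.2, 3.2) # NO_CHANGE: exactly one MCID
classify_change <- function(baseline, followup, mcid,
                            direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (!is.finite(mcid) || mcid <= 0) {
    abort_mdri("mcid must be a positive finite number", "mdri_validation_error")
  }
  if (is.na(baseline) || is.na(followup)) {
    return("MISSING")
  }
  if (!is.finite(baseline) || !is.finite(followup)) {
    abort_mdri("scores must be finite", "mdri_validation_error")
  }
  delta <- followup - baseline
  if (direction == "increase") delta <- -delta
  if (delta < -mcid) "IMPROVED" else if (delta > mcid) "WORSENED" else "NO_CHANGE"
}

#' Evaluate the multi-domain responder index for one participant
#'
#' Applies [classify_change()] to each of the six MDRI instruments between
#' day 1 and a follow-up week. Counts exclude `MISSING` classifications; a
#' participant with no assessable instrument is an error rather than a silent
#' zero row.
#'
#' @param baseline,followup named numeric vectors of instrument totals
#'   (names from [mdri_instruments()]; absent or `NA` entries are missing).
#' @param registry an [mcid_registry()].
#' @param participant_id,week identifiers carried into the result.
#' @return object of class `mdri_result`: list with `classifications` (named
#'   character, 6 entries), counts `n_improved`, `n_worsened`, `n_no_change`,
#'   `n_assessed`, and `any_improved`.
#' @export
evaluate_mdri <- function(baseline, followup, registry = mcid_registry(),
                          participant_id = NA_character_, week = NA_integer_) {
  cls <- vapply(mdri_instruments(), function(ins) {
    classify_change(
      baseline[ins][[1]] %na% NA_real_,
      followup[ins][[1]] %na% NA_real_,
      get_mcid(registry, ins)
    )
  }, character(1))
  n_imp <- sum(cls == "IMPROVED")
  n_wor <- sum(cls == "WORSENED")
  n_noc <- sum(cls == "NO_CHANGE")
  n_ass <- n_imp + n_wor + n_noc
  if (n_ass == 0) {
    abort_mdri(
      sprintf(
        "participant %s week %s: no assessable MDRI instrument",
        participant_id, week
      ),
      "mdri_insufficient_data_error"
    )
  }
  structure(
    list(
      participant_id = participant_id, week = week, classifications = cls,
      n_improved = n_imp, n_worsened = n_wor, n_no_change = n_noc,
      n_assessed = n_ass, any_improved = n_imp >= 1
    ),
    class = "mdri_result"
  )
}

# treat absent list element / length-0 as NA
`%na%` <- function(x, na) if (length(x) == 0 || is.null(x)) na else x

#' @export
print.mdri_result <- function(x, ...) {
  cat(sprintf(
    "<MDRI> %s week %s: %d improved / %d no change / %d worsened (of %d assessed)\n",
    x$participant_id, x$week, x$n_improved, x$n_no_change, x$n_worsened, x$n_assessed
  ))
  invisible(x)
}

#' Summarize MDRI results over a cohort
#'
#' Per-instrument fractions use, as denominator, the participants with a
#' non-missing classification for that instrument at that week; the
#' any-improved fraction uses participants with at least one assessable
#' instrument. Instruments missing for everyone are reported with `NA`
#' fractions (not assessable), never as 0%.
#'
#' @param results list of `mdri_result` objects (possibly several weeks).
#' @return list with `by_instrument` (data frame: week, instrument,
#'   n_assessed, n_improved, n_no_change, n_worsened, pct_improved,
#'   pct_no_change, pct_worsened) and `any_improved` (data frame: week, n,
#'   n_any_improved, pct_any_improved). Percents are in 0--100, unrounded.
#' @export
summarize_mdri_cohort <- function(results) {
  if (!length(results)) abort_mdri("no MDRI results supplied", "mdri_validation_error")
  weeks <- vapply(results, `[[`, numeric(1), "week")
  by_instr <- do.call(rbind, lapply(sort(unique(weeks)), function(w) {
    rs <- results[weeks == w]
    do.call(rbind, lapply(mdri_instruments(), function(ins) {
      cls <- vapply(rs, function(r) r$classifications[[ins]], character(1))
      n <- sum(cls != "MISSING")
      data.frame(
        week = w, instrument = ins, n_assessed = n,
        n_improved = sum(cls == "IMPROVED"),
        n_no_change = sum(cls == "NO_CHANGE"),
        n_worsened = sum(cls == "WORSENED"),
        pct_improved = if (n) 100 * sum(cls == "IMPROVED") / n else NA_real_,
        pct_no_change = if (n) 100 * sum(cls == "NO_CHANGE") / n else NA_real_,
        pct_worsened = if (n) 100 * sum(cls == "WORSENED") / n else NA_real_
      )
    }))
  }))
  any_imp <- do.call(rbind, lapply(sort(unique(weeks)), function(w) {
    rs <- results[weeks == w]
    ok <- vapply(rs, function(r) r$n_assessed >= 1, logical(1))
    data.frame(
      week = w, n = sum(ok),
      n_any_improved = sum(vapply(rs[ok], `[[`, logical(1), "any_improved")),
      pct_any_improved = 100 * mean(vapply(rs[ok], `[[`, logical(1), "any_improved"))
    )
  }))
  list(by_instrument = by_instr, any_improved = any_imp)
}

#' Derive the movement-log MCID from pre-treatment observation data
#'
#' The movement log is study-specific, so its MCID could not come from the
#' literature; it was instead derived from each participant's change in total
#' movement score over the 8-week pre-treatment observation period. The exact
#' published formula is not stated, so two standard distribution-based
#' candidates are offered: half the sample SD of the observation-period
#' changes (the common distribution-based MCID), or the mean absolute change.
#'
#' @param observation_changes numeric vector of per-participant changes over
#'   the observation period (`NA` dropped).
#' @param method `"half_sd"` (default) or `"mean_abs"`.
#' @return positive scalar MCID, with attributes `method` and `n`.
#' @export
#' @examples
#' derive_movement_mcid(c(0.2, -0.2, 0.3, -0.3)) # 0.5 * sd = 0.147
derive_movement_mcid <- function(observation_changes,
                                 method = c("half_sd", "mean_abs")) {
  method <- match.arg(method)
  x <- observation_changes[!is.na(observation_changes)]
  if (length(x) < 2) {
    abort_mdri("need >= 2 non-missing observation changes", "mdri_insufficient_data_error")
  }
  if (stats::sd(x) == 0) {
    abort_mdri(
      "all observation changes identical: degenerate distribution",
      "mdri_degenerate_error"
    )
  }
  val <- switch(method,
    half_sd = 0.5 * stats::sd(x),
    mean_abs = mean(abs(x))
  )
  structure(val, method = method, n = length(x))
}

#' Record a caregiver's two "most bothersome" outcomes
#'
#' At screening each caregiver selects the two outcomes most bothersome to
#' the family; the selection is immutable for the rest of the trial and
#' drives the dose-escalation decisions at weeks 8 and 16.
#'
#' @param instruments character vector of exactly two distinct identifiers.
#' @param allow_icr_items if `TRUE`, ICR menu items are also accepted.
#' @return character vector of length 2, class `bothersome_selection`.
#' @export
track_bothersome <- function(instruments, allow_icr_items = FALSE) {
  valid <- mdri_instruments()
  if (allow_icr_items) valid <- c(valid, icr_item_menu())
  if (length(instruments) != 2 || anyDuplicated(instruments)) {
    abort_mdri("exactly two distinct bothersome outcomes required", "mdri_validation_error")
  }
  bad <- setdiff(instruments, valid)
  if (length(bad)) {
    abort_mdri(
      paste0("not a selectable outcome: ", paste(bad, collapse = ", ")),
      "mdri_validation_error"
    )
  }
  structure(instruments, class = "bothersome_selection")
}
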