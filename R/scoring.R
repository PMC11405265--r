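# Score a long-format item-level visits table into one row per
# participant x visit x instrument.

#' Read a raw item-level visits CSV
#'
#' Expected columns: `participant_id`, `visit_week` (signed integer weeks
#' from day 1), `instrument`, `item_id`, `value` (empty = missing). Rows
#' failing validation are collected into a report; duplicated
#' participant x week x instrument x item keys are a hard error.
#'
#' @param path CSV file path.
#' @return data frame of typed records with attribute `"validation"` (data
#'   frame of row-level problems: `line`, `problem`).
#' @export
read_visits <- function(path) {
  raw <- utils::read.csv(path,
    colClasses = c(
      participant_id = "character", visit_week = "integer",
      instrument = "character", item_id = "character", value = "character"
    )
  )
  needed <- c("participant_id", "visit_week", "instrument", "item_id", "value")
  if (!identical(names(raw)[seq_along(needed)], needed)) {
    abort_mdri(
      paste0("visits CSV must have columns: ", paste(needed, collapse = ", ")),
      "mdri_validation_error"
    )
  }
  key <- do.call(paste, c(raw[c("participant_id", "visit_week", "instrument", "item_id")],
    sep = "\r"
  ))
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort_mdri(
      paste0(
        "duplicate participant x week x instrument x item at data line(s): ",
        paste(dup + 1, collapse = ", ")
      ),
      "mdri_validation_error"
    )
  }
  raw$value <- suppressWarnings(as.numeric(ifelse(raw$value == "", NA, raw$value)))
  report <- validate_visit_rows(raw)
  attr(raw, "validation") <- report
  raw
}

validate_visit_rows <- function(raw) {
  problems <- list()
  scale_of <- list(
    CSHQ = c(1, 3), SBRS = c(0, 6), NCCPC_R = c(0, 3),
    PROMIS_FATIGUE = c(1, 5), APSI = c(0, 5), ICR = c(0, 4)
  )
  for (ins in names(scale_of)) {
    i <- which(raw$instrument == ins & !is.na(raw$value) &
      (raw$value < scale_of[[ins]][1] | raw$value > scale_of[[ins]][2]))
    if (length(i)) {
      problems[[length(problems) + 1]] <- data.frame(
        line = i + 1,
        problem = sprintf("%s value outside item scale %g..%g", ins,
          scale_of[[ins]][1], scale_of[[ins]][2])
      )
    }
  }
  i <- which(raw$instrument == "MOVEMENT_LOG" & grepl("duration", raw$item_id) &
    !is.na(raw$value) & (raw$value < 1 | raw$value > 4))
  if (length(i)) {
    problems[[length(problems) + 1]] <-
      data.frame(line = i + 1, problem = "movement duration outside 1..4")
  }
  i <- which(raw$instrument == "MOVEMENT_LOG" & grepl("severity", raw$item_id) &
    !is.na(raw$value) & (raw$value < 1 | raw$value > 3))
  if (length(i)) {
    problems[[length(problems) + 1]] <-
      data.frame(line = i + 1, problem = "movement severity outside 1..3")
  }
  if (length(problems)) do.call(rbind, problems) else
    data.frame(line = integer(), problem = character())
}

item_sort <- function(item_id) {
  order(suppressWarnings(as.integer(gsub("\\D", "", item_id))), item_id)
}

#' Score an item-level visits table
#'
#' Dispatches each participant x visit x instrument cell to its scorer and
#' returns one scored row per cell. ICR item sets are checked for
#' longitudinal consistency: a participant whose rated ICR items change
#' across visits is an error.
#'
#' @param raw item-level data frame as from [read_visits()] (or the
#'   generator's `raw_items`).
#' @param sbrs_map SBRS structural map (default [sbrs_default_map()]).
#' @param nccpc_n,apsi_n configured form lengths.
#' @param prorate passed to the sum-scored instruments.
#' @return data frame `participant_id`, `week`, `instrument`, `total`,
#'   `duration_mean`, `severity_mean`, `n_items_used`.
#' @export
score_visits <- function(raw, sbrs_map = sbrs_default_map(),
                         nccpc_n = NULL, apsi_n = NULL, prorate = FALSE) {
  icr_sets <- list()
  cells <- unique(raw[c("participant_id", "visit_week", "instrument")])
  out <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    cell <- cells[r, ]
    rows <- raw[raw$participant_id == cell$participant_id &
      raw$visit_week == cell$visit_week &
      raw$instrument == cell$instrument, , drop = FALSE]
    rows <- rows[item_sort(rows$item_id), , drop = FALSE]
    v <- rows$value
    dm <- sm <- NA_real_
    sc <- switch(cell$instrument,
      CSHQ = score_cshq(v, prorate = prorate),
      SBRS = {
        p <- score_sbrs(v, map = sbrs_map)
        new_instrument_score("SBRS", p$total_mean, sum(!is.na(v)))
      },
      NCCPC_R = score_nccpc(v, n_items = nccpc_n %||% length(v), prorate = prorate),
      PROMIS_FATIGUE = score_promis_fatigue(v, prorate = prorate),
      APSI = score_apsi(v, n_items = apsi_n %||% length(v), prorate = prorate),
      ICR = {
        items <- rows$item_id
        prev <- icr_sets[[cell$participant_id]]
        if (!is.null(prev) && !identical(sort(items), prev)) {
          abort_mdri(
            sprintf(
              "participant %s: ICR item set changed across visits",
              cell$participant_id
            ),
            "mdri_longitudinal_consistency_error"
          )
        }
        icr_sets[[cell$participant_id]] <- sort(items)
        score_icr(items, v)
      },
      MOVEMENT_LOG = {
        dur <- rows$value[grepl("duration", rows$item_id)]
        sev <- rows$value[grepl("severity", rows$item_id)]
        s <- score_movement_log(dur, sev)
        dm <- s$subscales$duration_mean
        sm <- s$subscales$severity_mean
        s
      },
      abort_mdri(
        paste0("unknown instrument in visits table: ", cell$instrument),
        "mdri_validation_error"
      )
    )
    out[[r]] <- data.frame(
      participant_id = cell$participant_id, week = cell$visit_week,
      instrument = cell$instrument, total = sc$total,
      duration_mean = dm, severity_mean = sm,
      n_items_used = sc$n_items_used, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
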