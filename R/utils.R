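#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Fixed-decimal rounding in which a digit of exactly 5 rounds up (away from
#' zero), the convention used by most clinical-report tabulation software.
#' Base R's [round()] rounds half to even, which prints 43% where a trial
#' report prints 43% too but 22% where a report prints 22% -- the two differ on
#' exact halves, so safety tables use this helper throughout.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13
#' round_half_up(17 / 23 * 100) # 74
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon guards against values like 2.26499999 stored for 2.265
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# stop() with a classed condition so callers/tests can distinguish validation
# failures from configuration failures
abort_mdri <- function(msg, class) {
  stop(structure(
    class = c(class, "mdri_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_item_range <- function(items, lo, hi, instrument) {
  bad <- which(!is.na(items) & (items < lo | items > hi | items != floor(items)))
  if (length(bad)) {
    abort_mdri(
      sprintf(
        "%s: item(s) %s outside integer scale %d..%d",
        instrument, paste(bad, collapse = ", "), lo, hi
      ),
      "mdri_validation_error"
    )
  }
  invisible(items)
}

check_length <- function(items, n, instrument) {
  if (length(items) != n) {
    abort_mdri(
      sprintf("%s: expected %d items, got %d", instrument, n, length(items)),
      "mdri_length_error"
    )
  }
  invisible(items)
}

# sum score with explicit missing-item policy shared by CSHQ/NCCPC-R/APSI/PROMIS
sum_score <- function(items, n_items, lo, hi, instrument, prorate = FALSE) {
  check_length(items, n_items, instrument)
  check_item_range(items, lo, hi, instrument)
  miss <- is.na(items)
  if (any(miss)) {
    if (!prorate) {
      abort_mdri(
        sprintf(
          "%s: %d missing item(s); set prorate = TRUE to score from %d present items",
          instrument, sum(miss), sum(!miss)
        ),
        "mdri_missing_items_error"
      )
    }
    if (all(miss)) {
      abort_mdri(sprintf("%s: all items missing", instrument), "mdri_insufficient_data_error")
    }
    total <- mean(items[!miss]) * n_items
  } else {
    total <- sum(items)
  }
  list(total = total, n_items_used = sum(!miss))
}

new_instrument_score <- function(instrument_id, total, n_items_used,
                                 subscales = NULL) {
  structure(
    list(
      instrument_id = instrument_id, total = total,
      subscales = subscales, n_items_used = n_items_used
    ),
    class = "instrument_score"
  )
}

#' @export
print.instrument_score <- function(x, ...) {
  cat(sprintf(
    "<%s score> total = %g (%d items)\n",
    x$instrument_id, x$total, x$n_items_used
  ))
  if (!is.null(x$subscales)) {
    cat("subscales:\n")
    print(unlist(x$subscales))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
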