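# Sanfilippo Behavior Rating Scale: 68 items rated 0-6, 15 domain scales.
# Twelve domains group into four abnormality clusters (Movements, Lack of
# Fear, Social/Emotional Dysfunction, Executive Dysfunction); Orality and
# Mood/Anger/Aggression are analysed separately.

#' SBRS cluster names
#' @return character vector of the four abnormality clusters.
#' @export
sbrs_clusters <- function() {
  c(
    "Movements", "Lack of Fear", "Social/Emotional Dysfunction",
    "Executive Dysfunction"
  )
}

#' Default SBRS structural map
#'
#' The published form's exact item-to-domain assignment is proprietary and is
#' therefore configuration: real analyses must supply the licensed form's map.
#' This default is a synthetic layout used by the simulator and tests: it
#' partitions the 68 items into 15 domains with plausible sizes, assigns 12
#' domains to the four clusters (three each), and keeps Orality and
#' Mood/Anger/Aggression separate.
#'
#' @return list with elements `domains` (named list of item-index vectors,
#'   covering 1..68 exactly once), `clusters` (named list mapping each cluster
#'   to its member domains) and `separate` (character vector of the two
#'   stand-alone domains).
#' @export
sbrs_default_map <- function() {
  sizes <- c(
    stereotypic_movements = 5, restlessness = 5, chewing_mouthing = 4,
    fearlessness_danger = 4, fearlessness_heights = 4,
    social_withdrawal = 5, emotional_lability = 5, unusual_emotions = 4,
    inattention = 5, impulsivity = 5, perseveration = 4,
    defiance = 4, orality = 5, mood_anger_aggression = 5, sleep_motor_night = 4
  )
  stopifnot(sum(sizes) == 68)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  domains <- Map(seq, starts, ends)
  names(domains) <- names(sizes)
  list(
    domains = domains,
    clusters = list(
      "Movements" = c("stereotypic_movements", "restlessness", "chewing_mouthing"),
      "Lack of Fear" = c("fearlessness_danger", "fearlessness_heights", "sleep_motor_night"),
      "Social/Emotional Dysfunction" = c("social_withdrawal", "emotional_lability", "unusual_emotions"),
      "Executive Dysfunction" = c("inattention", "impulsivity", "perseveration")
    ),
    separate = c("orality", "mood_anger_aggression", "defiance")[1:2]
  )
}

validate_sbrs_map <- function(map, n_items = 68) {
  if (!all(c("domains", "clusters") %in% names(map))) {
    abort_mdri("SBRS map must define $domains and $clusters", "mdri_config_error")
  }
  idx <- sort(unlist(map$domains))
  if (!identical(as.integer(idx), seq_len(n_items))) {
    abort_mdri(
      sprintf("SBRS map must cover each of items 1..%d exactly once", n_items),
      "mdri_config_error"
    )
  }
  if (any(lengths(map$domains) == 0)) {
    abort_mdri("SBRS map has a zero-item domain", "mdri_config_error")
  }
  unknown <- setdiff(unlist(map$clusters), names(map$domains))
  if (length(unknown)) {
    abort_mdri(
      paste0("SBRS cluster references unknown domain(s): ", paste(unknown, collapse = ", ")),
      "mdri_config_error"
    )
  }
  invisible(map)
}

#' Score the Sanfilippo Behavior Rating Scale
#'
#' Each of 68 items is rated 0--6 for symptom frequency. The score of a domain
#' is the mean of its items; the score of a cluster is the mean over all items
#' of its member domains; the Total score averages the 15 domain means (an
#' item-weighted alternative is available). When a reference table is given,
#' each scale is also standardized as `(value - ref_mean) / ref_sd` against an
#' MPS III reference cohort. The MDRI consumes the raw Total mean (the scale
#' on which its MCID of 0.57 is defined), not z-scores.
#'
#' @param items integer vector of item ratings 0..6 (68 items on the
#'   published form); `NA` = missing item (excluded from its domain's mean).
#' @param map structural map as from [sbrs_default_map()]; must cover the
#'   supplied items exactly.
#' @param reference optional reference table: named list (or data frame with
#'   `scale`, `mean`, `sd`) giving reference mean and positive SD per domain,
#'   cluster and `total`.
#' @param total_method `"domain_mean"` (default: unweighted mean of the 15
#'   domain means) or `"item_mean"` (mean over all 68 items).
#' @return object of class `sbrs_profile`: list with `domain_means`,
#'   `cluster_means`, `separate` (the stand-alone domains' means),
#'   `total_mean`, and `z_scores` when a reference is supplied.
#' @export
score_sbrs <- function(items, map = sbrs_default_map(), reference = NULL,
                       total_method = c("domain_mean", "item_mean")) {
  total_method <- match.arg(total_method)
  check_item_range(items, 0, 6, "SBRS")
  validate_sbrs_map(map, n_items = length(items))

  dom_mean <- vapply(map$domains, function(i) {
    v <- items[i]
    if (all(is.na(v))) {
      abort_mdri("SBRS: a domain has no observed items", "mdri_missing_items_error")
    }
    mean(v, na.rm = TRUE)
  }, numeric(1))

  clu_mean <- vapply(map$clusters, function(doms) {
    mean(items[unlist(map$domains[doms])], na.rm = TRUE)
  }, numeric(1))

  total <- switch(total_method,
    domain_mean = mean(dom_mean),
    item_mean = mean(items, na.rm = TRUE)
  )

  z <- NULL
  if (!is.null(reference)) {
    ref <- as_sbrs_reference(reference)
    vals <- c(dom_mean, clu_mean, total = total)
    have <- intersect(names(vals), names(ref$mean))
    z <- (vals[have] - ref$mean[have]) / ref$sd[have]
  }

  structure(
    list(
      domain_means = dom_mean,
      cluster_means = clu_mean,
      separate = dom_mean[intersect(map$separate %||% character(), names(dom_mean))],
      total_mean = total,
      z_scores = z,
      total_method = total_method
    ),
    class = "sbrs_profile"
  )
}

as_sbrs_reference <- function(reference) {
  if (is.data.frame(reference)) {
    reference <- list(
      mean = stats::setNames(reference$mean, reference$scale),
      sd = stats::setNames(reference$sd, reference$scale)
    )
  }
  if (any(reference$sd <= 0)) {
    abort_mdri("SBRS reference table: all SDs must be > 0", "mdri_config_error")
  }
  reference
}

#' @export
print.sbrs_profile <- function(x, ...) {
  cat(sprintf("<SBRS profile> total mean = %.3f (%s)\n", x$total_mean, x$total_method))
  cat("cluster means:\n")
  print(round(x$cluster_means, 3))
  invisible(x)
}
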