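# Exact Wilcoxon signed-rank test (zero-drop, average ranks for ties, exact
# null by sign-pattern distribution) and Spearman rank correlation.
#
# stats::wilcox.test abandons the exact null in the presence of ties or
# zeros, which small caregiver-questionnaire change scores produce
# constantly; this implementation keeps the exact distribution in those
# cases, which is why the test is written out here rather than delegated.

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences receive average
#' ranks. For n (after zero removal) up to `exact_limit` the two-sided p-value
#' is exact, computed from the full null distribution of the positive-rank
#' sum over all 2^n sign patterns (accumulated by convolution, which
#' enumerates the same distribution without materializing every pattern);
#' otherwise a normal approximation with tie and continuity correction is
#' used.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_limit largest n for which the exact distribution is used
#'   (default 25).
#' @return list with `statistic` (positive-rank sum V), `n` (after zero
#'   removal), `p` (two-sided) and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))$p # 0.25
wilcoxon_signed_rank <- function(differences, exact_limit = 25) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort_mdri("all differences are zero: test undefined", "mdri_degenerate_error")
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])

  if (n <= exact_limit) {
    # exact null distribution of V over all sign patterns; work in units of
    # half-ranks so average ranks (x.5) stay integral
    r2 <- as.integer(round(2 * r))
    probs <- 1
    offset <- 0L # support starts at 0
    for (ri in r2) {
      new <- numeric(length(probs) + ri)
      new[seq_along(probs)] <- probs / 2
      new[seq_along(probs) + ri] <- new[seq_along(probs) + ri] + probs / 2
      probs <- new
    }
    support <- (seq_along(probs) - 1) / 2
    p_le <- sum(probs[support <= v + 1e-9])
    p_ge <- sum(probs[support >= v - 1e-9])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = v, n = n, p = p, method = method)
}

#' Spearman rank correlation
#'
#' Correlation of average ranks (handles ties), with a two-sided p-value from
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom, or by exact permutation of one variable's ranks for
#' small n.
#'
#' @param x,y numeric vectors of equal length (pairs with any `NA` dropped).
#' @param method `"t"` (default) or `"exact"` (full permutation; n <= 9).
#' @return list with `rho`, `p`, `n` and `method`.
#' @export
spearman_corr <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort_mdri("need >= 3 pairs", "mdri_insufficient_data_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_mdri("constant vector: correlation undefined", "mdri_degenerate_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)

  if (method == "exact") {
    if (n > 9) abort_mdri("exact permutation limited to n <= 9", "mdri_validation_error")
    perms <- permutations_of(seq_len(n))
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    }
  }
  list(rho = rho, p = p, n = n, method = method)
}

permutations_of <- function(v) {
  if (length(v) == 1) {
    return(matrix(v, 1))
  }
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], permutations_of(v[-i]))
  }))
}

#' Correlate immunophenotype change with MDRI response counts
#'
#' For each immune cell population, correlates the 16-week absolute change in
#' percent of the population with the number of improved (and, separately,
#' worsened) MDRI outcomes per participant, using Spearman's rank
#' correlation. A less pro-inflammatory shift (CD4+ T cells up; CD8+ T cells
#' and monocytes down) accompanying more improved outcomes is the
#' hypothesized pattern; B cells serve as a negative control.
#'
#' @param immuno data frame with columns `participant_id`, `population`
#'   (e.g. `"CD4_T"`, `"CD8_T"`, `"MONOCYTE"`, `"B_CELL"`), `change_pct`
#'   (absolute change in percent of population over 16 weeks).
#' @param mdri data frame with `participant_id`, `n_improved`, `n_worsened`.
#' @return data frame `population`, `response_definition`
#'   (`improved`/`worsened`), `rho`, `p`, `n`.
#' @export
immuno_mdri_correlation <- function(immuno, mdri) {
  m <- merge(immuno, mdri, by = "participant_id")
  do.call(rbind, lapply(split(m, m$population), function(g) {
    do.call(rbind, lapply(c("improved", "worsened"), function(def) {
      counts <- g[[paste0("n_", def)]]
      res <- tryCatch(spearman_corr(g$change_pct, counts),
        mdri_error = function(e) list(rho = NA_real_, p = NA_real_, n = nrow(g))
      )
      data.frame(
        population = g$population[1], response_definition = def,
        rho = res$rho, p = res$p, n = res$n
      )
    }))
  }))
}
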