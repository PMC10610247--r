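#' Cross-tabulate one drug against one event flag
#'
#' Builds the 2x2 contingency table for a target drug versus all other
#' drugs by the event flag: `a` = target drug with the event, `b` = target
#' drug with other events, `c` = other drugs with the event, `d` = other
#' drugs with other events. Cells partition the analysis rows exactly.
#'
#' @param analysis an analysis-unit tibble from [make_analysis_set()].
#' @param drug_name the target drug (normalized name).
#' @param event_col name of the logical event column.
#' @return list with integer `a`, `b`, `c`, `d` and `corrected = FALSE`.
#' @export
build_contingency <- function(analysis, drug_name, event_col = "is_pruritus") {
  tgt <- analysis$drug_name == drug_name
  ev <- analysis[[event_col]]
  tab <- list(a = sum(tgt & ev), b = sum(tgt & !ev),
              c = sum(!tgt & ev), d = sum(!tgt & !ev), corrected = FALSE)
  if (tab$a + tab$b == 0L) {
    warning("drug '", drug_name, "' absent from the analysis set",
            call. = FALSE)
  }
  tab
}

#' Reporting odds ratio with Haldane-Anscombe correction
#'
#' Adds 0.5 to all four cells unconditionally (the semi-correction is
#' applied to every table, not only those with zeros, so that every lnROR
#' is finite and tables remain comparable; `correct = "zeros"` restricts
#' it to tables containing a zero cell). Then
#' `ROR = (a' d') / (b' c')` and the 95% Wald interval on the log scale is
#' `exp(ln ROR +/- 1.96 sqrt(1/a' + 1/b' + 1/c' + 1/d'))`.
#'
#' All four cell arguments are vectorised.
#'
#' @param table a contingency list from [build_contingency()], or the `a`
#'   cell when `b`, `c`, `d` are given.
#' @param b,c,d remaining cells when `table` is numeric.
#' @param correct `"always"` (default) or `"zeros"`.
#' @return tibble with `ror`, `ln_ror`, `ci_low`, `ci_high`.
#' @export
compute_ror <- function(table, b = NULL, c = NULL, d = NULL,
                        correct = c("always", "zeros")) {
  correct <- match.arg(correct)
  if (is.list(table)) {
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
    already <- isTRUE(table$corrected)
  } else {
    a <- table
    already <- FALSE
  }
  if (!already) {
    add <- if (correct == "always") 0.5 else
      ifelse(a == 0 | b == 0 | c == 0 | d == 0, 0.5, 0)
    a <- a + add; b <- b + add; c <- c + add; d <- d + add
  }
  ln_ror <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble::tibble(
    ror = exp(ln_ror), ln_ror = ln_ror,
    ci_low = exp(ln_ror - 1.96 * se), ci_high = exp(ln_ror + 1.96 * se))
}

#' Two-sided Fisher exact probability for a 2x2 table
#'
#' The minimum-likelihood two-sided test: the sum of hypergeometric
#' probabilities of all outcomes no more likely than the observed one
#' (the convention of standard statistical packages). Operates on the
#' uncorrected integer cells.
#'
#' @inheritParams compute_ror
#' @return p-value in `[0, 1]` (vectorised over cells).
#' @export
fisher_p <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.list(table)) {
    a <- table$a; b <- table$b; c <- table$c; d <- table$d
  } else {
    a <- table
  }
  mapply(function(a, b, c, d) {
    stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE),
                       alternative = "two.sided")$p.value
  }, a, b, c, d, USE.NAMES = FALSE)
}

#' Per-drug ROR screen
#'
#' Computes, for every drug in the analysis set, the 2x2 cells, the
#' corrected ROR with 95% CI, the Fisher exact p-value and the volcano
#' coordinates, then applies [detect_signals()].
#'
#' @inheritParams build_contingency
#' @param min_reports minimum report count for signal flagging; drugs
#'   below it are still computed, only flagging is gated.
#' @param alpha significance level for flagging.
#' @param mode signal definition, see [detect_signals()].
#' @return tibble, one row per drug, ordered by descending `ror`.
#' @export
ror_screen <- function(analysis, event_col = "is_pruritus",
                       min_reports = 50L, alpha = 0.05,
                       mode = c("three_part", "ci_low")) {
  mode <- match.arg(mode)
  ev <- analysis[[event_col]]
  a <- tapply(ev, analysis$drug_name, sum)
  n <- tapply(ev, analysis$drug_name, length)
  drugs <- names(a)
  a <- as.integer(a); n <- as.integer(n)
  b <- n - a
  tot_ev <- sum(ev); tot <- length(ev)
  cc <- tot_ev - a
  d <- (tot - tot_ev) - b
  res <- compute_ror(a, b, cc, d)
  res <- tibble::tibble(
    drug_name = drugs, n_reports = n, a = a, b = b, c = cc, d = d,
    res,
    p_value = fisher_p(a, b, cc, d))
  res$neg_log10_p <- -log10(res$p_value)
  res$log10_n <- log10(res$n_reports)
  res <- detect_signals(res, mode = mode, alpha = alpha,
                        min_reports = min_reports)
  res[order(-res$ror, res$drug_name), ]
}

#' Flag signal drugs
#'
#' Two definitions are in circulation and both are exposed; neither is
#' silently preferred. `"three_part"` (default) flags drugs with ROR >= 1,
#' Fisher p < alpha and at least `min_reports` reports. `"ci_low"` flags
#' drugs whose lower 95% confidence bound exceeds 1 (still gated on
#' `min_reports`).
#'
#' @param results a [ror_screen()]-shaped tibble.
#' @inheritParams ror_screen
#' @return `results` with a logical `is_signal` column.
#' @export
detect_signals <- function(results, mode = c("three_part", "ci_low"),
                           alpha = 0.05, min_reports = 50L) {
  mode <- match.arg(mode)
  results$is_signal <- if (mode == "three_part") {
    results$ror >= 1 & results$p_value < alpha & results$n_reports >= min_reports
  } else {
    results$ci_low > 1 & results$n_reports >= min_reports
  }
  results
}

#' Volcano-plot data
#'
#' One row per drug with the effect coordinate (lnROR), the significance
#' coordinate (-log10 p) and the colour coordinate (log10 of the report
#' count). The conventional reference lines are attached as the
#' `reference_lines` attribute: lnROR = 0 and p = 0.05.
#'
#' @param results a [ror_screen()] tibble.
#' @param alpha significance reference level.
#' @return tibble with `drug_name`, `ln_ror`, `neg_log10_p`, `log10_n`.
#' @export
volcano_data <- function(results, alpha = 0.05) {
  out <- results[, c("drug_name", "ln_ror", "neg_log10_p", "log10_n")]
  attr(out, "reference_lines") <- list(ln_ror = 0, neg_log10_p = -log10(alpha))
  out
}
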