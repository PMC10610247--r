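#' Gender association with pruritus
#'
#' Two-sided Fisher's exact test on the 2x2 gender-by-pruritus table.
#' Cases with unknown gender are dropped before testing.
#'
#' @param cases a [case_table()] tibble.
#' @return one-row tibble: counts per group and the p-value.
#' @export
gender_association <- function(cases) {
  cases <- cases[cases$gender %in% c("male", "female"), ]
  tab <- table(factor(cases$gender, c("female", "male")),
               factor(cases$pruritus, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop("undefined test: an empty margin in the gender x pruritus table",
         call. = FALSE)
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  tibble::tibble(
    stratum = "all", variable = "gender",
    n_pruritus = sum(tab[, "TRUE"]), n_non_pruritus = sum(tab[, "FALSE"]),
    female_pruritus = tab["female", "TRUE"],
    female_non_pruritus = tab["female", "FALSE"],
    male_pruritus = tab["male", "TRUE"],
    male_non_pruritus = tab["male", "FALSE"],
    p_value = p, test = "fisher_exact")
}

#' Age/weight association with pruritus
#'
#' Two-sided Wilcoxon rank-sum test of the continuous variable between
#' pruritic and non-pruritic cases, with group means and standard
#' deviations. Missing values are removed before testing. Mid-rank tie
#' handling with the normal approximation and continuity correction is
#' used for larger samples; small untied samples are tested by exact
#' enumeration (the [stats::wilcox.test()] switching rule).
#'
#' @param cases a [case_table()] tibble.
#' @param variable `"age"` or `"weight"`.
#' @param stratum `"all"`, `"male"` or `"female"`; stratified analyses
#'   drop unknown-gender cases, the overall analysis keeps them.
#' @return one-row tibble in the demographic-summary layout.
#' @export
continuous_association <- function(cases, variable = c("age", "weight"),
                                   stratum = c("all", "male", "female")) {
  variable <- match.arg(variable)
  stratum <- match.arg(stratum)
  col <- if (variable == "age") "age_years" else "weight_kg"
  if (stratum != "all") cases <- cases[cases$gender == stratum, ]
  x <- cases[[col]][cases$pruritus]
  y <- cases[[col]][!cases$pruritus]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("undefined test: empty ", variable, " group in stratum '",
         stratum, "'", call. = FALSE)
  }
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", correct = TRUE)$p.value)
  tibble::tibble(
    stratum = stratum, variable = variable,
    n_pruritus = length(x), n_non_pruritus = length(y),
    mean_pruritus = mean(x), sd_pruritus = stats::sd(x),
    mean_non_pruritus = mean(y), sd_non_pruritus = stats::sd(y),
    p_value = p, test = "wilcoxon_rank_sum")
}

#' Bivariate demographic summary table
#'
#' Assembles the full demographic association table: the gender test plus
#' age and weight tests overall and within each gender stratum, in the
#' conventional layout (group mean +/- SD, counts, p-value per row).
#'
#' @param cases a [case_table()] tibble.
#' @return tibble, one row per (stratum, variable) analysis.
#' @export
demographic_table <- function(cases) {
  rows <- list(gender_association(cases))
  for (stratum in c("all", "male", "female")) {
    for (variable in c("age", "weight")) {
      rows <- c(rows, list(continuous_association(cases, variable, stratum)))
    }
  }
  dplyr::bind_rows(rows)
}
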