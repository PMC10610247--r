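#' The packaged pruritus preferred-term list
#'
#' The 37 MedDRA preferred terms implying itching that define "pruritus"
#' for this pipeline, together with the reported patient count for each
#' term in a large spontaneous-report tally. The list ships as data; it is
#' not regenerated from MedDRA (no license needed). Per-report matching is
#' exact after case-folding — the substring search over "itch"/"pruri..."
#' was the one-off harvesting step that produced this list, not the
#' matcher.
#'
#' @param path optional override: a TSV with columns `term` and
#'   (optionally) `patients`.
#' @return tibble with columns `term` and `patients`.
#' @export
pruritus_terms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pruritus_terms.tsv", package = "faersror",
                        mustWork = TRUE)
  }
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot("term" %in% names(out))
  if (anyDuplicated(tolower(out$term))) {
    stop("pruritus term list contains case-fold duplicates", call. = FALSE)
  }
  out
}

#' Deduplicate a report table
#'
#' Keeps at most one record per key combination. Among versions of one
#' case the highest `report_version` wins; ties are broken by the last
#' occurrence in file order. Tables without a `report_version` column are
#' deduplicated purely on file order (last wins).
#'
#' @param records a data frame.
#' @param key_columns character vector of key column names.
#' @return the deduplicated tibble, in original file order of the
#'   surviving rows.
#' @export
deduplicate <- function(records, key_columns) {
  missing_keys <- setdiff(key_columns, names(records))
  if (length(missing_keys)) {
    stop("key columns not found: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) return(tibble::as_tibble(records))
  idx <- seq_len(nrow(records))
  ver <- if ("report_version" %in% names(records)) {
    v <- records$report_version
    ifelse(is.na(v), -Inf, v)
  } else rep(0, nrow(records))
  o <- order(ver, idx)           # ascending: the last row per key wins
  key <- do.call(paste, c(lapply(records[key_columns], as.character),
                          sep = "\r"))
  keep_o <- o[!duplicated(key[o], fromLast = TRUE)]
  out <- tibble::as_tibble(records[sort(keep_o), , drop = FALSE])
  attr(out, "malformed") <- NULL  # a parse-stage diagnostic, not cohort state
  out
}

#' Merge the deduplicated source tables into a drug-event table
#'
#' Produces one row per `(case_id, drug_seq, event_pt)` for every case
#' present in the demographic table, carrying the case demographics and
#' the therapy window for that drug. Drugs of every role (suspect,
#' concomitant, interacting) are retained as candidate suspects.
#'
#' @param demo,drug,ther,reac deduplicated internal-schema tibbles from
#'   [read_faers_table()]/[normalize_faers()].
#' @return tibble with one row per (case, drug, event).
#' @export
merge_core <- function(demo, drug, ther, reac) {
  base <- dplyr::inner_join(drug, reac, by = "case_id",
                            relationship = "many-to-many")
  base <- dplyr::semi_join(base, demo, by = "case_id")
  base <- dplyr::left_join(
    base,
    demo[, intersect(c("case_id", "event_date", "gender", "age_value",
                       "age_unit", "weight_value", "weight_unit"),
                     names(demo))],
    by = "case_id")
  base <- dplyr::left_join(
    base, ther[, c("case_id", "drug_seq", "start_date", "end_date")],
    by = c("case_id", "drug_seq"))
  names(base)[names(base) == "pt"] <- "event_pt"
  base
}

#' Keep drug-event rows whose event falls inside the therapy window
#'
#' Partial dates denote their full containment interval; a row is kept iff
#' the event-date interval intersects `[start, end]`. A missing therapy
#' end is open-ended (ongoing therapy); a missing start date, a missing
#' event date, or a missing therapy record altogether excludes the row —
#' a chronological claim cannot be checked without them.
#'
#' @param joined output of [merge_core()].
#' @return the filtered tibble.
#' @export
chronological_filter <- function(joined) {
  if (nrow(joined) == 0L) return(joined)
  ev <- partial_date_bounds(joined$event_date)
  st <- partial_date_bounds(joined$start_date)
  en <- partial_date_bounds(joined$end_date)
  keep <- intervals_intersect(ev$lo, ev$hi, st$lo, en$hi)
  joined[keep, , drop = FALSE]
}

#' Remove whole cases whose indications include a pruritus term
#'
#' Reports that list a pruritus-related PT as an indication (underlying
#' disease) would contaminate the signal — the event may simply be the
#' inadequately treated disease. Removal is by whole case, not by row.
#'
#' @param table drug-event tibble.
#' @param indi deduplicated indication tibble.
#' @param terms a [pruritus_terms()] tibble (or character vector).
#' @return list with elements `table` (filtered) and `removed_case_ids`.
#' @export
exclude_indication_overlap <- function(table, indi, terms = pruritus_terms()) {
  term_set <- tolower(if (is.data.frame(terms)) terms$term else terms)
  removed <- unique(indi$case_id[tolower(indi$indication_pt) %in% term_set])
  list(table = table[!table$case_id %in% removed, , drop = FALSE],
       removed_case_ids = removed)
}

#' Flag pruritus events
#'
#' `is_pruritus` is exact case-folded membership of the event PT in the
#' packaged term list. Idempotent and order-independent.
#'
#' @inheritParams exclude_indication_overlap
#' @return the tibble with a logical `is_pruritus` column.
#' @export
label_pruritus <- function(table, terms = pruritus_terms()) {
  term_set <- tolower(if (is.data.frame(terms)) terms$term else terms)
  table$is_pruritus <- tolower(table$event_pt) %in% term_set
  table
}

#' Convert and range-check demographics
#'
#' Ages are converted to years (month/12, week/52.18, day/365.25,
#' hour/8766, decade x 10) and weights to kg (lbs x 0.453592). Values
#' outside the plausible ranges — age in `[0, 130]` years, weight in
#' `(0, 600]` kg — and values with unknown unit codes are set absent;
#' rows are never dropped.
#'
#' @param table tibble with `age_value`/`age_unit` and
#'   `weight_value`/`weight_unit` columns.
#' @return the tibble with numeric `age_years` and `weight_kg` columns.
#' @export
clean_demographics <- function(table) {
  age_factor <- c(year = 1, month = 1 / 12, week = 1 / 52.18,
                  day = 1 / 365.25, hour = 1 / 8766, decade = 10)
  f <- age_factor[table$age_unit]
  age <- table$age_value * f
  age[is.na(f) | age < 0 | age > 130] <- NA_real_
  wt_factor <- c(kg = 1, lbs = 0.453592)
  g <- wt_factor[table$weight_unit]
  wt <- table$weight_value * g
  wt[is.na(g) | wt <= 0 | wt > 600] <- NA_real_
  table$age_years <- unname(age)
  table$weight_kg <- unname(wt)
  table
}

#' Exclusion-chain audit for a cohort build
#'
#' Mirrors the flowchart of the data-table construction: raw and
#' deduplicated counts per source table, merged rows, rows surviving the
#' chronological filter ("linked reports"), pruritus share among linked
#' reports, indication-overlap removals, and the final count. The derived
#' fields are computed, never stored: `final_reports = linked_reports -
#' overlap_reports_removed` and `pruritus_share_pct` is the percentage of
#' linked reports labelled pruritus, rounded to one decimal.
#'
#' @param linked_reports rows surviving the chronological filter.
#' @param pruritus_reports linked rows labelled pruritus.
#' @param overlap_reports_removed rows removed by whole-case
#'   indication-overlap exclusion.
#' @param overlap_cases_removed number of cases removed (optional).
#' @param stage_counts optional named list of upstream per-stage counts.
#' @return object of class `cohort_audit`.
#' @export
cohort_audit <- function(linked_reports, pruritus_reports,
                         overlap_reports_removed,
                         overlap_cases_removed = NA_integer_,
                         stage_counts = list()) {
  stopifnot(linked_reports >= 0, pruritus_reports >= 0,
            pruritus_reports <= linked_reports,
            overlap_reports_removed <= linked_reports)
  structure(
    list(stage_counts = stage_counts,
         linked_reports = linked_reports,
         pruritus_reports = pruritus_reports,
         pruritus_share_pct = round(100 * pruritus_reports / linked_reports, 1),
         overlap_reports_removed = overlap_reports_removed,
         overlap_cases_removed = overlap_cases_removed,
         final_reports = linked_reports - overlap_reports_removed),
    class = "cohort_audit")
}

#' @export
print.cohort_audit <- function(x, ...) {
  cat("Cohort exclusion chain\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("  %-28s %s\n", nm, format(x$stage_counts[[nm]], big.mark = ",")))
  }
  cat(sprintf("  %-28s %s\n", "linked reports",
              format(x$linked_reports, big.mark = ",")))
  cat(sprintf("  %-28s %s (%.1f%%)\n", "of which pruritus",
              format(x$pruritus_reports, big.mark = ","), x$pruritus_share_pct))
  cat(sprintf("  %-28s %s\n", "indication-overlap removed",
              format(x$overlap_reports_removed, big.mark = ",")))
  cat(sprintf("  %-28s %s\n", "final analysis reports",
              format(x$final_reports, big.mark = ",")))
  invisible(x)
}

#' Build the analysis cohort from the five source tables
#'
#' Runs the full cleaning chain: per-table deduplication on the key
#' columns required for analysis, merge into a drug-event table,
#' chronological filtering, whole-case indication-overlap exclusion,
#' pruritus labelling, and demographic unit conversion / range checks.
#'
#' @param tables named list with internal-schema tibbles `demo`, `drug`,
#'   `reac`, `indi`, `ther` (e.g. from [read_faers_table()] or
#'   [normalize_faers()]).
#' @param terms a [pruritus_terms()] tibble.
#' @return list with `cohort` (the labelled drug-event tibble) and
#'   `audit` (a [cohort_audit()]).
#' @export
build_cohort <- function(tables, terms = pruritus_terms()) {
  stopifnot(all(c("demo", "drug", "reac", "indi", "ther") %in% names(tables)))
  raw_counts <- vapply(tables[c("demo", "drug", "reac", "indi", "ther")],
                       nrow, 1L)
  demo <- deduplicate(tables$demo, "case_id")
  drug <- deduplicate(tables$drug, c("case_id", "drug_seq"))
  reac <- deduplicate(tables$reac, c("case_id", "pt"))
  indi <- deduplicate(tables$indi, c("case_id", "drug_seq", "indication_pt"))
  ther <- deduplicate(tables$ther, c("case_id", "drug_seq"))
  merged <- merge_core(demo, drug, ther, reac)
  linked <- chronological_filter(merged)
  linked <- label_pruritus(linked, terms)
  excl <- exclude_indication_overlap(linked, indi, terms)
  cohort <- clean_demographics(excl$table)
  audit <- cohort_audit(
    linked_reports = nrow(linked),
    pruritus_reports = sum(linked$is_pruritus),
    overlap_reports_removed = nrow(linked) - nrow(excl$table),
    overlap_cases_removed = length(excl$removed_case_ids),
    stage_counts = list(
      raw_demo = raw_counts[["demo"]], raw_drug = raw_counts[["drug"]],
      raw_reac = raw_counts[["reac"]], raw_indi = raw_counts[["indi"]],
      raw_ther = raw_counts[["ther"]],
      dedup_demo = nrow(demo), dedup_drug = nrow(drug),
      dedup_reac = nrow(reac), dedup_indi = nrow(indi),
      dedup_ther = nrow(ther),
      merged_rows = nrow(merged)))
  list(cohort = cohort, audit = audit)
}

#' Collapse the cohort to an analysis unit
#'
#' The disproportionality analysis counts either one row per
#' `(case, drug)` pair, collapsed over events into a single pruritus
#' yes/no flag (`"case_drug"`, the default — one patient-drug exposure is
#' one opportunity to report pruritus), or one row per drug-event record
#' (`"drug_event"`, used for term-level profiling).
#'
#' @param cohort labelled cohort tibble from [build_cohort()].
#' @param unit `"case_drug"` or `"drug_event"`.
#' @return tibble with columns `case_id`, `drug_name`, `is_pruritus`
#'   (and `event_pt` for `"drug_event"`).
#' @export
make_analysis_set <- function(cohort, unit = c("case_drug", "drug_event")) {
  unit <- match.arg(unit)
  if (unit == "drug_event") {
    return(cohort[, c("case_id", "drug_name", "event_pt", "is_pruritus")])
  }
  dplyr::summarise(
    dplyr::group_by(cohort, .data$case_id, .data$drug_name),
    is_pruritus = any(.data$is_pruritus), .groups = "drop")
}

#' One row per case for demographic analysis
#'
#' @param cohort labelled cohort tibble (after [clean_demographics()]).
#' @return tibble with one row per case: `gender`, `age_years`,
#'   `weight_kg`, `pruritus` (any pruritus event for the case).
#' @export
case_table <- function(cohort) {
  dplyr::summarise(
    dplyr::group_by(cohort, .data$case_id),
    gender = .data$gender[1L],
    age_years = .data$age_years[1L],
    weight_kg = .data$weight_kg[1L],
    pruritus = any(.data$is_pruritus), .groups = "drop")
}
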