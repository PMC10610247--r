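demo_row <- function(case_id, version = 1L, event = "20190601",
                     gender = "female", age = 50, wt = 70) {
  tibble::tibble(case_id = case_id, report_version = version,
                 event_date = event, gender = gender,
                 age_value = age, age_unit = "year",
                 weight_value = wt, weight_unit = "kg")
}

test_that("deduplication keeps the highest version, last occurrence on ties", {
  tbl <- dplyr::bind_rows(
    demo_row("A", 1, wt = 1), demo_row("B", 1, wt = 2),
    demo_row("A", 2, wt = 3), demo_row("B", 1, wt = 4))
  out <- deduplicate(tbl, "case_id")
  expect_equal(nrow(out), 2L)
  expect_equal(out$weight_value[out$case_id == "A"], 3)  # higher version
  expect_equal(out$weight_value[out$case_id == "B"], 4)  # tie: last wins
  distinct <- dplyr::bind_rows(demo_row("A"), demo_row("B"), demo_row("C"))
  expect_equal(as.data.frame(deduplicate(distinct, "case_id")),
               as.data.frame(distinct))
  expect_error(deduplicate(distinct, "nope"), "nope")
})

test_that("synthetic duplicates leave exactly the ground-truth survivors", {
  gen <- synth_generate(synthetic_config(n_cases = 1500, seed = 8,
                                         duplicate_rate = 0.15))
  demo <- normalize_faers(gen$tables$demo, "demo")
  surv <- deduplicate(demo, "case_id")
  want_version <- ifelse(gen$truth$cases$case_id %in%
                           gen$truth$duplicates$case_id, 2L, 1L)
  got <- surv[match(gen$truth$cases$case_id, surv$case_id), ]
  expect_equal(got$report_version, want_version)
})

test_that("the merge yields the drug x reaction cross product per demo case", {
  demo <- demo_row("A")
  drug <- tibble::tibble(case_id = "A", drug_seq = 1:2,
                         drug_name = c("x", "y"),
                         role = "primary_suspect")
  reac <- tibble::tibble(case_id = c("A", "A", "A", "Z"),
                         pt = c("Pruritus", "Nausea", "Headache", "Rash"))
  ther <- tibble::tibble(case_id = "A", drug_seq = 1:2,
                         start_date = "20190501", end_date = "20190701")
  out <- merge_core(demo, drug, ther, reac)
  expect_equal(nrow(out), 6L)  # 2 drugs x 3 reactions; case Z has no demo
  expect_setequal(unique(out$event_pt), c("Pruritus", "Nausea", "Headache"))
  expect_true(all(out$start_date == "20190501"))
})

test_that("merged row count equals sum over demo cases of drugs x events", {
  gen <- synth_generate(synthetic_config(n_cases = 800, seed = 21,
                                         duplicate_rate = 0))
  tabs <- normalize_tables(gen$tables)
  merged <- merge_core(tabs$demo, tabs$drug, tabs$ther, tabs$reac)
  n_drugs <- table(gen$truth$exposures$case_id)
  n_events <- table(gen$truth$events$case_id)
  shared <- intersect(names(n_drugs), names(n_events))
  expect_equal(nrow(merged),
               sum(as.integer(n_drugs[shared]) * as.integer(n_events[shared])))
})

test_that("the chronological filter follows interval semantics", {
  base <- tibble::tibble(
    case_id = as.character(1:7), drug_seq = 1L, drug_name = "x",
    event_pt = "Pruritus",
    event_date = c("20190120", "2018", "20190120", "2019", "20190120",
                   NA, "20190120"),
    start_date = c("20190110", "20190101", "20190110", "20181201",
                   NA, "20190110", "20190125"),
    end_date   = c("20190201", "20191231", NA, "20181220", "20190201",
                   "20190201", "20190228"))
  out <- chronological_filter(base)
  # 1: event inside window; 2: disjoint years; 3: open-ended end;
  # 4: window ends before the event year; 5: no start; 6: no event date;
  # 7: event before window start
  expect_equal(out$case_id, c("1", "3"))
})

test_that("rows without a therapy record are excluded", {
  demo <- demo_row("A")
  drug <- tibble::tibble(case_id = "A", drug_seq = 1:2,
                         drug_name = c("x", "y"), role = "concomitant")
  reac <- tibble::tibble(case_id = "A", pt = "Pruritus")
  ther <- tibble::tibble(case_id = "A", drug_seq = 1L,
                         start_date = "20190501", end_date = "20190701")
  out <- chronological_filter(merge_core(demo, drug, ther, reac))
  expect_equal(out$drug_name, "x")
})

test_that("synthetic in-window fractions survive the filter exactly", {
  gen <- synth_generate(synthetic_config(n_cases = 1200, seed = 4,
                                         duplicate_rate = 0,
                                         missing_date_rate = 0,
                                         out_of_window_rate = 0.3,
                                         indication_overlap_rate = 0))
  tabs <- normalize_tables(gen$tables)
  merged <- merge_core(tabs$demo, tabs$drug, tabs$ther, tabs$reac)
  kept <- chronological_filter(merged)
  truth_rows <- dplyr::inner_join(
    gen$truth$exposures[gen$truth$exposures$in_window,
                        c("case_id", "drug_name")],
    gen$truth$events, by = "case_id", relationship = "many-to-many")
  expect_equal(nrow(kept), nrow(truth_rows))
})

test_that("indication overlap removes whole cases", {
  tbl <- tibble::tibble(case_id = c(rep("A", 5), "B"),
                        event_pt = "Nausea")
  indi <- tibble::tibble(case_id = c("A", "B"), drug_seq = 1L,
                         indication_pt = c("Pruritus", "Hypertension"))
  out <- exclude_indication_overlap(tbl, indi)
  expect_equal(out$removed_case_ids, "A")
  expect_equal(nrow(out$table), 1L)
  none <- exclude_indication_overlap(
    tbl, tibble::tibble(case_id = "A", drug_seq = 1L,
                        indication_pt = "Hypertension"))
  expect_equal(nrow(none$table), 6L)
})

test_that("the synthetic overlap rate is removed as expected", {
  rate <- 0.02
  gen <- synth_generate(synthetic_config(n_cases = 5000, seed = 31,
                                         indication_overlap_rate = rate))
  n_removed <- sum(gen$truth$cases$indication_overlap)
  se <- sqrt(rate * (1 - rate) * 5000)
  expect_lt(abs(n_removed - rate * 5000), 3 * se)
  tabs <- normalize_tables(gen$tables)
  # every flagged case with an exposure row is actually removed
  out <- exclude_indication_overlap(
    tibble::tibble(case_id = gen$truth$cases$case_id, event_pt = "x"),
    tabs$indi)
  flagged <- gen$truth$cases$case_id[gen$truth$cases$indication_overlap]
  flagged <- intersect(flagged, tabs$indi$case_id)
  expect_setequal(out$removed_case_ids, flagged)
})

test_that("pruritus labelling is exact case-folded membership and idempotent", {
  tbl <- tibble::tibble(event_pt = c("Pruritus", "Headache", "EYE PRURITUS",
                                     "pruritus genital", "Pruritic rash"))
  out <- label_pruritus(tbl)
  expect_equal(out$is_pruritus, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(label_pruritus(out), out)
  shuffled <- label_pruritus(tbl[c(3, 1, 5, 2, 4), ])
  expect_equal(shuffled$is_pruritus, out$is_pruritus[c(3, 1, 5, 2, 4)])
})

test_that("demographic units convert and outliers go absent, not dropped", {
  tbl <- tibble::tibble(
    age_value = c(24, 150, 36, 520, 2, NA),
    age_unit = c("month", "year", "year", "week", "decade", "year"),
    weight_value = c(200, 70, 700, 0, 60, 80),
    weight_unit = c("lbs", "kg", "kg", "kg", "unknown", "kg"))
  out <- clean_demographics(tbl)
  expect_equal(nrow(out), 6L)
  expect_equal(out$age_years,
               c(2, NA, 36, 520 / 52.18, 20, NA))
  expect_equal(out$weight_kg, c(90.7184, 70, NA, NA, NA, 80))
})

test_that("with all noise off the cohort equals the intended analysis set", {
  gen <- synth_generate(synthetic_config(
    n_cases = 1000, seed = 17, duplicate_rate = 0, missing_date_rate = 0,
    missing_demo_rate = 0, out_of_window_rate = 0,
    indication_overlap_rate = 0))
  built <- synth_cohort(gen)
  got <- dplyr::arrange(built$cohort[, c("case_id", "drug_name", "event_pt")],
                        case_id, drug_name, event_pt)
  want <- dplyr::arrange(gen$truth$analysis_rows, case_id, drug_name, event_pt)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("audit counts never increase along the exclusion chain", {
  gen <- synth_generate(synthetic_config(n_cases = 2000, seed = 23,
                                         indication_overlap_rate = 0.05))
  audit <- synth_cohort(gen)$audit
  expect_lte(audit$pruritus_reports, audit$linked_reports)
  expect_lte(audit$final_reports, audit$linked_reports)
  expect_equal(audit$final_reports,
               audit$linked_reports - audit$overlap_reports_removed)
  expect_lte(audit$linked_reports, audit$stage_counts$merged_rows)
  expect_lte(audit$stage_counts$dedup_demo, audit$stage_counts$raw_demo)
})
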