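#' Pipeline configuration
#'
#' Bundles the input source (synthetic config or file paths), every stage
#' parameter, and the output directory. The configuration is validated
#' before any compute and serialised as `config.json` next to the
#' outputs, so a run is reproducible from its output tree alone.
#'
#' @param out_dir output directory (created if needed).
#' @param synthetic a [synthetic_config()], or `NULL` when reading files.
#' @param input_paths named list/vector of file paths (`demo`, `drug`,
#'   `reac`, `indi`, `ther`) when `synthetic` is `NULL`.
#' @param delim field delimiter of the input files.
#' @param analysis_unit `"case_drug"` or `"drug_event"` for the signal
#'   screen.
#' @param min_reports,alpha,signal_mode signal-detection parameters, see
#'   [ror_screen()].
#' @param min_drug_reports,max_drugs,min_pt_patients,n_components,k
#'   profile-stage parameters, see [select_drugs()], [select_pts()],
#'   [ward_cluster()].
#' @param terms_path optional override for the pruritus term list.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = NULL,
                            input_paths = NULL,
                            delim = "$",
                            analysis_unit = c("case_drug", "drug_event"),
                            min_reports = 50L,
                            alpha = 0.05,
                            signal_mode = c("three_part", "ci_low"),
                            min_drug_reports = 0L,
                            max_drugs = 200L,
                            min_pt_patients = 1L,
                            n_components = 3L,
                            k = 6L,
                            terms_path = NULL) {
  analysis_unit <- match.arg(analysis_unit)
  signal_mode <- match.arg(signal_mode)
  if (is.null(synthetic) && is.null(input_paths)) {
    stop("config error: provide either a synthetic config or input paths",
         call. = FALSE)
  }
  if (!is.null(input_paths) &&
      !all(c("demo", "drug", "reac", "indi", "ther") %in% names(input_paths))) {
    stop("config error: input_paths must name demo, drug, reac, indi, ther",
         call. = FALSE)
  }
  if (!is.null(synthetic)) validate_synthetic_config(synthetic)
  stopifnot(alpha > 0, alpha < 1, min_reports >= 0, k >= 1, n_components >= 1)
  structure(
    list(out_dir = out_dir, synthetic = synthetic, input_paths = input_paths,
         delim = delim, analysis_unit = analysis_unit,
         min_reports = as.integer(min_reports), alpha = alpha,
         signal_mode = signal_mode,
         min_drug_reports = as.integer(min_drug_reports),
         max_drugs = as.integer(max_drugs),
         min_pt_patients = as.integer(min_pt_patients),
         n_components = as.integer(n_components), k = as.integer(k),
         terms_path = terms_path),
    class = "pipeline_config")
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("stale: stage '", name, "' failed at ",
                      "this point; outputs beyond it were not written"),
               file.path(out_dir, "STALE"))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — source tables, cohort, demographics,
#' signal screen, multivariate profile — writing every output table plus
#' an audit JSON with per-stage counts and the serialised configuration.
#' Identical configuration and inputs produce byte-identical output
#' trees; any stage error aborts with the stage named and a `STALE`
#' marker left in the output directory.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) a list with the cohort, audit, demographic table,
#'   signal table, profile objects and the output directory.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "STALE"))
  say <- function(...) if (!quiet) message("[faersror] ", ...)

  cfg_json <- config
  cfg_json$out_dir <- NULL  # location is not part of the analysis config
  cfg_json$synthetic <- unclass(cfg_json$synthetic)
  jsonlite::write_json(unclass(cfg_json), file.path(out_dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, na = "null",
                       force = TRUE, pretty = TRUE)

  tables <- run_stage("input", out_dir, {
    if (!is.null(config$synthetic)) {
      gen <- synth_generate(config$synthetic)
      src <- file.path(out_dir, "source")
      dir.create(src, showWarnings = FALSE)
      for (nm in names(gen$tables)) {
        write_faers_table(gen$tables[[nm]],
                          file.path(src, paste0(nm, ".txt")), delim = "$")
      }
      jsonlite::write_json(lapply(gen$truth, unclass),
                           file.path(src, "ground_truth.json"),
                           digits = NA, na = "null", dataframe = "columns",
                           force = TRUE)
      lapply(setNames(names(gen$tables), names(gen$tables)), function(nm) {
        read_faers_table(file.path(src, paste0(nm, ".txt")), nm, delim = "$")
      })
    } else {
      lapply(setNames(names(config$input_paths), names(config$input_paths)),
             function(nm) {
               read_faers_table(config$input_paths[[nm]], nm,
                                delim = config$delim)
             })
    }
  })
  say("input: ", paste(vapply(tables, nrow, 1L), collapse = "/"),
      " records (demo/drug/reac/indi/ther)")

  terms <- pruritus_terms(config$terms_path)
  built <- run_stage("cohort", out_dir, build_cohort(tables, terms))
  cohort <- built$cohort
  audit <- built$audit
  write_results(cohort, file.path(out_dir, "cohort.tsv"))
  jsonlite::write_json(unclass(audit), file.path(out_dir, "audit.json"),
                       digits = NA, auto_unbox = TRUE, na = "null",
                       pretty = TRUE)
  say("cohort: ", audit$linked_reports, " linked rows, ",
      audit$pruritus_reports, " pruritus (", audit$pruritus_share_pct,
      "%), ", audit$final_reports, " after exclusion")

  demo_tab <- run_stage("demographics", out_dir,
                        demographic_table(case_table(cohort)))
  write_results(demo_tab, file.path(out_dir, "demographics.tsv"))
  say("demographics: ", nrow(demo_tab), " association rows")

  signals <- run_stage("signals", out_dir, {
    unit <- make_analysis_set(cohort, config$analysis_unit)
    ror_screen(unit, min_reports = config$min_reports, alpha = config$alpha,
               mode = config$signal_mode)
  })
  write_results(signals, file.path(out_dir, "signals.tsv"))
  write_results(volcano_data(signals, config$alpha),
                file.path(out_dir, "volcano.tsv"))
  say("signals: ", nrow(signals), " drugs screened, ",
      sum(signals$is_signal), " flagged")

  profile <- run_stage("multivariate", out_dir, {
    de <- make_analysis_set(cohort, "drug_event")
    drugs <- select_drugs(de, config$min_drug_reports, config$max_drugs)
    counts <- pt_patient_counts(cohort[cohort$is_pruritus, ], terms)
    pts <- select_pts(counts, config$min_pt_patients)
    rm_ <- build_ror_matrix(de, drugs, pts)
    pca <- pca_covariance(rm_)
    cl <- ward_cluster(pca, config$n_components, config$k)
    list(matrix = rm_, pca = pca, clusters = cl,
         signatures = cluster_signatures(cl, pca))
  })
  vals <- profile$matrix$values
  write_results(tibble::tibble(drug_name = rownames(vals),
                               tibble::as_tibble(vals)),
                file.path(out_dir, "matrix.tsv"))
  write_results(tibble::tibble(component = seq_along(profile$pca$contributions),
                               contribution = profile$pca$contributions),
                file.path(out_dir, "pca_contributions.tsv"))
  write_results(tibble::tibble(term = rownames(profile$pca$loadings),
                               tibble::as_tibble(profile$pca$loadings)),
                file.path(out_dir, "loadings.tsv"))
  write_results(tibble::tibble(drug_name = rownames(profile$pca$scores),
                               tibble::as_tibble(profile$pca$scores)),
                file.path(out_dir, "scores.tsv"))
  write_results(tibble::tibble(drug_name = names(profile$clusters$labels),
                               cluster = unname(profile$clusters$labels)),
                file.path(out_dir, "clusters.tsv"))
  write_results(profile$signatures, file.path(out_dir, "cluster_signatures.tsv"))
  jsonlite::write_json(
    list(merge = profile$clusters$merge, height = profile$clusters$height,
         order = profile$clusters$order, k = profile$clusters$k),
    file.path(out_dir, "linkage.json"), digits = NA)
  say("multivariate: ", nrow(vals), " drugs x ", ncol(vals),
      " terms, k = ", profile$clusters$k)

  invisible(list(tables = tables, cohort = cohort, audit = audit,
                 demographics = demo_tab, signals = signals,
                 profile = profile, out_dir = out_dir))
}
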