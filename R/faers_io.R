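#' Column aliases for FAERS-style tables
#'
#' FAERS changed its table layouts over the years (the early ISR-keyed
#' archives versus the later `primaryid`-keyed ones). Rather than guessing
#' at unknown layouts, the reader maps a fixed, documented alias table onto
#' the internal schema and fails loudly when a required column is missing
#' under every alias.
#'
#' @return A tibble with columns `table_kind`, `internal` (the pipeline's
#'   column name), `alias` (an accepted header name, matched
#'   case-insensitively) and `required`.
#' @export
faers_alias_table <- function() {
  schema <- list(
    demo = list(
      case_id        = list(c("primaryid", "isr", "caseid", "case_id"), TRUE),
      report_version = list(c("caseversion", "case_version", "report_version"), FALSE),
      event_date     = list(c("event_dt", "eventdate", "event_date"), TRUE),
      gender         = list(c("sex", "gndr_cod", "gender"), FALSE),
      age_value      = list(c("age", "age_value"), FALSE),
      age_unit       = list(c("age_cod", "age_unit"), FALSE),
      weight_value   = list(c("wt", "weight", "weight_value"), FALSE),
      weight_unit    = list(c("wt_cod", "weight_unit"), FALSE)),
    drug = list(
      case_id   = list(c("primaryid", "isr", "caseid", "case_id"), TRUE),
      drug_seq  = list(c("drug_seq", "drugseq", "seq"), TRUE),
      drug_name = list(c("drugname", "drug_name"), TRUE),
      role      = list(c("role_cod", "role"), TRUE)),
    reac = list(
      case_id = list(c("primaryid", "isr", "caseid", "case_id"), TRUE),
      pt      = list(c("pt", "reac_pt", "preferred_term"), TRUE)),
    indi = list(
      case_id       = list(c("primaryid", "isr", "caseid", "case_id"), TRUE),
      drug_seq      = list(c("indi_drug_seq", "drug_seq", "drugseq"), TRUE),
      indication_pt = list(c("indi_pt", "indication_pt"), TRUE)),
    ther = list(
      case_id    = list(c("primaryid", "isr", "caseid", "case_id"), TRUE),
      drug_seq   = list(c("dsg_drug_seq", "drug_seq", "drugseq"), TRUE),
      start_date = list(c("start_dt", "start_date"), TRUE),
      end_date   = list(c("end_dt", "end_date"), FALSE))
  )
  rows <- lapply(names(schema), function(kind) {
    per <- schema[[kind]]
    tibble::tibble(
      table_kind = kind,
      internal = rep(names(per), vapply(per, function(p) length(p[[1]]), 1L)),
      alias = unlist(lapply(per, `[[`, 1L), use.names = FALSE),
      required = rep(vapply(per, function(p) p[[2]], TRUE),
                     vapply(per, function(p) length(p[[1]]), 1L)))
  })
  dplyr::bind_rows(rows)
}

faers_table_kinds <- c("demo", "drug", "reac", "indi", "ther")

#' Read a FAERS-style quarterly table
#'
#' Reads a `"$"`-delimited (or tab-delimited) ASCII table with a header
#' line, maps header names onto the internal schema through
#' [faers_alias_table()], and validates each record. Parsing is total:
#' every data line either yields one record or increments the malformed
#' counter (available as `attr(x, "malformed")`); it is never fatal.
#' Partial dates of the forms `YYYY`, `YYYYMM` and `YYYYMMDD` all parse and
#' are kept at their stated precision.
#'
#' Lines are decoded as UTF-8 with a per-line latin-1 fallback, since mixed
#' encodings are common in spontaneous-report archives.
#'
#' @param path file path.
#' @param table_kind one of `"demo"`, `"drug"`, `"reac"`, `"indi"`, `"ther"`.
#' @param delim field delimiter; `"$"` (FAERS) by default, `"\t"` also works.
#' @return A tibble of typed records in the internal schema, with an
#'   integer attribute `malformed` counting dropped data lines/records.
#' @export
read_faers_table <- function(path, table_kind = faers_table_kinds,
                             delim = "$") {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) {
    stop("I/O error: cannot read '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  bad_enc <- !validUTF8(lines)
  if (any(bad_enc)) {
    lines[bad_enc] <- iconv(lines[bad_enc], from = "latin1", to = "UTF-8")
  }
  if (length(lines) == 0L) {
    stop("schema error: '", path, "' has no header line", call. = FALSE)
  }
  header <- strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, delim, fixed = TRUE)
  nf <- lengths(parts)
  overlong <- nf > length(header)
  malformed_lines <- sum(overlong)
  parts <- parts[!overlong]
  raw <- as.data.frame(
    do.call(rbind, lapply(parts, function(p) {
      length(p) <- length(header)  # pad trailing empties
      p
    })), stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) raw <- as.data.frame(matrix(character(), 0, length(header)))
  names(raw) <- header
  raw[is.na(raw)] <- ""
  out <- normalize_faers(raw, table_kind)
  attr(out, "malformed") <- attr(out, "malformed") + malformed_lines
  out
}

#' Normalise a raw FAERS-layout table to the internal schema
#'
#' The in-memory counterpart of [read_faers_table()]: applies the column
#' alias map, coerces types, recodes gender/role/unit codes, normalises
#' drug names (trim, collapse internal whitespace, case-fold) and drops
#' records that violate the schema invariants (empty case id, unknown drug
#' role code, empty preferred term, a fully-dated therapy window with
#' start after end), counting them in the `malformed` attribute.
#'
#' @param raw a data frame whose column names are FAERS header names (any
#'   case) or already-internal names.
#' @inheritParams read_faers_table
#' @return tibble in the internal schema with attribute `malformed`.
#' @export
normalize_faers <- function(raw, table_kind = faers_table_kinds) {
  table_kind <- match.arg(table_kind)
  amap <- faers_alias_table()
  amap <- amap[amap$table_kind == table_kind, ]
  lower <- tolower(names(raw))
  cols <- list()
  for (int in unique(amap$internal)) {
    aliases <- amap$alias[amap$internal == int]
    hit <- which(lower %in% aliases)[1]
    if (is.na(hit)) {
      if (amap$required[amap$internal == int][1]) {
        stop("schema error: ", table_kind, " table is missing required column '",
             int, "' (accepted headers: ",
             paste(aliases, collapse = ", "), ")", call. = FALSE)
      }
      cols[[int]] <- rep(NA_character_, nrow(raw))
    } else {
      cols[[int]] <- as.character(raw[[hit]])
    }
  }
  df <- tibble::as_tibble(cols)
  n_in <- nrow(df)
  bad <- !nzchar(trimws(df$case_id)) | is.na(df$case_id)
  df$case_id <- trimws(df$case_id)

  if (table_kind == "demo") {
    ver <- suppressWarnings(as.integer(df$report_version))
    df$report_version <- ifelse(is.na(ver), 1L, ver)
    df$event_date <- parse_partial_date(df$event_date)
    df$gender <- recode_gender(df$gender)
    age <- suppressWarnings(as.numeric(df$age_value))
    df$age_value <- ifelse(!is.na(age) & age < 0, NA_real_, age)
    df$age_unit <- recode_unit(df$age_unit, age_unit_codes)
    wt <- suppressWarnings(as.numeric(df$weight_value))
    df$weight_value <- ifelse(!is.na(wt) & wt < 0, NA_real_, wt)
    df$weight_unit <- recode_unit(df$weight_unit, weight_unit_codes)
  } else if (table_kind == "drug") {
    df$drug_seq <- suppressWarnings(as.integer(df$drug_seq))
    df$drug_name <- normalize_drug_name(df$drug_name)
    role <- role_codes[toupper(trimws(df$role))]
    bad <- bad | is.na(df$drug_seq) | !nzchar(df$drug_name) |
      is.na(df$drug_name) | is.na(role)
    df$role <- unname(role)
  } else if (table_kind == "reac") {
    df$pt <- trimws(df$pt)
    bad <- bad | !nzchar(df$pt) | is.na(df$pt)
  } else if (table_kind == "indi") {
    df$drug_seq <- suppressWarnings(as.integer(df$drug_seq))
    df$indication_pt <- trimws(df$indication_pt)
    bad <- bad | is.na(df$drug_seq) | !nzchar(df$indication_pt) |
      is.na(df$indication_pt)
  } else if (table_kind == "ther") {
    df$drug_seq <- suppressWarnings(as.integer(df$drug_seq))
    df$start_date <- parse_partial_date(df$start_date)
    df$end_date <- parse_partial_date(df$end_date)
    full <- function(x) !is.na(x) & nchar(x) == 8L
    inverted <- full(df$start_date) & full(df$end_date) &
      df$end_date < df$start_date
    bad <- bad | is.na(df$drug_seq) | inverted
  }
  out <- df[!bad, , drop = FALSE]
  attr(out, "malformed") <- as.integer(sum(bad))
  out
}

role_codes <- c(PS = "primary_suspect", SS = "secondary_suspect",
                C = "concomitant", I = "interacting")
age_unit_codes <- c(YR = "year", MON = "month", WK = "week", DY = "day",
                    HR = "hour", DEC = "decade")
weight_unit_codes <- c(KG = "kg", KGS = "kg", LBS = "lbs", LB = "lbs")

recode_gender <- function(x) {
  x <- toupper(trimws(x))
  dplyr::case_when(x == "M" ~ "male", x == "F" ~ "female", .default = "unknown")
}

recode_unit <- function(x, codes) {
  out <- unname(codes[toupper(trimws(x))])
  out[is.na(out)] <- "unknown"
  out
}

#' Normalise a drug name
#'
#' Trim, collapse internal whitespace, case-fold. No spelling correction
#' or ingredient-dictionary lookup is attempted.
#'
#' @param x character vector.
#' @return character vector.
#' @export
normalize_drug_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Write and re-read pipeline output tables
#'
#' Every stage's output table can be persisted as TSV or JSON. The
#' round-trip `write_results()` then `read_results()` reproduces the
#' table: string columns byte-identical, numeric columns to at least 12
#' significant digits.
#'
#' @param records a data frame sharing one schema.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a tibble.
#' @export
write_results <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("I/O error: directory '", dir, "' does not exist", call. = FALSE)
  }
  if (format == "tsv") {
    readr::write_tsv(records, path, progress = FALSE)
  } else {
    jsonlite::write_json(records, path, digits = NA, na = "null",
                         auto_unbox = FALSE, dataframe = "rows")
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}

#' Write a table in the FAERS "$"-delimited layout
#'
#' Used by the synthetic generator and the pipeline to persist source
#' tables in the same ASCII dialect the reader consumes.
#'
#' @param df data frame (raw FAERS-layout columns).
#' @inheritParams read_faers_table
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(df, path, delim = "$") {
  chr <- vapply(df, function(col) {
    col <- as.character(col)
    ifelse(is.na(col), "", col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) chr <- matrix(chr, nrow = 1L, dimnames = list(NULL, names(df)))
  if (nrow(df) == 0L) {
    writeLines(paste(names(df), collapse = delim), path)
    return(invisible(path))
  }
  lines <- c(paste(names(df), collapse = delim),
             apply(chr, 1L, paste, collapse = delim))
  writeLines(lines, path)
  invisible(path)
}
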