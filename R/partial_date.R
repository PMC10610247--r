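#' Partial calendar dates
#'
#' FAERS date fields come in three precisions: `YYYY`, `YYYYMM` and
#' `YYYYMMDD`. A partial date is never imputed to a single day; it denotes
#' the full interval of days it could be (a bare year means Jan 1 through
#' Dec 31). All chronological comparisons in the pipeline use these
#' containment intervals.
#'
#' `parse_partial_date()` normalises a character vector of date strings to
#' canonical digit strings (`NA` for blank or unparseable input, or a year
#' outside 1900-2100). `partial_date_bounds()` maps a vector of canonical
#' strings to the first and last [Date] each could denote.
#'
#' @param x character vector of date strings.
#' @return `parse_partial_date()`: a character vector of canonical
#'   `YYYY[MM[DD]]` strings with `NA` where unparseable.
#'   `partial_date_bounds()`: a tibble with `lo` and `hi` [Date] columns.
#' @examples
#' parse_partial_date(c("2019", "201906", "20190615", "", "junk"))
#' partial_date_bounds(c("2019", "201906", "20190615"))
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA")] <- NA_character_
  ok <- !is.na(x) & grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)
  out <- ifelse(ok, x, NA_character_)
  yr <- suppressWarnings(as.integer(substr(out, 1L, 4L)))
  out[!is.na(yr) & (yr < 1900L | yr > 2100L)] <- NA_character_
  # month/day zero (e.g. "20190600") trims to the coarser precision
  mo <- substr(out, 5L, 6L)
  out[!is.na(out) & nchar(out) >= 6L & mo == "00"] <- substr(
    out[!is.na(out) & nchar(out) >= 6L & mo == "00"], 1L, 4L)
  dy <- substr(out, 7L, 8L)
  out[!is.na(out) & nchar(out) == 8L & dy == "00"] <- substr(
    out[!is.na(out) & nchar(out) == 8L & dy == "00"], 1L, 6L)
  out
}

#' @rdname parse_partial_date
#' @export
partial_date_bounds <- function(x) {
  x <- parse_partial_date(x)
  n <- nchar(x)
  y <- substr(x, 1L, 4L)
  m <- ifelse(!is.na(n) & n >= 6L, substr(x, 5L, 6L), NA_character_)
  d <- ifelse(!is.na(n) & n == 8L, substr(x, 7L, 8L), NA_character_)

  lo <- as.Date(
    paste(y, ifelse(is.na(m), "01", m), ifelse(is.na(d), "01", d), sep = "-"),
    format = "%Y-%m-%d")
  # hi: stated day; else last day of stated month; else Dec 31
  hi_str <- ifelse(
    is.na(x), NA_character_,
    ifelse(!is.na(d), paste(y, m, d, sep = "-"),
      ifelse(!is.na(m), NA_character_, paste0(y, "-12-31"))))
  hi <- as.Date(hi_str, format = "%Y-%m-%d")
  month_only <- !is.na(x) & is.na(d) & !is.na(m)
  if (any(month_only)) {
    first <- as.Date(paste(y[month_only], m[month_only], "01", sep = "-"),
                     format = "%Y-%m-%d")
    hi[month_only] <- next_month_start(first) - 1L
  }
  # invalid concrete dates (e.g. Feb 30) collapse to NA throughout
  bad <- is.na(lo) & !is.na(x)
  lo[bad] <- NA
  hi[bad] <- NA
  tibble::tibble(lo = lo, hi = hi)
}

next_month_start <- function(d) {
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  y <- y + (m == 12L)
  m <- ifelse(m == 12L, 1L, m + 1L)
  as.Date(sprintf("%04d-%02d-01", y, m))
}

#' Do two partial-date intervals intersect?
#'
#' Vectorised interval intersection used by the chronological filter. An
#' `NA` left endpoint on either side yields `FALSE` (an undated event or an
#' undated therapy start cannot be placed in time); an `NA` therapy end is
#' open-ended.
#'
#' @param ev_lo,ev_hi event-date interval bounds ([Date]).
#' @param th_lo,th_hi therapy-window interval bounds ([Date]); `th_hi` may
#'   be `NA` for ongoing therapy.
#' @return logical vector.
#' @keywords internal
intervals_intersect <- function(ev_lo, ev_hi, th_lo, th_hi) {
  open_end <- is.na(th_hi)
  ok <- !is.na(ev_lo) & !is.na(th_lo)
  ok & (ev_hi >= th_lo) & (open_end | ev_lo <= th_hi)
}
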