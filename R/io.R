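read_csv_checked <- function(path, what) {
  if (!is.character(path) || length(path) != 1L)
    stop_io("%s path must be a single file path", what)
  if (!file.exists(path))
    stop_io("%s file not found: %s", what, path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  blank.lines.skip = TRUE)
}

#' Read a case table from CSV
#'
#' Expects columns `year`, `stage`, `cases`, and optionally `band` and
#' `year_total`. When a `year_total` column is present its (per-year constant)
#' value is stored as the explicit total and takes precedence over the
#' stage-cell sum. Lines starting with `#` are ignored, so files written by
#' [render_tables()] re-load directly.
#'
#' @param path CSV file path.
#' @param scenario optional scenario name to record.
#' @return a [case_table()].
#' @export
read_case_table <- function(path, scenario = NULL) {
  df <- read_csv_checked(path, "case table")
  if (!nrow(df))
    return(case_table(data.frame(year = integer(), stage = character(),
                                 cases = numeric())))
  if ("cases_raw" %in% names(df)) df$cases <- df$cases_raw
  yt <- NULL
  if ("year_total" %in% names(df)) {
    tot <- df$year_total[!is.na(df$year_total)]
    yrs <- df$year[!is.na(df$year_total)]
    if (length(tot)) {
      per_year <- tapply(tot, yrs, unique, simplify = FALSE)
      if (any(lengths(per_year) > 1L))
        stop_validation("year_total column must be constant within each year")
      yt <- stats::setNames(vapply(per_year, `[[`, numeric(1), 1L), names(per_year))
      if (!setequal(names(yt), unique(as.character(df$year))))
        stop_validation("year_total must be given for every year or none")
    }
  }
  if (all(is.na(df$stage)) || all(df$stage == "")) {
    return(case_table_totals(df$year, df$cases, scenario = scenario))
  }
  case_table(df[c("year", "stage", "cases", intersect("band", names(df)))],
             year_totals = yt, scenario = scenario)
}

#' Write a case table to CSV
#'
#' By default values are written unrounded, so `read_case_table()` of the
#' output reproduces the table (round-trip identity). A display rounding mode
#' may be requested instead; the unrounded values can then be preserved in a
#' parallel `cases_raw` column.
#'
#' @param table a [case_table()].
#' @param path output CSV path.
#' @param rounding `"none"` (default) or a mode accepted by [round_display()].
#' @param keep_unrounded when rounding, also write the raw values in a
#'   `cases_raw` column.
#' @return the path, invisibly.
#' @export
write_case_table <- function(table, path, rounding = "none", keep_unrounded = FALSE) {
  stopifnot(inherits(table, "case_table"))
  df <- as.data.frame(table)
  yt <- year_totals(table)
  df$year_total <- if (length(yt)) unname(yt[as.character(df$year)]) else numeric(0)
  if (!identical(rounding, "none")) {
    raw <- df$cases
    df$cases <- round_display(df$cases, mode = rounding)
    df$year_total <- round_display(df$year_total, mode = rounding)
    if (keep_unrounded) df$cases_raw <- raw
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io("cannot write case table to %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Workforce headcount series
#'
#' Registered-practitioner headcounts by profession, year and (optionally)
#' remoteness band. Headcounts are persons registered at a primary location,
#' not full-time equivalents. An optional logical `uncertain` column flags
#' cells whose source could not be transcribed unambiguously.
#'
#' @param df data.frame with columns `profession`, `year`, `headcount`, and
#'   optionally `band` and `uncertain`.
#' @return a `workforce_series` (classed data.frame).
#' @export
workforce_series <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("profession", "year", "headcount")
  if (!all(required %in% names(df)))
    stop_validation("workforce series needs columns %s", paste(required, collapse = ", "))
  if (!"band" %in% names(df)) df$band <- NA_character_
  if (!"uncertain" %in% names(df)) df$uncertain <- FALSE
  out <- data.frame(profession = as.character(df$profession),
                    year       = as.integer(df$year),
                    band       = as.character(df$band),
                    headcount  = as.numeric(df$headcount),
                    uncertain  = as.logical(df$uncertain),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(!is.finite(out$headcount)) || any(out$headcount < 0))
      stop_validation("headcounts must be finite and non-negative")
    if (any(!is_wholenumber(out$headcount)))
      stop_validation("headcounts must be integer-valued (persons)")
    bad_band <- !is.na(out$band) & !out$band %in% mm_bands()
    if (any(bad_band))
      stop_validation("unknown remoteness band(s): %s",
                      paste(unique(out$band[bad_band]), collapse = ", "))
    key <- paste(out$profession, out$year, out$band, sep = "\r")
    if (anyDuplicated(key))
      stop_validation("duplicate (profession, year, band) headcounts")
  }
  rownames(out) <- NULL
  structure(out, class = c("workforce_series", "data.frame"))
}

#' @rdname workforce_series
#' @param path CSV path with the columns described above.
#' @export
read_workforce_series <- function(path) {
  workforce_series(read_csv_checked(path, "workforce"))
}

#' @rdname workforce_series
#' @param series a `workforce_series`.
#' @export
write_workforce_series <- function(series, path) {
  stopifnot(inherits(series, "workforce_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.workforce_series <- function(x, ...) {
  cat(sprintf("Workforce series: %d professions, years %s\n",
              length(unique(x$profession)),
              if (nrow(x)) paste(range(x$year), collapse = "-") else "none"))
  if (nrow(x) && all(is.na(x$band))) {
    w <- stats::reshape(as.data.frame(x)[c("profession", "year", "headcount")],
                        idvar = "year", timevar = "profession", direction = "wide")
    names(w) <- sub("^headcount\\.", "", names(w))
    print(w, row.names = FALSE)
  } else if (nrow(x)) {
    print(as.data.frame(x))
  }
  invisible(x)
}

#' Read a key/value shares file
#'
#' Reads `shares.csv` (columns `key`, `value`) into a named numeric vector.
#' Keys use the dotted form `stage.<label>`, `survival.<label>` and
#' `remoteness.<band>`.
#'
#' @param path CSV path.
#' @return named numeric vector.
#' @export
read_shares <- function(path) {
  df <- read_csv_checked(path, "shares")
  if (!all(c("key", "value") %in% names(df)))
    stop_validation("shares file needs columns key, value")
  stats::setNames(as.numeric(df$value), as.character(df$key))
}

shares_subset <- function(shares, prefix, labels) {
  keys <- paste0(prefix, ".", labels)
  if (!all(keys %in% names(shares))) return(NULL)
  stats::setNames(unname(shares[keys]), labels)
}
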