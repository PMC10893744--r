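#' Case tables
#'
#' A `case_table` holds expected new-case counts indexed by calendar year,
#' diagnostic stage and (optionally) remoteness band. Counts are real-valued
#' internally; they are only rounded when rendered (see [round_display()]).
#' Each year carries a stored total. Totals are usually the stage-cell sum,
#' but published tables round from non-integer internals, so an explicit
#' total may be supplied and then takes precedence over the cell sum (a small
#' discrepancy, at most half a case per stage cell, is tolerated).
#'
#' @param cells data.frame with columns `year`, `stage`, `cases` and
#'   optionally `band`. `stage` must use [pc_stages()] labels; `band`, when
#'   present, [mm_bands()] labels (NA for statewide rows).
#' @param year_totals optional named numeric of explicit per-year totals
#'   (names are years). When omitted, totals are the per-year cell sums.
#' @param scenario optional scenario name recorded as metadata.
#' @param totals_tol maximum tolerated absolute gap between an explicit year
#'   total and its stage-cell sum; defaults to 1.5 (three stage cells rounded
#'   by at most half a case each).
#' @return a `case_table` (a data.frame with attributes `year_totals`,
#'   `explicit_totals`, `band_totals`, `scenario`).
#' @seealso [case_table_totals()] for year totals with stages unassigned,
#'   [read_case_table()] and [write_case_table()] for CSV I/O.
#' @export
case_table <- function(cells, year_totals = NULL, scenario = NULL, totals_tol = 1.5) {
  stopifnot(is.data.frame(cells))
  required <- c("year", "stage", "cases")
  if (!all(required %in% names(cells)))
    stop_validation("case table needs columns %s", paste(required, collapse = ", "))
  if (!"band" %in% names(cells)) cells$band <- rep(NA_character_, nrow(cells))

  cells <- data.frame(year  = as.integer(cells$year),
                      stage = as.character(cells$stage),
                      band  = as.character(cells$band),
                      cases = as.numeric(cells$cases),
                      stringsAsFactors = FALSE)

  if (nrow(cells)) {
    if (any(!is.finite(cells$cases)) || any(cells$cases < 0))
      stop_validation("case counts must be finite and non-negative")
    bad_stage <- !is.na(cells$stage) & !cells$stage %in% pc_stages()
    if (any(bad_stage))
      stop_validation("unknown stage label(s): %s",
                      paste(unique(cells$stage[bad_stage]), collapse = ", "))
    if (anyNA(cells$stage) && !all(is.na(cells$stage)))
      stop_validation("stage must be either assigned for all rows or for none (totals-only)")
    bad_band <- !is.na(cells$band) & !cells$band %in% mm_bands()
    if (any(bad_band))
      stop_validation("unknown remoteness band(s): %s",
                      paste(unique(cells$band[bad_band]), collapse = ", "))
    key <- paste(cells$year, cells$stage, cells$band, sep = "\r")
    if (anyDuplicated(key))
      stop_validation("duplicate (year, stage, band) cells")
    yrs <- sort(unique(cells$year))
    if (length(yrs) > 1L && !all(diff(yrs) == 1L))
      stop_validation("years must be consecutive (got %s)", paste(yrs, collapse = ", "))
    ord <- order(cells$year,
                 match(cells$stage, pc_stages()),
                 match(cells$band, mm_bands()))
    cells <- cells[ord, , drop = FALSE]
    rownames(cells) <- NULL
  }

  cell_sums <- if (nrow(cells)) {
    vapply(split(cells$cases, cells$year), sum, numeric(1))
  } else numeric(0)

  explicit <- !is.null(year_totals)
  if (explicit) {
    year_totals <- stats::setNames(as.numeric(year_totals), names(year_totals))
    if (is.null(names(year_totals)))
      stop_validation("explicit year totals must be named by year")
    if (nrow(cells) && !setequal(names(year_totals), names(cell_sums)))
      stop_validation("explicit year totals must cover exactly the years present")
    if (any(!is.finite(year_totals)) || any(year_totals < 0))
      stop_validation("year totals must be finite and non-negative")
    if (nrow(cells) && !all(is.na(cells$stage))) {
      gap <- abs(year_totals[names(cell_sums)] - cell_sums)
      if (any(gap > totals_tol + 1e-6))
        stop_validation("explicit total differs from stage-cell sum by more than %.2f in year(s) %s",
                        totals_tol,
                        paste(names(cell_sums)[gap > totals_tol + 1e-6], collapse = ", "))
    }
    year_totals <- year_totals[order(as.integer(names(year_totals)))]
  } else {
    year_totals <- cell_sums
  }

  band_totals <- NULL
  if (nrow(cells) && any(!is.na(cells$band))) {
    # implicit band totals; allocate_by_remoteness() overrides these with
    # share * year-total so explicit totals propagate into bands
    agg <- stats::aggregate(cases ~ year + band, data = cells, FUN = sum)
    names(agg)[names(agg) == "cases"] <- "total"
    band_totals <- agg
  }

  structure(cells,
            year_totals     = year_totals,
            explicit_totals = explicit,
            band_totals     = band_totals,
            scenario        = scenario,
            class           = c("case_table", "data.frame"))
}

#' Year totals with stages unassigned
#'
#' Builds a totals-only [case_table()], the output shape of
#' [project_incidence()] and the input shape of [apply_stage_distribution()].
#'
#' @param years integer vector of consecutive calendar years.
#' @param totals expected new cases per year (real-valued).
#' @inheritParams case_table
#' @export
case_table_totals <- function(years, totals, scenario = NULL) {
  if (length(years) != length(totals))
    stop_validation("years and totals must have equal length")
  case_table(data.frame(year = as.integer(years), stage = NA_character_,
                        cases = as.numeric(totals)),
             year_totals = stats::setNames(totals, years),
             scenario = scenario)
}

#' @rdname case_table
#' @param x a `case_table`.
#' @export
year_totals <- function(x) {
  stopifnot(inherits(x, "case_table"))
  attr(x, "year_totals")
}

#' @rdname case_table
#' @export
case_years <- function(x) as.integer(names(year_totals(x)))

#' @rdname case_table
#' @export
is_stratified <- function(x) {
  stopifnot(inherits(x, "case_table"))
  nrow(x) > 0L && any(!is.na(x$band))
}

#' @rdname case_table
#' @export
is_totals_only <- function(x) {
  stopifnot(inherits(x, "case_table"))
  nrow(x) > 0L && all(is.na(x$stage))
}

band_totals <- function(x) attr(x, "band_totals")

scenario_name <- function(x) attr(x, "scenario")

# named stage-cell vector for one year (optionally one band)
stage_cells <- function(x, year, band = NULL) {
  rows <- x$year == year &
    (if (is.null(band)) is.na(x$band) else !is.na(x$band) & x$band == band)
  out <- stats::setNames(rep(NA_real_, 3L), pc_stages())
  out[x$stage[rows]] <- x$cases[rows]
  out
}

# years x stages matrix, statewide view (sums over bands when stratified)
case_matrix <- function(x) {
  yrs <- case_years(x)
  m <- matrix(0, nrow = length(yrs), ncol = 3L,
              dimnames = list(yrs, pc_stages()))
  if (nrow(x) && !all(is.na(x$stage))) {
    agg <- stats::aggregate(cases ~ year + stage, data = as.data.frame(x), FUN = sum)
    m[cbind(as.character(agg$year), agg$stage)] <- agg$cases
  }
  m
}

#' @export
print.case_table <- function(x, digits = 1, ...) {
  sc <- scenario_name(x)
  cat("Case table", if (!is.null(sc)) sprintf("[scenario: %s]", sc), "\n")
  if (!nrow(x)) {
    cat("  (empty)\n")
    return(invisible(x))
  }
  if (is_totals_only(x)) {
    cat("  Year totals (stages unassigned):\n")
    print(round(year_totals(x), digits))
    return(invisible(x))
  }
  m <- case_matrix(x)
  m <- cbind(m, Total = year_totals(x)[rownames(m)])
  print(round(m, digits))
  if (is_stratified(x))
    cat(sprintf("  (stratified over %d remoteness bands; statewide sums shown)\n",
                length(unique(x$band[!is.na(x$band)]))))
  invisible(x)
}
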