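#' Fit a supply growth trend for one profession
#'
#' Log-linear least squares on a profession's statewide headcount series,
#' mirroring [fit_incidence_trend()]. Published projected headcounts can
#' instead be passed through unchanged ("fixture mode"); the fitter exists
#' for synthetic or registry-style inputs.
#'
#' @param series a [workforce_series()].
#' @param profession profession label present in `series`.
#' @return a `growth_trend` (see [fit_incidence_trend()]) with the profession
#'   recorded as an attribute.
#' @export
fit_supply_trend <- function(series, profession) {
  stopifnot(inherits(series, "workforce_series"))
  rows <- series$profession == profession & is.na(series$band)
  if (!any(rows))
    stop_validation("profession '%s' not present in the workforce series", profession)
  df <- data.frame(year = series$year[rows], count = series$headcount[rows])
  trend <- fit_incidence_trend(df)
  attr(trend, "profession") <- profession
  trend
}

#' Project headcounts over a horizon
#'
#' Evaluates a fitted supply trend as `base * growth^(year - base_year)`.
#'
#' @param trend a `growth_trend` from [fit_supply_trend()].
#' @param horizon integer vector of years after the base (reference) year.
#' @return a [workforce_series()] with real-valued projections stored rounded
#'   to whole persons.
#' @export
project_supply <- function(trend, horizon) {
  stopifnot(inherits(trend, "growth_trend"))
  horizon <- as.integer(horizon)
  if (any(horizon <= trend$reference_year))
    stop_validation("supply horizon must start after the base year %d", trend$reference_year)
  workforce_series(data.frame(
    profession = attr(trend, "profession") %||% "profession",
    year = horizon,
    headcount = round_display(unname(predict(trend, horizon)))
  ))
}

#' Demand versus supply by profession, remoteness band and year
#'
#' Joins band-stratified case demand with band-stratified headcounts and
#' reports cases per registered specialist. A cell is flagged as a shortage
#' exactly when there is demand but no registered supply; such cells carry no
#' numeric ratio and are summarised in the `travel_necessity` attribute (care
#' requires patient or clinician travel). No conversion from cases to
#' appointments or procedures is attempted: the metric is descriptive.
#'
#' When the supply snapshot covers a single year (a current-workforce
#' snapshot), it is applied to every demand year.
#'
#' @param demand a band-stratified [case_table()]; each (year, band) demand is
#'   the sum of its stage cells.
#' @param supply a [workforce_series()] with band-level rows for the listed
#'   professions.
#' @param professions professions to report; default all in `supply`.
#' @return a `gap_report`: data.frame with `profession`, `band`, `year`,
#'   `demand`, `supply`, `cases_per_specialist` (NA where supply is zero) and
#'   `shortage`, with attribute `travel_necessity`.
#' @export
compute_gap <- function(demand, supply, professions = NULL) {
  stopifnot(inherits(demand, "case_table"), inherits(supply, "workforce_series"))
  if (!is_stratified(demand))
    stop_validation("demand must be stratified by remoteness band")
  sup <- as.data.frame(supply)
  sup <- sup[!is.na(sup$band), , drop = FALSE]
  if (is.null(professions)) professions <- unique(sup$profession)
  missing_prof <- setdiff(professions, sup$profession)
  if (length(missing_prof))
    stop_validation("profession(s) absent from band-level supply: %s",
                    paste(missing_prof, collapse = ", "))
  dem <- stats::aggregate(cases ~ year + band, data = as.data.frame(demand), FUN = sum)
  sup_years <- sort(unique(sup$year))
  rows <- do.call(rbind, lapply(professions, function(p) {
    sp <- sup[sup$profession == p, , drop = FALSE]
    out <- dem
    out$profession <- p
    out$supply <- vapply(seq_len(nrow(out)), function(i) {
      yr <- if (length(sup_years) == 1L) sup_years else out$year[i]
      hit <- sp$year == yr & sp$band == out$band[i]
      if (!any(hit)) NA_real_ else sp$headcount[which(hit)[1L]]
    }, numeric(1))
    out
  }))
  if (anyNA(rows$supply))
    stop_validation("band-level supply missing for some (profession, band, year) cells")
  names(rows)[names(rows) == "cases"] <- "demand"
  rows$cases_per_specialist <- ifelse(rows$supply > 0, rows$demand / rows$supply, NA_real_)
  rows$shortage <- rows$supply == 0 & rows$demand > 0
  rows <- rows[order(rows$profession, match(rows$band, mm_bands()), rows$year),
               c("profession", "band", "year", "demand", "supply",
                 "cases_per_specialist", "shortage")]
  rownames(rows) <- NULL
  travel <- unique(rows[rows$shortage, c("profession", "band")])
  rownames(travel) <- NULL
  structure(rows, travel_necessity = travel,
            class = c("gap_report", "data.frame"))
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Demand per registered specialist (headcount, primary registration location)\n")
  df <- as.data.frame(x)
  df$demand <- round(df$demand, 1)
  df$cases_per_specialist <- round(df$cases_per_specialist, 3)
  print(df, row.names = FALSE)
  tn <- attr(x, "travel_necessity")
  if (nrow(tn)) {
    cat("\nNo registered supply despite demand (travel required):\n")
    print(tn, row.names = FALSE)
  }
  invisible(x)
}
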