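#' Registry incidence history
#'
#' Observed annual new-case counts from a cancer registry.
#'
#' @param years consecutive calendar years.
#' @param counts non-negative integer counts (cases/year).
#' @param region label for the covered region.
#' @return an `incidence_history` (classed data.frame).
#' @export
incidence_history <- function(years, counts, region = "Victoria") {
  years <- as.integer(years)
  if (length(years) != length(counts))
    stop_validation("years and counts must have equal length")
  if (length(years) > 1L && !all(diff(sort(years)) == 1L))
    stop_validation("history years must be consecutive")
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) || any(!is_wholenumber(counts)))
    stop_validation("counts must be non-negative integers")
  structure(data.frame(year = years, count = counts)[order(years), ],
            region = region,
            class = c("incidence_history", "data.frame"))
}

#' Fit a log-linear growth trend
#'
#' Fits least squares of log counts on calendar year, the projection model
#' used for both incidence and workforce series: counts are assumed to grow
#' by a constant multiplicative factor per year. When any count is zero a
#' small offset (default 0.5) is added inside the log so the fit is defined;
#' on all-positive data no offset is applied, so an exactly geometric series
#' is recovered exactly.
#'
#' @param history an [incidence_history()], or any data.frame with columns
#'   `year` and `count`.
#' @param offset value added to counts before taking logs. The default `NULL`
#'   means 0 when all counts are positive, 0.5 otherwise.
#' @return a `growth_trend` object: list with `intercept` (log level at the
#'   reference year, the last observed year), `slope` (log growth per year),
#'   `growth` (`exp(slope)`), `reference_year`, `sigma2` (residual variance),
#'   `n`, and the underlying `lm` fit.
#' @examples
#' h <- incidence_history(2010:2021, round(900 * 1.025^(0:11)))
#' fit_incidence_trend(h)
#' @export
fit_incidence_trend <- function(history, offset = NULL) {
  if (!is.data.frame(history) || !all(c("year", "count") %in% names(history)))
    stop_validation("history must have columns year and count")
  year <- as.numeric(history$year)
  count <- as.numeric(history$count)
  if (length(year) < 3L)
    stop_validation("need at least 3 years of history to fit a trend (got %d)",
                    length(year))
  if (all(count == 0))
    stop_validation("degenerate fit: all counts are zero")
  if (is.null(offset)) offset <- if (any(count == 0)) 0.5 else 0
  ref <- max(year)
  fit <- stats::lm(log(count + offset) ~ I(year - ref))
  cf <- stats::coef(fit)
  structure(list(intercept      = unname(cf[1L]),
                 slope          = unname(cf[2L]),
                 growth         = exp(unname(cf[2L])),
                 reference_year = ref,
                 offset         = offset,
                 sigma2         = stats::sigma(fit)^2,
                 n              = length(year),
                 fit            = fit),
            class = "growth_trend")
}

#' @export
print.growth_trend <- function(x, ...) {
  cat(sprintf("Log-linear growth trend: %+.2f%%/year (factor %.4f), level %.1f at %d (n = %d years)\n",
              100 * (x$growth - 1), x$growth, exp(x$intercept),
              x$reference_year, x$n))
  invisible(x)
}

#' @export
coef.growth_trend <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope, growth = object$growth)
}

#' @export
confint.growth_trend <- function(object, parm = "growth", level = 0.95, ...) {
  ci <- stats::confint(object$fit, level = level)[2L, ]
  if (identical(parm, "growth")) exp(ci) else ci
}

#' @param object a `growth_trend`.
#' @param years calendar years at which to evaluate the fitted level.
#' @param ... unused.
#' @rdname fit_incidence_trend
#' @export
predict.growth_trend <- function(object, years, ...) {
  stats::setNames(
    exp(object$intercept + object$slope * (as.numeric(years) - object$reference_year)) -
      object$offset,
    years)
}

#' Project annual totals over a horizon
#'
#' Evaluates a fitted [growth_trend][fit_incidence_trend()] over future years,
#' returning expected annual totals with stages unassigned.
#'
#' @param trend a `growth_trend` from [fit_incidence_trend()].
#' @param horizon integer vector of consecutive future years; must start after
#'   the fitted data.
#' @return a totals-only [case_table()].
#' @export
project_incidence <- function(trend, horizon) {
  stopifnot(inherits(trend, "growth_trend"))
  horizon <- as.integer(horizon)
  if (any(horizon <= trend$reference_year))
    stop_validation("projection horizon must start after the fitted data (last observed %d)",
                    trend$reference_year)
  case_table_totals(horizon, unname(predict(trend, horizon)))
}

#' Decompose annual totals by diagnostic stage
#'
#' Multiplies each year's total by the stage shares: `C_{y,k} = N_y * s_k`.
#' Because shares sum to one, the per-year stage sum equals the total exactly.
#'
#' @param totals a totals-only [case_table()] (stages unassigned).
#' @param shares a [stage_distribution()].
#' @return a [case_table()] with stage cells.
#' @export
apply_stage_distribution <- function(totals, shares) {
  stopifnot(inherits(totals, "case_table"))
  if (nrow(totals) && !is_totals_only(totals))
    stop_validation("case table already has stages assigned")
  shares <- if (inherits(shares, "stage_distribution")) shares else stage_distribution(shares)
  yt <- year_totals(totals)
  if (!length(yt))
    return(case_table(data.frame(year = integer(), stage = character(),
                                 cases = numeric())))
  cells <- data.frame(
    year  = rep(as.integer(names(yt)), each = 3L),
    stage = rep(pc_stages(), times = length(yt)),
    cases = as.vector(vapply(unname(yt), function(n) n * unname(shares), numeric(3L)))
  )
  case_table(cells, year_totals = yt, scenario = scenario_name(totals))
}

#' Allocate a case table across remoteness bands
#'
#' Splits every stage cell proportionally across bands,
#' `C_{y,k,m} = w_m * C_{y,k}`, so band sums reproduce the statewide cell
#' exactly; each band's year total is `w_m * N_y`, preserving explicit totals.
#'
#' @param table an unstratified [case_table()] with stage cells.
#' @param shares a [remoteness_shares()].
#' @return a band-stratified [case_table()].
#' @export
allocate_by_remoteness <- function(table, shares) {
  stopifnot(inherits(table, "case_table"))
  if (is_stratified(table))
    stop_validation("case table is already stratified by remoteness band")
  if (is_totals_only(table))
    stop_validation("assign stages before allocating by remoteness")
  shares <- if (inherits(shares, "remoteness_shares")) shares else remoteness_shares(shares)
  df <- as.data.frame(table)
  if (!nrow(df)) return(table)
  cells <- do.call(rbind, lapply(mm_bands(), function(b) {
    data.frame(year = df$year, stage = df$stage, band = b,
               cases = df$cases * unname(shares[b]))
  }))
  yt <- year_totals(table)
  out <- case_table(cells, year_totals = yt, scenario = scenario_name(table))
  bt <- expand.grid(band = mm_bands(), year = as.integer(names(yt)),
                    stringsAsFactors = FALSE)
  bt$total <- unname(yt[as.character(bt$year)]) * unname(shares[bt$band])
  attr(out, "band_totals") <- bt[c("year", "band", "total")]
  out
}
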