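#' Expected 5-year survivors of one set of stage cells
#'
#' The survival model is a fixed point probability per stage: expected
#' survivors are `S = sum_k C_k v_k`, with stages mapped to SEER summary
#' categories (I-II to localized, III to regional, IV to distant).
#'
#' @param cells named numeric of cases over [pc_stages()].
#' @param rates a [survival_rates()].
#' @return expected persons alive five years post-diagnosis (real-valued).
#' @examples
#' expected_survivors(c("I-II" = 198, "III" = 297, "IV" = 495),
#'                    survival_rates(c(0.416, 0.144, 0.030)))
#' @export
expected_survivors <- function(cells, rates) {
  rates <- if (inherits(rates, "survival_rates")) rates else survival_rates(rates)
  if (is.null(names(cells)) && length(cells) == 3L) names(cells) <- pc_stages()
  if (!all(pc_stages() %in% names(cells)))
    stop_validation("stage cells must cover {%s}", paste(pc_stages(), collapse = ", "))
  if (any(!is.finite(cells)) || any(cells < 0))
    stop_validation("stage cells must be finite and non-negative")
  sum(cells[pc_stages()] * rates[pc_stages()])
}

#' Expected 5-year survivors per year (and band)
#'
#' Applies [expected_survivors()] to every year (and remoteness band) of a
#' case table; proportions are survivors over the year (or year-band) total.
#'
#' @param table a [case_table()] with stage cells.
#' @param rates a [survival_rates()].
#' @return a `survivor_table`: data.frame with `year`, optionally `band`,
#'   `survivors` (real), `survivors_display`, `proportion`; the scenario name
#'   and year totals are carried as attributes.
#' @export
survivor_table <- function(table, rates) {
  stopifnot(inherits(table, "case_table"))
  if (is_totals_only(table))
    stop_validation("assign stages before computing survivors")
  rates <- if (inherits(rates, "survival_rates")) rates else survival_rates(rates)
  yt <- year_totals(table)
  if (!is_stratified(table)) {
    out <- data.frame(year = case_years(table))
    out$survivors <- vapply(out$year, function(y)
      expected_survivors(stage_cells(table, y), rates), numeric(1))
    tot <- unname(yt[as.character(out$year)])
  } else {
    bt <- band_totals(table)
    out <- bt[c("year", "band")]
    out$survivors <- vapply(seq_len(nrow(bt)), function(i)
      expected_survivors(stage_cells(table, bt$year[i], bt$band[i]), rates),
      numeric(1))
    tot <- bt$total
  }
  out$survivors_display <- round_display(out$survivors)
  out$proportion <- ifelse(tot > 0, out$survivors / tot, NA_real_)
  rownames(out) <- NULL
  structure(out,
            scenario = scenario_name(table),
            year_totals = yt,
            class = c("survivor_table", "data.frame"))
}

#' @export
print.survivor_table <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat("Expected 5-year survivors", if (!is.null(sc)) sprintf("[scenario: %s]", sc), "\n")
  df <- as.data.frame(x)
  df$proportion <- sprintf("%.1f%%", 100 * df$proportion)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Survival gain of a scenario over the status quo
#'
#' Per-year and cumulative additional 5-year survivors, plus the per-year
#' percent increase (rounded half away from zero to integer percent, as
#' reported).
#'
#' @param proposed,current `survivor_table`s over matching years (and bands).
#' @return list with `per_year` (data.frame of `year`, optionally `band`,
#'   `gain`, `gain_display`, `percent_increase`), `cumulative` and
#'   `cumulative_display`.
#' @export
survival_gain <- function(proposed, current) {
  stopifnot(inherits(proposed, "survivor_table"), inherits(current, "survivor_table"))
  key_cols <- intersect(c("year", "band"), intersect(names(proposed), names(current)))
  if (!identical(proposed[key_cols], current[key_cols]))
    stop_validation("survivor tables cover different years or bands")
  out <- as.data.frame(proposed)[key_cols]
  out$gain <- proposed$survivors - current$survivors
  out$gain_display <- round_display(out$gain)
  out$percent_increase <- ifelse(current$survivors > 0,
                                 round_display(100 * out$gain / current$survivors),
                                 NA_real_)
  list(per_year = out,
       cumulative = sum(out$gain),
       cumulative_display = round_display(sum(out$gain)))
}

#' Overall 5-year survival proportion per year
#'
#' Survivors over the year's total new cases, as integer percent.
#'
#' @param survivors a `survivor_table` (unstratified).
#' @param totals optional [case_table()] supplying year totals; defaults to
#'   the totals recorded on the survivor table.
#' @return named numeric of integer percentages per year (NA where the total
#'   is zero).
#' @export
overall_survival_rate <- function(survivors, totals = NULL) {
  stopifnot(inherits(survivors, "survivor_table"))
  if ("band" %in% names(survivors))
    stop_validation("overall survival uses the unstratified survivor table")
  yt <- if (is.null(totals)) attr(survivors, "year_totals") else year_totals(totals)
  if (!identical(sort(as.integer(names(yt))), sort(survivors$year)))
    stop_validation("totals cover different years than the survivor table")
  n <- unname(yt[as.character(survivors$year)])
  pct <- ifelse(n > 0, round_display(100 * survivors$survivors / n), NA_real_)
  stats::setNames(pct, survivors$year)
}
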