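#' Shift one year's stage cells under an early-diagnosis scenario
#'
#' Core scenario arithmetic for a single year: a fraction `r` of current
#' stage-IV cases and a fraction `1 - q` of current stage-III cases are
#' diagnosed at stages I-II instead, with the year's total conserved:
#' `C'_IV = (1 - r) C_IV`, `C'_III = q C_III`,
#' `C'_I-II = N - C'_III - C'_IV`. Stage I-II is obtained by subtraction from
#' the stored total (not by adding shifted cases to the, possibly rounded,
#' I-II cell) because published totals are conserved while published cells
#' are not always self-consistent.
#'
#' @param cells named numeric of current cases over [pc_stages()].
#' @param total the year's stored total `N`.
#' @param scenario a [stage_shift_scenario()].
#' @return named numeric of shifted cases over [pc_stages()], summing to
#'   `total` exactly.
#' @examples
#' sc <- stage_shift_scenario("base case", r = 0.7)
#' apply_stage_shift(c("I-II" = 198, "III" = 297, "IV" = 495), 991, sc)
#' @export
apply_stage_shift <- function(cells, total, scenario) {
  stopifnot(inherits(scenario, "stage_shift_scenario"))
  if (is.null(names(cells)) && length(cells) == 3L) names(cells) <- pc_stages()
  if (!setequal(names(cells), pc_stages()) || length(cells) != 3L)
    stop_validation("stage cells must be named over {%s}", paste(pc_stages(), collapse = ", "))
  cells <- cells[pc_stages()]
  if (any(!is.finite(cells)) || any(cells < 0) || !is.finite(total) || total < 0)
    stop_validation("stage cells and total must be finite and non-negative")
  # the identity scenario is a strict no-op: published cells need not sum to
  # the published total, and recomputing I-II by subtraction would silently
  # absorb that rounding gap
  if (scenario$r == 0 && scenario$q == 1) return(cells)
  new_iv  <- (1 - scenario$r) * cells[["IV"]]
  new_iii <- scenario$q * cells[["III"]]
  new_early <- total - new_iii - new_iv
  if (new_early < 0)
    stop_infeasible("scenario '%s' infeasible: retained stage III+IV (%.2f) exceeds the year total (%.2f)",
                    scenario$name, new_iii + new_iv, total)
  c("I-II" = unname(new_early), "III" = unname(new_iii), "IV" = unname(new_iv))
}

#' Build a scenario case table
#'
#' Applies [apply_stage_shift()] to every year (and, for stratified tables,
#' within every remoteness band, using the band's own total) of a status-quo
#' case table. Totals are conserved per year and band.
#'
#' @param status_quo a [case_table()] with stage cells.
#' @param scenario a [stage_shift_scenario()].
#' @return a [case_table()] tagged with the scenario name.
#' @export
build_scenario_table <- function(status_quo, scenario) {
  stopifnot(inherits(status_quo, "case_table"),
            inherits(scenario, "stage_shift_scenario"))
  if (!nrow(status_quo)) return(status_quo)
  if (is_totals_only(status_quo))
    stop_validation("assign stages before applying a scenario")
  yt <- year_totals(status_quo)
  if (!is_stratified(status_quo)) {
    cells <- do.call(rbind, lapply(names(yt), function(y) {
      shifted <- apply_stage_shift(stage_cells(status_quo, as.integer(y)),
                                   yt[[y]], scenario)
      data.frame(year = as.integer(y), stage = names(shifted), cases = unname(shifted))
    }))
    out <- case_table(cells, year_totals = yt, scenario = scenario$name,
                      totals_tol = Inf)
  } else {
    bt <- band_totals(status_quo)
    cells <- do.call(rbind, lapply(seq_len(nrow(bt)), function(i) {
      shifted <- apply_stage_shift(
        stage_cells(status_quo, bt$year[i], band = bt$band[i]),
        bt$total[i], scenario)
      data.frame(year = bt$year[i], stage = names(shifted), band = bt$band[i],
                 cases = unname(shifted))
    }))
    out <- case_table(cells, year_totals = yt, scenario = scenario$name,
                      totals_tol = Inf)
    attr(out, "band_totals") <- bt
  }
  out
}

match_tables <- function(proposed, current) {
  if (!identical(case_years(proposed), case_years(current)))
    stop_validation("case tables cover different year ranges")
  if (is_stratified(proposed) != is_stratified(current))
    stop_validation("case tables differ in remoteness stratification")
}

#' Additional early-stage (I-II) diagnoses under a scenario
#'
#' Per-year and cumulative differences in stage I-II cases between a scenario
#' table and the status quo; the headline "additional early diagnoses" metric.
#'
#' @param proposed,current [case_table()]s over the same years and
#'   stratification.
#' @return list with `per_year` (data.frame of `year`, optionally `band`,
#'   `additional`, `additional_display`), `cumulative` (unrounded) and
#'   `cumulative_display`.
#' @export
additional_early_cases <- function(proposed, current) {
  stopifnot(inherits(proposed, "case_table"), inherits(current, "case_table"))
  match_tables(proposed, current)
  key_cols <- if (is_stratified(proposed)) c("year", "band") else "year"
  pick <- function(tb) {
    df <- as.data.frame(tb)
    df <- df[df$stage == "I-II", , drop = FALSE]
    df[order(df$year, match(df$band, mm_bands())), , drop = FALSE]
  }
  p <- pick(proposed); c_ <- pick(current)
  if (!identical(p[key_cols], c_[key_cols]))
    stop_validation("case tables have mismatched cells")
  out <- p[key_cols]
  out$additional <- p$cases - c_$cases
  out$additional_display <- round_display(out$additional)
  rownames(out) <- NULL
  list(per_year = out,
       cumulative = sum(out$additional),
       cumulative_display = round_display(sum(out$additional)))
}

#' Lead-time ("diagnosed L years earlier") scenario variant
#'
#' Experimental pull-forward reading of a screening lead time of `L` years:
#' with `L = 1` the shift acts within the diagnosis year and the result equals
#' [build_scenario_table()]; with `L > 1`, the first horizon year's stage I-II
#' cell additionally receives the scenario's early-stage gains of the
#' following `L - 1` horizon years, and that year's total grows accordingly
#' (incidence conservation deliberately does not hold in year one). The
#' output is flagged `experimental`.
#'
#' @param status_quo an unstratified [case_table()] with stage cells covering
#'   at least `L` years.
#' @param scenario a [stage_shift_scenario()] with `lead_time_years >= 1`.
#' @return a [case_table()] with attribute `experimental = TRUE` when
#'   `L > 1`.
#' @export
apply_lead_time <- function(status_quo, scenario) {
  stopifnot(inherits(status_quo, "case_table"),
            inherits(scenario, "stage_shift_scenario"))
  L <- scenario$lead_time_years
  if (L < 1L)
    stop_validation("lead-time variant needs lead_time_years >= 1")
  if (is_stratified(status_quo))
    stop_validation("apply the lead-time variant before remoteness allocation")
  shifted <- build_scenario_table(status_quo, scenario)
  if (L == 1L) return(shifted)
  yrs <- case_years(status_quo)
  if (length(yrs) < L)
    stop_validation("lead time of %d years needs projections for %d horizon years (have %d)",
                    L, L, length(yrs))
  gains <- additional_early_cases(shifted, status_quo)$per_year
  pulled <- sum(gains$additional[gains$year > yrs[1L] & gains$year <= yrs[1L] + (L - 1L)])
  df <- as.data.frame(shifted)
  first_early <- df$year == yrs[1L] & df$stage == "I-II"
  df$cases[first_early] <- df$cases[first_early] + pulled
  yt <- year_totals(shifted)
  yt[[as.character(yrs[1L])]] <- yt[[as.character(yrs[1L])]] + pulled
  out <- case_table(df, year_totals = yt,
                    scenario = sprintf("%s (diagnosed %d years earlier)",
                                       scenario$name, L),
                    totals_tol = Inf)
  attr(out, "experimental") <- TRUE
  out
}
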