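#' Bundled Victorian model inputs (2023-2027)
#'
#' The package ships the published Victorian pancreatic-cancer planning inputs
#' as plain-text fixtures: the status-quo case table for 2023-2027 (stage
#' cells and explicit year totals, which the cells do not always sum to
#' because the source rounds from non-integer internals), the stage
#' distribution at diagnosis (0.20 / 0.30 / 0.50), stage-specific 5-year
#' relative survival (0.416 / 0.144 / 0.030, SEER-derived: localized /
#' regional / distant), remoteness-band shares (0.81 / 0.0575 / 0.06 /
#' 0.0725), statewide registered-headcount series for the seven professions
#' involved in pancreatic cancer care, and a 2023 by-band headcount snapshot.
#'
#' Some non-metropolitan by-band headcounts could not be transcribed
#' unambiguously from the source table; these rows are flagged
#' `uncertain = TRUE` and nothing in the package's checks depends on them.
#'
#' @return a list with elements `cases` ([case_table()]), `stage_shares`
#'   ([stage_distribution()]), `survival` ([survival_rates()]), `remoteness`
#'   ([remoteness_shares()]), `workforce` and `workforce_by_band`
#'   ([workforce_series()]), and `scenarios` (the three published stage-shift
#'   scenarios with r = 0.2, 0.5, 0.7 and q = 0.8216).
#' @examples
#' fx <- victoria_fixture()
#' fx$cases
#' @export
victoria_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "pancwf", mustWork = TRUE)
  shares <- read_shares(path("victoria_shares.csv"))
  list(
    cases             = read_case_table(path("victoria_cases_2023_2027.csv"),
                                        scenario = "status quo"),
    stage_shares      = stage_distribution(shares_subset(shares, "stage", pc_stages())),
    survival          = survival_rates(shares_subset(shares, "survival", pc_stages())),
    remoteness        = remoteness_shares(shares_subset(shares, "remoteness", mm_bands())),
    workforce         = read_workforce_series(path("victoria_workforce_2023_2027.csv")),
    workforce_by_band = read_workforce_series(path("victoria_workforce_by_band_2023.csv")),
    scenarios = list(
      stage_shift_scenario("20% stage-IV reduction", r = 0.2),
      stage_shift_scenario("50% stage-IV reduction", r = 0.5),
      stage_shift_scenario("70% stage-IV reduction (base case)", r = 0.7)
    )
  )
}

#' Write a ready-to-run configuration for the bundled Victorian inputs
#'
#' Convenience wrapper that writes a YAML configuration pointing at the
#' bundled fixture files, with the three published scenarios, suitable for
#' [load_config()] and [run_pipeline()].
#'
#' @param path output path for the YAML file.
#' @return the config path, invisibly.
#' @examples
#' cfg <- load_config(victoria_config_file(tempfile(fileext = ".yaml")))
#' @export
victoria_config_file <- function(path = tempfile(fileext = ".yaml")) {
  extdata <- function(f) system.file("extdata", f, package = "pancwf", mustWork = TRUE)
  cfg <- list(
    years = list(start = 2023L, end = 2027L),
    scenarios = list(
      list(name = "20% stage-IV reduction", r = 0.2, q = 0.8216),
      list(name = "50% stage-IV reduction", r = 0.5, q = 0.8216),
      list(name = "70% stage-IV reduction (base case)", r = 0.7, q = 0.8216)
    ),
    io = list(cases = extdata("victoria_cases_2023_2027.csv"),
              workforce = extdata("victoria_workforce_2023_2027.csv"),
              workforce_by_band = extdata("victoria_workforce_by_band_2023.csv"))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
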