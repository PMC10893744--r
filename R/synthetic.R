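#' Parameters for the synthetic registry-data generator
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' registry incidence history with constant multiplicative growth plus
#' optional Poisson count noise, and near-geometric workforce headcount
#' growth per profession, split across remoteness bands. Defaults mirror the
#' bundled Victorian study conditions: a 12-year history ending 2022 at a
#' level that projects to roughly 991 cases in 2023 with ~2.6% annual growth
#' (the growth implied by the published 2023-2027 totals), the published
#' stage, survival and remoteness shares, and the seven professions'
#' published 2023 headcounts with their fitted annual growth.
#'
#' @param base_incidence expected cases in the last history year.
#' @param incidence_growth annual multiplicative incidence growth (> 0).
#' @param noise_model `"poisson"` (counts drawn as Poisson around the
#'   geometric mean; needs `seed`) or `"none"` (rounded exact means).
#' @param stage_shares a [stage_distribution()].
#' @param band_shares a [remoteness_shares()].
#' @param survival a [survival_rates()].
#' @param workforce_bases named numeric, headcount per profession in the
#'   first horizon year.
#' @param workforce_growths named numeric, annual growth per profession.
#' @param n_history_years length of the generated incidence history.
#' @param end_history_year last history year; the horizon starts after it.
#' @param horizon projection years for workforce and config.
#' @param scenarios list of [stage_shift_scenario()] written to the bundle's
#'   config; defaults to the three published scenarios.
#' @param exact_totals optional named numeric of horizon totals to write into
#'   the bundle config verbatim (explicit-totals mode; the pipeline then
#'   bypasses trend fitting).
#' @param seed integer seed; mandatory when `noise_model != "none"`. One seed
#'   governs all streams: the incidence stream draws under `seed + 101`, the
#'   workforce stream under `seed + 202`, so either can be regenerated alone.
#' @return a validated `synth_params` list.
#' @export
synth_params <- function(base_incidence = 966,
                         incidence_growth = 1.026,
                         noise_model = c("poisson", "none"),
                         stage_shares = stage_distribution(c(0.20, 0.30, 0.50)),
                         band_shares = remoteness_shares(c(0.81, 0.0575, 0.06, 0.0725)),
                         survival = survival_rates(c(0.416, 0.144, 0.030)),
                         workforce_bases = c(endocrinology = 1862,
                                             gastroenterology_hepatology = 2274,
                                             palliative_medicine = 601,
                                             pain_medicine = 310,
                                             general_surgery = 4135,
                                             radiation_oncology = 914,
                                             medical_oncology = 2104),
                         workforce_growths = c(endocrinology = 1.056,
                                               gastroenterology_hepatology = 1.046,
                                               palliative_medicine = 1.075,
                                               pain_medicine = 1.085,
                                               general_surgery = 1.027,
                                               radiation_oncology = 1.035,
                                               medical_oncology = 1.065),
                         n_history_years = 12L,
                         end_history_year = 2022L,
                         horizon = 2023:2027,
                         scenarios = NULL,
                         exact_totals = NULL,
                         seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (base_incidence <= 0 || incidence_growth <= 0)
    stop_validation("base incidence and growth must be positive")
  if (n_history_years < 3L)
    stop_validation("need at least 3 history years")
  if (!setequal(names(workforce_bases), names(workforce_growths)))
    stop_validation("workforce bases and growths must name the same professions")
  if (any(workforce_bases < 0) || any(workforce_growths <= 0))
    stop_validation("workforce bases must be non-negative and growths positive")
  if (noise_model != "none" && is.null(seed))
    stop_validation("a seed is mandatory when noise_model is not 'none'")
  if (min(horizon) <= end_history_year)
    stop_validation("horizon must start after the history")
  if (is.null(scenarios))
    scenarios <- list(stage_shift_scenario("20% stage-IV reduction", r = 0.2),
                      stage_shift_scenario("50% stage-IV reduction", r = 0.5),
                      stage_shift_scenario("70% stage-IV reduction (base case)", r = 0.7))
  structure(list(base_incidence = base_incidence,
                 incidence_growth = incidence_growth,
                 noise_model = noise_model,
                 stage_shares = if (inherits(stage_shares, "stage_distribution"))
                   stage_shares else stage_distribution(stage_shares),
                 band_shares = if (inherits(band_shares, "remoteness_shares"))
                   band_shares else remoteness_shares(band_shares),
                 survival = if (inherits(survival, "survival_rates"))
                   survival else survival_rates(survival),
                 workforce_bases = workforce_bases,
                 workforce_growths = workforce_growths,
                 n_history_years = as.integer(n_history_years),
                 end_history_year = as.integer(end_history_year),
                 horizon = as.integer(horizon),
                 scenarios = scenarios,
                 exact_totals = exact_totals,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "synth_params")
}

with_stream_seed <- function(seed, offset, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + offset)
  eval.parent(substitute(expr))
}

#' Generate a synthetic registry incidence history
#'
#' Counts are drawn as `Poisson(base * growth^(y - y_end))` (or the rounded
#' exact means when `noise_model = "none"`); reproducible for a fixed seed.
#'
#' @param params a [synth_params()].
#' @return an [incidence_history()].
#' @export
generate_incidence_history <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  years <- seq(params$end_history_year - params$n_history_years + 1L,
               params$end_history_year)
  means <- params$base_incidence *
    params$incidence_growth^(years - params$end_history_year)
  counts <- if (params$noise_model == "none") {
    round_display(means)
  } else {
    with_stream_seed(params$seed, 101L, stats::rpois(length(means), means))
  }
  incidence_history(years, counts, region = "synthetic")
}

#' Generate a synthetic workforce series
#'
#' Per-profession geometric headcount growth over the horizon, rounded to
#' whole persons (Poisson-perturbed around the geometric mean under the
#' `"poisson"` noise model). Band-level rows split the statewide counts by
#' the configured band shares.
#'
#' @param params a [synth_params()].
#' @param by_band also emit band-level rows.
#' @return a [workforce_series()].
#' @export
generate_workforce_series <- function(params, by_band = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  years <- params$horizon
  prof <- names(params$workforce_bases)
  means <- do.call(rbind, lapply(prof, function(p) {
    data.frame(profession = p, year = years,
               mean = params$workforce_bases[[p]] *
                 params$workforce_growths[[p]]^(years - years[1L]))
  }))
  means$headcount <- if (params$noise_model == "none") {
    round_display(means$mean)
  } else {
    with_stream_seed(params$seed, 202L, stats::rpois(nrow(means), means$mean))
  }
  statewide <- means[c("profession", "year", "headcount")]
  if (!by_band) return(workforce_series(statewide))
  bands <- do.call(rbind, lapply(mm_bands(), function(b) {
    data.frame(profession = statewide$profession, year = statewide$year,
               band = b,
               headcount = round_display(statewide$headcount *
                                           unname(params$band_shares[b])))
  }))
  statewide$band <- NA_character_
  workforce_series(rbind(statewide, bands))
}

#' Write a complete synthetic input bundle
#'
#' Generates every input the pipeline needs and writes it under `out_dir`:
#' `cases.csv` (incidence history, stages unassigned), `workforce.csv`,
#' `shares.csv` and `config.yaml`. The bundle loads through the package's own
#' readers without validation errors, and identical parameters plus seed give
#' byte-identical files.
#'
#' @param params a [synth_params()].
#' @param out_dir writable output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
generate_full_bundle <- function(params, out_dir) {
  stopifnot(inherits(params, "synth_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop_io("output directory not writable: %s", out_dir)

  hist <- generate_incidence_history(params)
  cases_path <- file.path(out_dir, "cases.csv")
  utils::write.csv(data.frame(year = hist$year, stage = NA_character_,
                              cases = hist$count),
                   cases_path, row.names = FALSE, quote = FALSE)

  wf <- generate_workforce_series(params)
  wf_path <- file.path(out_dir, "workforce.csv")
  write_workforce_series(wf, wf_path)

  shares_path <- file.path(out_dir, "shares.csv")
  utils::write.csv(data.frame(
    key = c(paste0("stage.", pc_stages()), paste0("survival.", pc_stages()),
            paste0("remoteness.", mm_bands())),
    value = c(unname(params$stage_shares), unname(params$survival),
              unname(params$band_shares))
  ), shares_path, row.names = FALSE, quote = FALSE)

  cfg <- list(
    years = c(list(start = min(params$horizon), end = max(params$horizon)),
              if (!is.null(params$exact_totals))
                list(totals = as.numeric(params$exact_totals))),
    stages = as.list(unclass(params$stage_shares)),
    survival = as.list(unclass(params$survival)),
    remoteness = as.list(unclass(params$band_shares)),
    scenarios = lapply(params$scenarios, function(s)
      list(name = s$name, r = s$r, q = s$q, lead_time_years = s$lead_time_years)),
    io = list(cases = "cases.csv", workforce = "workforce.csv")
  )
  if (!is.null(params$seed)) cfg$seed <- params$seed
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)

  invisible(c(cases = cases_path, workforce = wf_path,
              shares = shares_path, config = cfg_path))
}
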