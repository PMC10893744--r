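#' Run the full demand / scenario / survival / workforce pipeline
#'
#' Executes the model stages in order: status-quo demand (explicit totals or
#' trend-projected history, then stage decomposition), stage-shift scenarios,
#' expected 5-year survivors and gains, remoteness allocation, and the
#' workforce gap comparison. Deterministic given the configuration and
#' inputs.
#'
#' @param config a [load_config()] result, or a path to a config file.
#' @param verbose log each stage to stderr.
#' @return a `report_bundle`: list with `status_quo`, `scenario_tables`,
#'   `survivors` (per scenario, current first), `gains`,
#'   `additional_early` (statewide) and `additional_by_band`,
#'   `survivors_by_band`, `overall_rates`, `gap` (or NULL when no band-level
#'   supply is configured), and `meta`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "model_config"))
  say <- function(fmt, ...) if (verbose)
    message(sprintf(paste0("[pancwf] ", fmt), ...))
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("pancwf_pipeline_error", class(e)))))
  }

  status_quo <- stage("demand projection", {
    if (!is.null(config$totals)) {
      apply_stage_distribution(
        case_table_totals(config$years, unname(config$totals), scenario = "status quo"),
        config$stage_shares)
    } else {
      tab <- read_case_table(config$io$cases, scenario = "status quo")
      if (identical(case_years(tab), config$years) && !is_totals_only(tab)) {
        tab # pre-resolved status-quo table (fixture mode)
      } else if (identical(case_years(tab), config$years)) {
        apply_stage_distribution(tab, config$stage_shares)
      } else {
        trend <- fit_incidence_trend(
          data.frame(year = tab$year, count = tab$cases))
        proj <- project_incidence(trend, config$years)
        attr(proj, "scenario") <- "status quo"
        apply_stage_distribution(proj, config$stage_shares)
      }
    }
  })

  scenario_tables <- stage("stage-shift scenarios", {
    out <- lapply(config$scenarios, function(s) {
      if (s$lead_time_years > 1L) apply_lead_time(status_quo, s)
      else build_scenario_table(status_quo, s)
    })
    stats::setNames(out, vapply(config$scenarios, `[[`, character(1), "name"))
  })

  survivors <- stage("survival model", {
    all_tabs <- c(list(`status quo` = status_quo), scenario_tables)
    lapply(all_tabs, survivor_table, rates = config$survival)
  })
  gains <- stage("survival gains", {
    lapply(survivors[-1L], survival_gain, current = survivors[[1L]])
  })
  additional_early <- stage("additional early-stage cases", {
    lapply(scenario_tables, additional_early_cases, current = status_quo)
  })
  overall_rates <- stage("overall survival rates", {
    lapply(survivors, overall_survival_rate)
  })

  by_band <- stage("remoteness allocation", {
    tabs <- c(list(`status quo` = status_quo), scenario_tables)
    # lead-time variants break year-total conservation on purpose; they are
    # statewide-only and skipped here
    tabs <- Filter(function(t) !isTRUE(attr(t, "experimental")), tabs)
    lapply(tabs, allocate_by_remoteness, shares = config$remoteness)
  })
  survivors_by_band <- stage("survival by remoteness", {
    lapply(by_band, survivor_table, rates = config$survival)
  })
  additional_by_band <- stage("early-stage increase by remoteness", {
    lapply(by_band[-1L], additional_early_cases, current = by_band[[1L]])
  })

  gap <- stage("workforce gap", {
    wf_path <- config$io$workforce_by_band %||% config$io$workforce
    supply <- if (!is.null(wf_path)) read_workforce_series(wf_path)
    if (is.null(supply) || all(is.na(supply$band))) {
      NULL # no band-level supply configured; the comparison has no basis
    } else {
      # headline comparison: band-level increase in early-stage cases under
      # the last configured scenario (the base case) vs registered headcounts
      demand <- if (length(by_band) > 1L) {
        add <- additional_by_band[[length(additional_by_band)]]$per_year
        ct <- case_table(data.frame(year = add$year, stage = "I-II",
                                    band = add$band,
                                    cases = pmax(add$additional, 0)))
        attr(ct, "scenario") <- names(by_band)[length(by_band)]
        ct
      } else by_band[[1L]]
      compute_gap(demand, supply)
    }
  })

  meta <- list(
    years = config$years,
    seed = config$seed,
    scenarios = vapply(config$scenarios, `[[`, character(1), "name"),
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    version = as.character(utils::packageVersion("pancwf"))
  )
  structure(list(status_quo = status_quo,
                 scenario_tables = scenario_tables,
                 survivors = survivors,
                 gains = gains,
                 additional_early = additional_early,
                 overall_rates = overall_rates,
                 by_band = by_band,
                 survivors_by_band = survivors_by_band,
                 additional_by_band = additional_by_band,
                 gap = gap,
                 config = config,
                 meta = meta),
            class = "report_bundle")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "io")]), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("pancwf report bundle: horizon %d-%d, %d scenario(s)\n",
              min(x$meta$years), max(x$meta$years), length(x$scenario_tables)))
  yrs <- as.character(x$meta$years)
  cur <- x$survivors[["status quo"]]
  cat(sprintf("  status quo: %s total cases, %s expected 5-year survivors\n",
              paste(round_display(year_totals(x$status_quo)), collapse = "/"),
              paste(cur$survivors_display, collapse = "/")))
  for (nm in names(x$scenario_tables)) {
    g <- x$gains[[nm]]
    cat(sprintf("  %s: +%d early-stage cases and +%d survivors over %d years\n",
                nm, x$additional_early[[nm]]$cumulative_display,
                g$cumulative_display, length(yrs)))
  }
  if (!is.null(x$gap)) {
    tn <- attr(x$gap, "travel_necessity")
    cat(sprintf("  workforce gap: %d profession-band cells with demand but no registered supply\n",
                nrow(tn)))
  }
  invisible(x)
}

#' @export
summary.report_bundle <- function(object, ...) {
  print(object)
  cat("\nOverall 5-year survival (integer %):\n")
  print(do.call(rbind, object$overall_rates))
  invisible(object)
}

#' Render the report bundle to CSV tables
#'
#' Writes `cases_by_scenario.csv`, `survivors.csv`, `survivors_by_band.csv`,
#' `additional_cases_by_band.csv` and `gap_report.csv` under `out_dir`.
#' Display-rounded columns sit beside the unrounded values, and each file
#' opens with a `#`-prefixed provenance header (version, config hash, seed,
#' bundle timestamp) that the package's own readers skip. Re-rendering the
#' same bundle reproduces the files byte for byte.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
render_tables <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop_io("output directory not writable: %s", out_dir)
  header <- c(sprintf("# pancwf %s", bundle$meta$version),
              sprintf("# config_hash: %s", bundle$meta$config_hash),
              sprintf("# seed: %s", bundle$meta$seed %||% "none"),
              sprintf("# generated: %s", bundle$meta$timestamp))
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    path
  }
  mode <- bundle$config$rounding

  all_tabs <- c(list(`status quo` = bundle$status_quo), bundle$scenario_tables)
  cases <- do.call(rbind, lapply(names(all_tabs), function(nm) {
      tb <- all_tabs[[nm]]
      df <- as.data.frame(tb)
      data.frame(scenario = scenario_name(tb) %||% nm, year = df$year, stage = df$stage,
                 cases_raw = df$cases,
                 cases_display = round_display(df$cases, mode),
                 year_total = round_display(
                   unname(year_totals(tb)[as.character(df$year)]), mode))
    }))
  p1 <- emit(cases, "cases_by_scenario.csv")

  surv_df <- function(tabs) do.call(rbind, lapply(names(tabs), function(nm) {
    df <- as.data.frame(tabs[[nm]])
    data.frame(scenario = nm, year = df$year,
               band = if ("band" %in% names(df)) df$band else NA_character_,
               survivors_raw = df$survivors,
               survivors_display = round_display(df$survivors, mode),
               proportion = round(df$proportion, 4))
  }))
  p2 <- emit(surv_df(bundle$survivors), "survivors.csv")
  p3 <- emit(surv_df(bundle$survivors_by_band), "survivors_by_band.csv")

  add <- do.call(rbind, lapply(names(bundle$additional_by_band), function(nm) {
    df <- bundle$additional_by_band[[nm]]$per_year
    data.frame(scenario = nm, year = df$year, band = df$band,
               additional_raw = df$additional,
               additional_display = round_display(df$additional, mode))
  }))
  p4 <- if (!is.null(add)) emit(add, "additional_cases_by_band.csv") else NULL

  p5 <- if (!is.null(bundle$gap)) {
    df <- as.data.frame(bundle$gap)
    names(df)[names(df) == "cases_per_specialist"] <- "ratio"
    names(df)[names(df) == "shortage"] <- "shortage_flag"
    emit(df, "gap_report.csv")
  } else NULL

  invisible(c(cases_by_scenario = p1, survivors = p2, survivors_by_band = p3,
              additional_cases_by_band = p4, gap_report = p5))
}
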