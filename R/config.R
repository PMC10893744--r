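#' Load and validate a model configuration
#'
#' The configuration is a YAML file with sections `years`, `stages`,
#' `survival`, `remoteness`, `scenarios`, `io` and `seed`. Omitted optional
#' sections fall back to the bundled Victorian defaults (stage shares
#' 0.20/0.30/0.50, survival 0.416/0.144/0.030, remoteness
#' 0.81/0.0575/0.06/0.0725). `years` gives the projection horizon (`start`,
#' `end`) and may carry explicit `totals`, in which case the demand side
#' passes them through unchanged instead of fitting a trend. `io` paths are
#' resolved relative to the config file's directory and must exist.
#'
#' @param path path to a YAML configuration file.
#' @return a `model_config` list: `years`, `totals` (or NULL), `stage_shares`,
#'   `survival`, `remoteness`, `scenarios` (list of
#'   [stage_shift_scenario()]), `io` (resolved paths), `rounding`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_io("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  known <- c("years", "stages", "survival", "remoteness", "scenarios", "io",
             "seed", "rounding")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop_validation("unknown config section(s): %s", paste(unknown, collapse = ", "))

  yrs <- cfg$years
  if (is.null(yrs$start) || is.null(yrs$end))
    stop_validation("config section 'years' must give start and end")
  years <- seq(as.integer(yrs$start), as.integer(yrs$end))
  totals <- NULL
  if (!is.null(yrs$totals)) {
    totals <- as.numeric(unlist(yrs$totals))
    if (length(totals) != length(years))
      stop_validation("years.totals must give one total per horizon year (%d needed, %d given)",
                      length(years), length(totals))
    totals <- stats::setNames(totals, years)
  }

  section_vec <- function(x, labels, what, default, ctor) {
    if (is.null(x)) return(ctor(default))
    v <- unlist(x)
    if (!setequal(names(v), labels))
      stop_validation("config section '%s' must name exactly {%s}",
                      what, paste(labels, collapse = ", "))
    tryCatch(ctor(stats::setNames(as.numeric(v[labels]), labels)),
             pancwf_validation_error = function(e)
               stop_validation("config section '%s': %s", what, conditionMessage(e)))
  }
  stage_shares <- section_vec(cfg$stages, pc_stages(), "stages",
                              c("I-II" = 0.20, "III" = 0.30, "IV" = 0.50),
                              stage_distribution)
  survival <- section_vec(cfg$survival, pc_stages(), "survival",
                          c("I-II" = 0.416, "III" = 0.144, "IV" = 0.030),
                          survival_rates)
  remoteness <- section_vec(cfg$remoteness, mm_bands(), "remoteness",
                            c(metropolitan = 0.81, regional_centres = 0.0575,
                              large_rural = 0.06, medium_small_rural_plus = 0.0725),
                            remoteness_shares)

  scen_keys <- c("name", "r", "q", "lead_time_years")
  scenarios <- lapply(cfg$scenarios %||% list(), function(s) {
    bad <- setdiff(names(s), scen_keys)
    if (length(bad))
      stop_validation("unknown scenario key(s): %s", paste(bad, collapse = ", "))
    if (is.null(s$name) || is.null(s$r))
      stop_validation("every scenario needs at least 'name' and 'r'")
    stage_shift_scenario(s$name, r = s$r, q = s$q %||% 0.8216,
                         lead_time_years = s$lead_time_years %||% 0L)
  })
  nm <- vapply(scenarios, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_validation("scenario names must be unique (duplicated: %s)",
                    paste(unique(nm[duplicated(nm)]), collapse = ", "))

  base_dir <- dirname(normalizePath(path))
  io <- lapply(cfg$io %||% list(), function(p) {
    full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
    if (!file.exists(full))
      stop_io("configured input file not found: %s", full)
    full
  })
  if (is.null(totals) && is.null(io$cases))
    stop_validation("config must give either years.totals or io.cases")

  structure(list(years = years, totals = totals,
                 stage_shares = stage_shares, survival = survival,
                 remoteness = remoteness, scenarios = scenarios,
                 io = io, rounding = cfg$rounding %||% "half-away",
                 seed = cfg$seed),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Model configuration: horizon %d-%d (%s), %d scenario(s)\n",
              min(x$years), max(x$years),
              if (is.null(x$totals)) "trend-projected" else "explicit totals",
              length(x$scenarios)))
  invisible(x)
}
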