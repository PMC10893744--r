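#' Diagnostic stage labels
#'
#' The model resolves pancreatic cancer cases into three diagnostic stage
#' groups: localized (stages I-II), regional (stage III) and distant
#' (stage IV) disease. The order is clinical: I-II < III < IV.
#'
#' @return character vector `c("I-II", "III", "IV")`.
#' @export
pc_stages <- function() c("I-II", "III", "IV")

#' Remoteness bands (Modified Monash classification, collapsed)
#'
#' Four geographic bands derived from the Modified Monash Model (MM) scale:
#' MM1 metropolitan, MM2 regional centres, MM3 large rural towns, and MM4-MM7
#' (medium/small rural towns through very remote) combined into one band.
#'
#' @return character vector of the four band labels.
#' @export
mm_bands <- function() {
  c("metropolitan", "regional_centres", "large_rural", "medium_small_rural_plus")
}

#' @rdname mm_bands
#' @export
mm_band_labels <- function() {
  c(metropolitan            = "Metropolitan (MM1)",
    regional_centres        = "Regional centres (MM2)",
    large_rural             = "Large rural towns (MM3)",
    medium_small_rural_plus = "Medium/small rural towns and beyond (MM4-7)")
}

check_named_props <- function(x, labels, what, sum_to_one = TRUE, tol = 1e-9) {
  if (!is.numeric(x))
    stop_validation("%s must be numeric", what)
  if (is.null(names(x)) && length(x) == length(labels))
    names(x) <- labels
  if (!setequal(names(x), labels) || length(x) != length(labels))
    stop_validation("%s must be named over {%s}", what, paste(labels, collapse = ", "))
  x <- x[labels]
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_validation("%s values must lie in [0, 1]", what)
  if (sum_to_one && abs(sum(x) - 1) > tol)
    stop_validation("%s must sum to 1 (got %.10f)", what, sum(x))
  x
}

#' Stage distribution at diagnosis
#'
#' Shares of new cases diagnosed at each stage group; must sum to one.
#'
#' @param shares numeric vector of length 3, named with [pc_stages()] (names
#'   optional if given in stage order).
#' @return a `stage_distribution` object (validated named numeric).
#' @examples
#' stage_distribution(c(0.20, 0.30, 0.50))
#' @export
stage_distribution <- function(shares) {
  shares <- check_named_props(shares, pc_stages(), "stage distribution")
  structure(shares, class = "stage_distribution")
}

#' Stage-specific 5-year relative survival
#'
#' Fixed point probabilities of surviving five years post-diagnosis, relative
#' to matched general-population survival, one per stage group. No survival
#' curve or interim mortality timing is modelled.
#'
#' @param rates numeric vector of length 3 in [0, 1], named with
#'   [pc_stages()] (names optional if given in stage order).
#' @return a `survival_rates` object.
#' @examples
#' survival_rates(c(0.416, 0.144, 0.030))
#' @export
survival_rates <- function(rates) {
  rates <- check_named_props(rates, pc_stages(), "survival rates", sum_to_one = FALSE)
  structure(rates, class = "survival_rates")
}

#' Remoteness-band population shares
#'
#' Proportions used to allocate statewide demand across the four remoteness
#' bands; must sum to one.
#'
#' @param shares numeric vector of length 4 named with [mm_bands()] (names
#'   optional if given in band order).
#' @return a `remoteness_shares` object.
#' @examples
#' remoteness_shares(c(0.81, 0.0575, 0.06, 0.0725))
#' @export
remoteness_shares <- function(shares) {
  shares <- check_named_props(shares, mm_bands(), "remoteness shares")
  structure(shares, class = "remoteness_shares")
}

#' Early-diagnosis stage-shift scenario
#'
#' A scenario reassigns a fraction `r` of current stage-IV diagnoses and a
#' fraction `1 - q` of current stage-III diagnoses to stages I-II, holding the
#' year's total incidence fixed: within each year,
#' \deqn{C'_{IV} = (1-r)\,C_{IV},\quad C'_{III} = q\,C_{III},\quad
#'       C'_{I\text{-}II} = N - C'_{III} - C'_{IV}.}
#'
#' @param name scenario identifier (unique within a configuration).
#' @param r fraction of current stage-IV cases shifted to stages I-II, in
#'   [0, 1].
#' @param q retained fraction of current stage-III cases, in [0, 1]. The
#'   default 0.8216 reproduces the published Victorian scenario tables, where
#'   the proposed stage-III column is identical across scenarios.
#' @param lead_time_years non-negative integer; 0 or 1 means the shift acts
#'   within the diagnosis year, larger values invoke the experimental
#'   pull-forward variant (see [apply_lead_time()]).
#' @return a `stage_shift_scenario` object.
#' @examples
#' stage_shift_scenario("base case", r = 0.7)
#' @export
stage_shift_scenario <- function(name, r, q = 0.8216, lead_time_years = 0L) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("scenario name must be a non-empty string")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
    stop_validation("scenario '%s': r must be a single value in [0, 1]", name)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop_validation("scenario '%s': q must be a single value in [0, 1]", name)
  if (!is.numeric(lead_time_years) || length(lead_time_years) != 1L ||
      is.na(lead_time_years) || lead_time_years < 0 ||
      !is_wholenumber(lead_time_years))
    stop_validation("scenario '%s': lead_time_years must be a non-negative integer", name)
  structure(list(name = name, r = r, q = q,
                 lead_time_years = as.integer(lead_time_years)),
            class = "stage_shift_scenario")
}

#' @export
print.stage_shift_scenario <- function(x, ...) {
  cat(sprintf("Stage-shift scenario '%s': r = %g (stage IV shifted), q = %g (stage III retained)",
              x$name, x$r, x$q))
  if (x$lead_time_years > 1L)
    cat(sprintf(", lead time %d years [experimental]", x$lead_time_years))
  cat("\n")
  invisible(x)
}

#' @export
print.stage_distribution <- function(x, ...) {
  cat("Stage distribution at diagnosis:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.survival_rates <- function(x, ...) {
  cat("5-year relative survival by stage:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.remoteness_shares <- function(x, ...) {
  cat("Remoteness-band shares:\n")
  print(unclass(x), ...)
  invisible(x)
}
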