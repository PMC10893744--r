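#' Display rounding
#'
#' Round real-valued model quantities for display. The model keeps all
#' arithmetic real-valued; integers exist only in rendered tables, so the
#' rounding mode is a presentation choice, not part of the model.
#'
#' @param x numeric vector.
#' @param mode one of `"half-away"` (round half away from zero, the default
#'   used in all rendered tables), `"half-even"` (IEEE banker's rounding, as
#'   [base::round()]), `"floor"` or `"ceiling"`.
#' @return numeric vector of whole numbers (still of type double).
#' @examples
#' round_display(c(148.5, 495.45, -2.5))
#' @export
round_display <- function(x, mode = c("half-away", "half-even", "floor", "ceiling")) {
  mode <- match.arg(mode)
  switch(mode,
    "half-away" = sign(x) * floor(abs(x) + 0.5),
    "half-even" = round(x),
    "floor"     = floor(x),
    "ceiling"   = ceiling(x)
  )
}

# classed conditions so callers/tests can distinguish bad input from bad files
stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pancwf_validation_error", "pancwf_error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pancwf_io_error", "pancwf_error")))
}

stop_infeasible <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pancwf_infeasible_error", "pancwf_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
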