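#' Arterial glucose providers
#'
#' The hormone model needs an arterial glucose signal Ca,g(t) (mmol/L); the
#' metabolic network that would generate it is outside this package's scope,
#' so glucose enters through a provider contract: any function of time (min)
#' returning finite positive mmol/L works. Three constructors are supplied:
#'
#' * `glucose_constant(level)` — fixed glucose, default the fasting 5 mmol/L.
#' * `glucose_timeseries(times, values)` — linear interpolation through a
#'   measured or precomputed series; constant extrapolation at the ends.
#' * `glucose_feedback(a, b)` — a deliberately simple closed-loop toy: the
#'   glucose state follows
#'   `dCa_g/dt = a * (CG/CI - CG0/CI0) - b * PVO2max * Ca_g`,
#'   a qualitative hepatic-production (glucagon-to-insulin ratio) versus
#'   exercise-uptake balance. It exists so closed-loop tests exercise the
#'   glucose-dependent secretion term; it is a package-invented toy, not a
#'   validated metabolic model.
#'
#' @param level Constant glucose, mmol/L.
#' @return A function or object usable as the `glucose` argument of
#'   [simulate_protocol()].
#' @name glucose_providers
NULL

#' @rdname glucose_providers
#' @export
glucose_constant <- function(level = 5) {
  stopifnot(is.numeric(level), length(level) == 1L, is.finite(level),
            level > 0)
  structure(function(t) rep.int(level, length(t)),
            class = c("glucose_provider", "function"),
            type = "constant", level = level)
}

#' @rdname glucose_providers
#' @param times,values Time grid (min) and glucose values (mmol/L) for the
#'   tabulated provider.
#' @export
glucose_timeseries <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2L,
            !is.unsorted(times, strictly = TRUE),
            all(is.finite(values)), all(values > 0))
  f <- stats::approxfun(times, values, rule = 2)
  structure(function(t) f(t),
            class = c("glucose_provider", "function"),
            type = "timeseries", times = times, values = values)
}

#' @rdname glucose_providers
#' @param a Hepatic-production gain, mmol/L/min per unit deviation of the
#'   glucagon-to-insulin ratio from basal.
#' @param b Exercise-uptake rate, per %VO2max per minute.
#' @param level0 Initial glucose, mmol/L.
#' @export
glucose_feedback <- function(a = 0.05, b = 2e-4, level0 = 5) {
  stopifnot(a >= 0, b >= 0, level0 > 0)
  structure(list(a = a, b = b, level0 = level0),
            class = c("glucose_provider", "glucose_feedback"),
            type = "feedback")
}

is_feedback_glucose <- function(glucose) {
  inherits(glucose, "glucose_feedback")
}
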