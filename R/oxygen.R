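#' Exercise intensity input u(t)
#'
#' The piecewise-constant intensity driving the oxygen-uptake kinetics:
#' within a segment (closed interval, boundaries included) it equals the
#' segment's Tv, elsewhere it is 0.
#'
#' @param t Time(s) in minutes (vectorised).
#' @param protocol An [exercise_protocol()].
#' @return Intensity in %VO2max, same length as `t`.
#' @export
exercise_input <- function(t, protocol) {
  stopifnot(inherits(protocol, "exercise_protocol"))
  u <- numeric(length(t))
  for (s in protocol$segments) {
    u[t >= s$t_start & t <= s$t_end] <- s$tv
  }
  u
}

#' Suprabasal oxygen-uptake derivative
#'
#' First-order kinetics of the suprabasal oxygen consumption PVO2max(t),
#' expressed in %VO2max: `d/dt PVO2max = -rate * PVO2max + rate * u`.
#' The default rate of 0.8 per minute brings PVO2max to the target intensity
#' in roughly 5-6 minutes after exercise onset, and back to basal on the
#' same time scale after it ends.
#'
#' @param p Current PVO2max, %VO2max.
#' @param u Current intensity input, %VO2max.
#' @param rate First-order rate constant, per minute (> 0).
#' @return Time derivative in %VO2max per minute.
#' @export
pvo2max_derivative <- function(p, u, rate = 0.8) {
  stopifnot(rate > 0)
  -rate * p + rate * u
}

#' Closed-form suprabasal oxygen uptake under a piecewise-constant input
#'
#' Exact solution of the first-order oxygen-uptake equation, chained across
#' the protocol's segment breakpoints: within each interval of constant
#' input u, `p(t) = u + (p0 - u) * exp(-rate * (t - t0))`. Serves as the
#' analytic oracle against which numerical integration is checked.
#'
#' @param t Time(s) in minutes (vectorised, each >= 0).
#' @param protocol An [exercise_protocol()].
#' @param rate First-order rate constant, per minute.
#' @param p0 Initial PVO2max at t = 0 (default 0, rest).
#' @return PVO2max in %VO2max at each `t`.
#' @export
pvo2max_closed_form <- function(t, protocol, rate = 0.8, p0 = 0) {
  stopifnot(inherits(protocol, "exercise_protocol"), rate > 0, all(t >= 0))
  bps <- segment_breakpoints(protocol)
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    knots <- c(0, bps[bps < ti], ti)
    p <- p0
    for (j in seq_len(length(knots) - 1L)) {
      a <- knots[j]; b <- knots[j + 1L]
      # input is constant on (a, b); sample at the midpoint
      u <- exercise_input((a + b) / 2, protocol)
      p <- u + (p - u) * exp(-rate * (b - a))
    }
    out[i] <- p
  }
  out
}
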