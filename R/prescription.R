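#' Exercise segment
#'
#' One piecewise-constant bout of exercise: the intensity input u(t) equals
#' `tv` (%VO2max) on the closed interval \[t_start, t_end\] and 0 outside it.
#'
#' @param t_start,t_end Start and end of the bout in minutes,
#'   `t_end > t_start >= 0`.
#' @param tv Relative intensity in %VO2max, in (0, 100\].
#' @param above_lt Logical flag marking a bout above the lactate threshold,
#'   where the model's first-order oxygen kinetics are no longer valid.
#' @return A list of class `exercise_segment`.
#' @export
exercise_segment <- function(t_start, t_end, tv, above_lt = FALSE) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(tv))
  if (t_start < 0 || t_end <= t_start) {
    stop("need t_end > t_start >= 0 (minutes)", call. = FALSE)
  }
  if (tv <= 0 || tv > 100) {
    stop("tv must lie in (0, 100] %VO2max", call. = FALSE)
  }
  structure(list(t_start = t_start, t_end = t_end, tv = tv,
                 above_lt = isTRUE(above_lt)),
            class = "exercise_segment")
}

#' Exercise protocol
#'
#' An ordered sequence of non-overlapping exercise segments plus a modality.
#' A single segment reproduces the classical step input: intensity Tv between
#' texstart and texend, zero elsewhere.
#'
#' @param segments A list of [exercise_segment()]s (possibly empty: a
#'   rest-only protocol).
#' @param modality One of "leg_cycling", "arm_cycling", "walking", "running",
#'   "stepping".
#' @param vo2_rest Resting oxygen uptake, ml O2 per kg per min; defaults to
#'   3.5 (1 MET).
#' @return A list of class `exercise_protocol`.
#' @export
exercise_protocol <- function(segments = list(), modality = "leg_cycling",
                              vo2_rest = 3.5) {
  modality <- match.arg(modality, c("leg_cycling", "arm_cycling", "walking",
                                    "running", "stepping"))
  if (inherits(segments, "exercise_segment")) segments <- list(segments)
  stopifnot(is.list(segments))
  for (s in segments) {
    if (!inherits(s, "exercise_segment")) {
      stop("segments must be exercise_segment objects", call. = FALSE)
    }
  }
  if (vo2_rest <= 0) stop("vo2_rest must be > 0", call. = FALSE)
  if (length(segments) > 1L) {
    o <- order(vapply(segments, `[[`, numeric(1), "t_start"))
    segments <- segments[o]
    starts <- vapply(segments, `[[`, numeric(1), "t_start")
    ends <- vapply(segments, `[[`, numeric(1), "t_end")
    if (any(starts[-1] < ends[-length(ends)])) {
      stop("exercise segments must not overlap", call. = FALSE)
    }
  }
  structure(list(modality = modality, segments = segments,
                 vo2_rest = vo2_rest),
            class = "exercise_protocol")
}

#' @export
print.exercise_protocol <- function(x, ...) {
  cat("<exercise_protocol> ", x$modality, ", ", length(x$segments),
      " segment(s), vo2_rest = ", x$vo2_rest, " ml/kg/min\n", sep = "")
  for (s in x$segments) {
    cat(sprintf("  [%g, %g] min at Tv = %g %%VO2max%s\n", s$t_start, s$t_end,
                s$tv, if (s$above_lt) " (above LT)" else ""))
  }
  invisible(x)
}

segment_breakpoints <- function(protocol) {
  if (length(protocol$segments) == 0L) return(numeric(0))
  sort(unique(unlist(lapply(protocol$segments,
                            function(s) c(s$t_start, s$t_end)))))
}

#' Gait parameters for walking, running and stepping
#'
#' @param v Speed in m/min (walking/running).
#' @param grade Fractional slope, e.g. 0.05 for 5% (walking/running).
#' @param step_freq Stepping frequency in steps/min (stepping).
#' @param step_height Step height in m (stepping).
#' @return A list of class `gait_parameters`.
#' @export
gait_parameters <- function(v = 0, grade = 0, step_freq = 0,
                            step_height = 0) {
  vals <- c(v = v, grade = grade, step_freq = step_freq,
            step_height = step_height)
  if (any(vals < 0)) stop("gait parameters must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "gait_parameters")
}

#' Work rate from oxygen consumption for cycle ergometry
#'
#' Inverts the linear moderate-intensity relations between external work rate
#' (Watt) and oxygen cost for leg and arm cycling:
#' leg `WR = BW * (VO2 - 2 * VO2rest) / 10.8`,
#' arm `WR = BW * (VO2 - VO2rest) / 18`.
#'
#' @param vo2 Oxygen consumption, ml O2 per kg per min.
#' @param bw Body weight, kg.
#' @param vo2_rest Resting oxygen uptake, ml O2 per kg per min (default 3.5).
#' @param mode "leg" or "arm".
#' @return Work rate in Watt.
#' @export
wr_from_vo2_cycling <- function(vo2, bw, vo2_rest = 3.5,
                                mode = c("leg", "arm")) {
  mode <- match.arg(mode)
  stopifnot(bw > 0, vo2_rest > 0)
  wr <- switch(mode,
               leg = bw * (vo2 - 2 * vo2_rest) / 10.8,
               arm = bw * (vo2 - vo2_rest) / 18)
  if (any(wr < 0)) {
    stop("oxygen consumption below the relation's validity range (negative ",
         "work rate); ", mode, " cycling needs vo2 >= ",
         if (mode == "leg") "2*vo2_rest" else "vo2_rest", call. = FALSE)
  }
  wr
}

#' Oxygen consumption of cycle ergometry at a given work rate
#'
#' Algebraic inverse of [wr_from_vo2_cycling()].
#'
#' @inheritParams wr_from_vo2_cycling
#' @param wr Work rate in Watt (>= 0).
#' @return Oxygen consumption in ml O2 per kg per min.
#' @export
vo2_from_wr_cycling <- function(wr, bw, vo2_rest = 3.5,
                                mode = c("leg", "arm")) {
  mode <- match.arg(mode)
  stopifnot(bw > 0, vo2_rest > 0)
  if (any(wr < 0)) stop("work rate must be >= 0 W", call. = FALSE)
  switch(mode,
         leg = 10.8 * wr / bw + 2 * vo2_rest,
         arm = 18 * wr / bw + vo2_rest)
}

#' Oxygen cost of walking, running and stepping
#'
#' Metabolic equations for the gross oxygen cost of the three gait
#' modalities:
#' walking `vo2_rest + 0.1 v + 1.8 v G`,
#' running `vo2_rest + 0.2 v + 0.9 v G`,
#' stepping `vo2_rest + 0.2 F + 1.33 * 1.8 * H * F`.
#'
#' @param params A [gait_parameters()] object.
#' @param vo2_rest Resting oxygen uptake, ml O2 per kg per min.
#' @param mode "walking", "running" or "stepping".
#' @return Oxygen consumption in ml O2 per kg per min.
#' @export
vo2_from_gait <- function(params, vo2_rest = 3.5,
                          mode = c("walking", "running", "stepping")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "gait_parameters"), vo2_rest > 0)
  switch(mode,
         walking = vo2_rest + 0.1 * params$v + 1.8 * params$v * params$grade,
         running = vo2_rest + 0.2 * params$v + 0.9 * params$v * params$grade,
         stepping = vo2_rest + 0.2 * params$step_freq +
           1.33 * 1.8 * params$step_height * params$step_freq)
}

#' Session energy-equivalent work-rate figure for gait modalities
#'
#' For walking, running and stepping the work-rate figure is obtained from
#' the oxygen consumed over the whole session, using the 5 kcal per litre O2
#' caloric equivalent and the kcal-per-hour-to-Watt factor 1.163:
#' `vo2 * BW * (t_end - t_start) * 5e-3 * 1.163`.
#' Note the session duration enters as a factor, so the result scales with
#' session length; it is the conventional per-session surrogate used to map
#' gait exercise onto a Watt-denominated model input, not an instantaneous
#' mechanical power.
#'
#' @param vo2 Oxygen consumption, ml O2 per kg per min.
#' @param bw Body weight, kg.
#' @param t_start,t_end Session start/end in minutes.
#' @return The energy-equivalent work-rate figure (Watt-denominated).
#' @export
wr_energy_equivalent <- function(vo2, bw, t_start, t_end) {
  stopifnot(bw > 0)
  if (t_end < t_start) stop("t_end must be >= t_start", call. = FALSE)
  vo2 * bw * (t_end - t_start) * 5e-3 * 1.163
}

#' Relative intensity of a gait prescription
#'
#' Composes the gait oxygen-cost equations with the definition of relative
#' intensity: `tv = 100 * vo2 / vo2max`.
#'
#' @inheritParams vo2_from_gait
#' @param vo2max Maximal oxygen uptake, ml O2 per kg per min.
#' @return Relative intensity in %VO2max.
#' @export
tv_from_gait <- function(params, vo2_rest = 3.5,
                         mode = c("walking", "running", "stepping"),
                         vo2max) {
  stopifnot(vo2max > 0)
  vo2 <- vo2_from_gait(params, vo2_rest, mode)
  tv <- 100 * vo2 / vo2max
  if (any(tv > 100)) {
    stop("prescription demands ", round(max(tv), 1),
         " %VO2max, exceeding maximal aerobic capacity", call. = FALSE)
  }
  tv
}
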