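#' Simulation settings
#'
#' @param t0,t_end Simulation window in minutes.
#' @param output_grid Output spacing in minutes.
#' @param rel_tol,abs_tol Solver tolerances (adaptive, stiff-capable).
#' @param seed Integer seed recorded in trajectory metadata (the core model
#'   is deterministic; the seed matters for downstream noisy-observation
#'   generation).
#' @return A list of class `simulation_settings`.
#' @export
simulation_settings <- function(t0 = 0, t_end = 210, output_grid = 1,
                                rel_tol = 1e-8, abs_tol = 1e-10,
                                seed = NULL) {
  if (t_end <= t0) stop("t_end must exceed t0", call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0 || output_grid <= 0) {
    stop("tolerances and output_grid must be > 0", call. = FALSE)
  }
  structure(list(t0 = t0, t_end = t_end, output_grid = output_grid,
                 rel_tol = rel_tol, abs_tol = abs_tol, seed = seed),
            class = "simulation_settings")
}

state_columns <- c("pvo2max_pct", "ce_pM", "ci_pM", "cg_pM", "cag_mM")

#' Simulate the coupled exercise-hormone system
#'
#' Integrates the four-state system — suprabasal oxygen uptake, epinephrine,
#' insulin and glucagon (plus glucose when the feedback provider is used) —
#' over an exercise protocol, starting from the basal state. Segment
#' boundaries are mandatory integrator restart points so the discontinuous
#' intensity input never straddles a solver step.
#'
#' @param subject A [subject_profile()] (supplies body weight; its VO2max is
#'   used by the prescription layer, not by the hormone dynamics, which run
#'   on relative intensity).
#' @param protocol An [exercise_protocol()].
#' @param params A [model_parameters()] bundle; its body weight must match
#'   the subject's (an error is raised on mismatch, since the derived
#'   elimination constant depends on body weight).
#' @param glucose A glucose provider (see [glucose_providers]); default
#'   constant 5 mmol/L.
#' @param settings A [simulation_settings()] object.
#' @return A data.frame of class `exermet_trajectory` with columns
#'   `time_min`, `pvo2max_pct`, `ce_pM`, `ci_pM`, `cg_pM`, `cag_mM`, and
#'   attributes `basal` (named basal values) and `meta`.
#' @export
simulate_protocol <- function(subject, protocol,
                              params = reference_parameters(
                                bw = subject$body_weight),
                              glucose = glucose_constant(5),
                              settings = simulation_settings()) {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(protocol, "exercise_protocol"),
            inherits(params, "model_parameters"),
            inherits(settings, "simulation_settings"))
  if (abs(params$bw - subject$body_weight) > 1e-9) {
    stop("params were derived for bw = ", params$bw,
         " kg but the subject weighs ", subject$body_weight,
         " kg; rebuild model_parameters for this subject", call. = FALSE)
  }
  if (any(vapply(protocol$segments, `[[`, logical(1), "above_lt"))) {
    warning("protocol contains a segment above the lactate threshold; ",
            "the first-order oxygen kinetics are not valid there",
            call. = FALSE)
  }

  ep <- params$epinephrine
  ctl <- params$controller
  feedback <- is_feedback_glucose(glucose)

  y0 <- c(p = 0, ce = ep$CE0, ci = ctl$CI0, cg = ctl$CG0)
  if (feedback) y0 <- c(y0, cag = glucose$level0)

  deriv <- function(t, y, parms) {
    ca_g <- if (feedback) y[["cag"]] else glucose(t)
    u <- parms$u
    dp <- pvo2max_derivative(y[["p"]], u)
    dce <- epinephrine_derivative(y[["ce"]], ca_g, max(y[["p"]], 0),
                                  params$bw, ep, k = params$k)
    dci <- insulin_derivative(max(y[["ci"]], 0), y[["cg"]], y[["ce"]], ctl,
                              h = params$h, ca_g = ca_g, ce0 = ep$CE0)
    dcg <- glucagon_derivative(max(y[["cg"]], 0), y[["ci"]], ctl,
                               h = params$h, ca_g = ca_g)
    d <- c(dp, dce, dci, dcg)
    if (feedback) {
      dcag <- glucose$a * (y[["cg"]] / y[["ci"]] - ctl$CG0 / ctl$CI0) -
        glucose$b * max(y[["p"]], 0) * ca_g
      d <- c(d, dcag)
    }
    list(d)
  }

  grid <- seq(settings$t0, settings$t_end, by = settings$output_grid)
  if (grid[length(grid)] < settings$t_end) grid <- c(grid, settings$t_end)
  bps <- segment_breakpoints(protocol)
  bps <- bps[bps > settings$t0 & bps < settings$t_end]
  knots <- c(settings$t0, bps, settings$t_end)

  rows <- vector("list", length(knots) - 1L)
  y <- y0
  for (j in seq_len(length(knots) - 1L)) {
    a <- knots[j]; b <- knots[j + 1L]
    times <- sort(unique(c(a, grid[grid > a & grid < b], b)))
    # constant input on this inter-breakpoint piece
    u <- exercise_input((a + b) / 2, protocol)
    sol <- deSolve::ode(y = y, times = times, func = deriv,
                        parms = list(u = u), method = "lsoda",
                        rtol = settings$rel_tol, atol = settings$abs_tol,
                        maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed; last accepted time ",
           max(sol[, "time"]), " min", call. = FALSE)
    }
    rows[[j]] <- sol
    y <- sol[nrow(sol), -1]
  }
  sol <- do.call(rbind, lapply(seq_along(rows), function(j) {
    if (j < length(rows)) rows[[j]][-nrow(rows[[j]]), , drop = FALSE]
    else rows[[j]]
  }))

  keep <- sol[, "time"] %in% grid | seq_len(nrow(sol)) == nrow(sol)
  sol <- sol[keep, , drop = FALSE]
  traj <- data.frame(
    time_min = sol[, "time"],
    pvo2max_pct = sol[, "p"],
    ce_pM = sol[, "ce"],
    ci_pM = sol[, "ci"],
    cg_pM = sol[, "cg"],
    cag_mM = if (feedback) sol[, "cag"] else glucose(sol[, "time"]))
  traj <- traj[!duplicated(traj$time_min), ]
  rownames(traj) <- NULL
  if (any(!is.finite(as.matrix(traj)))) {
    stop("non-finite state values in trajectory", call. = FALSE)
  }
  basal <- c(pvo2max_pct = 0, ce_pM = ep$CE0, ci_pM = ctl$CI0,
             cg_pM = ctl$CG0,
             cag_mM = if (feedback) glucose$level0 else ep$cag_star)
  structure(traj,
            class = c("exermet_trajectory", "data.frame"),
            basal = basal,
            meta = list(subject = subject, protocol = protocol,
                        settings = settings, k = params$k, h = params$h,
                        k5 = ctl$k5, suprabasal = FALSE))
}

#' Suprabasal view of a trajectory
#'
#' Expresses each hormone (and glucose) column as its deviation from basal;
#' the oxygen-uptake column is already suprabasal and is left unchanged.
#' Adding the basal values back recovers the original trajectory.
#'
#' @param traj An `exermet_trajectory`.
#' @return A trajectory with suprabasal columns and the same attributes.
#' @export
to_suprabasal <- function(traj) {
  stopifnot(inherits(traj, "exermet_trajectory"))
  basal <- attr(traj, "basal")
  out <- traj
  for (col in c("ce_pM", "ci_pM", "cg_pM", "cag_mM")) {
    out[[col]] <- traj[[col]] - basal[[col]]
  }
  meta <- attr(out, "meta")
  meta$suprabasal <- TRUE
  attr(out, "meta") <- meta
  out
}

#' @export
print.exermet_trajectory <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("<exermet_trajectory> ", nrow(x), " time points, ",
      min(x$time_min), "-", max(x$time_min), " min",
      if (isTRUE(meta$suprabasal)) " (suprabasal)", "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4), ...)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Sensitivity sweep over a model parameter
#'
#' Re-simulates a base scenario for each value of one sweepable parameter —
#' body weight `BW`, exercise intensity `Tv`, or the epinephrine-to-insulin
#' coupling `k5` — recomputing the derived constants (k, h) for every run.
#'
#' @param name One of "BW", "Tv", "k5".
#' @param values Numeric vector of parameter values.
#' @param subject,protocol,params,glucose,settings Base scenario, as in
#'   [simulate_protocol()].
#' @return A named list of trajectories, one per value.
#' @export
sweep_parameter <- function(name, values, subject, protocol,
                            params = reference_parameters(
                              bw = subject$body_weight),
                            glucose = glucose_constant(5),
                            settings = simulation_settings()) {
  sweepables <- c("BW", "Tv", "k5")
  if (!name %in% sweepables) {
    stop("unknown sweep parameter '", name, "'; sweepables: ",
         paste(sweepables, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.numeric(values), all(is.finite(values)))
  out <- lapply(values, function(v) {
    subj <- subject; prot <- protocol; par <- params
    if (name == "BW") {
      subj$body_weight <- v
      par <- model_parameters(params$epinephrine, params$controller, bw = v)
    } else if (name == "Tv") {
      prot$segments <- lapply(prot$segments, function(s) {
        s$tv <- v
        s
      })
    } else if (name == "k5") {
      ctl <- params$controller
      ctl$k5 <- v
      par <- model_parameters(params$epinephrine, ctl, bw = params$bw)
    }
    simulate_protocol(subj, prot, par, glucose, settings)
  })
  names(out) <- paste0(name, "=", values)
  out
}
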