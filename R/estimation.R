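#' Observation set
#'
#' Paired insulin and glucagon measurements over time, with the constant
#' percent coefficient of variation that defines the weighted least-squares
#' weights. Measurement errors are modelled as zero-mean Gaussian with
#' standard deviation `cv * value` (default CV 4%).
#'
#' @param times Sampling times, minutes (sorted, within the simulation
#'   horizon).
#' @param insulin_obs,glucagon_obs Observed concentrations, pM (positive).
#' @param cv Fractional measurement coefficient of variation (> 0,
#'   default 0.04).
#' @param subject,protocol Metadata: the subject and protocol under which
#'   the observations were collected (used by the fitting routine to
#'   re-simulate).
#' @return A list of class `observation_set`.
#' @export
observation_set <- function(times, insulin_obs, glucagon_obs, cv = 0.04,
                            subject = NULL, protocol = NULL) {
  stopifnot(length(times) == length(insulin_obs),
            length(times) == length(glucagon_obs))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("observation times must be strictly increasing", call. = FALSE)
  }
  if (any(insulin_obs <= 0) || any(glucagon_obs <= 0)) {
    stop("observed concentrations must be positive", call. = FALSE)
  }
  if (cv <= 0) stop("cv must be > 0", call. = FALSE)
  structure(list(times = times, insulin_obs = insulin_obs,
                 glucagon_obs = glucagon_obs, cv = cv,
                 subject = subject, protocol = protocol),
            class = "observation_set")
}

# simulate at exactly the observation times (plus enough grid for accuracy)
simulate_at <- function(obs, params, glucose, rel_tol = 1e-8,
                        abs_tol = 1e-10) {
  settings <- simulation_settings(
    t0 = min(0, min(obs$times)), t_end = max(obs$times),
    output_grid = 1, rel_tol = rel_tol, abs_tol = abs_tol)
  traj <- simulate_protocol(obs$subject, obs$protocol, params, glucose,
                            settings)
  list(
    insulin = stats::approx(traj$time_min, traj$ci_pM, obs$times)$y,
    glucagon = stats::approx(traj$time_min, traj$cg_pM, obs$times)$y)
}

#' Weighted residuals of the hormone model at given parameters
#'
#' Simulates the model under the observation set's subject and protocol and
#' returns `(observed - simulated) / (cv * observed)` for each hormone at
#' each sampling time, insulin first then glucagon. Weighting by the
#' measurement CV makes each residual a unit-variance quantity under the
#' Gaussian error model.
#'
#' @param obs An [observation_set()] (must carry subject and protocol).
#' @param params A [model_parameters()] bundle.
#' @param glucose Glucose provider, default constant 5 mmol/L.
#' @param weight_by "observed" (measurement-CV convention, default) or
#'   "predicted".
#' @return Numeric residual vector of length `2 * length(obs$times)`.
#' @export
weighted_residuals <- function(obs, params, glucose = glucose_constant(5),
                               weight_by = c("observed", "predicted")) {
  stopifnot(inherits(obs, "observation_set"))
  weight_by <- match.arg(weight_by)
  if (is.null(obs$subject) || is.null(obs$protocol)) {
    stop("observation set must carry subject and protocol metadata",
         call. = FALSE)
  }
  sim <- tryCatch(
    simulate_at(obs, params, glucose),
    error = function(e) {
      stop("simulation failed at k5 = ", params$controller$k5, ": ",
           conditionMessage(e), call. = FALSE)
    })
  den_i <- if (weight_by == "observed") obs$insulin_obs else sim$insulin
  den_g <- if (weight_by == "observed") obs$glucagon_obs else sim$glucagon
  c((obs$insulin_obs - sim$insulin) / (obs$cv * den_i),
    (obs$glucagon_obs - sim$glucagon) / (obs$cv * den_g))
}

# rebuild a model_parameters bundle with named free parameters replaced,
# re-deriving k and h
apply_free <- function(params, free_values) {
  ep <- params$epinephrine
  ctl <- params$controller
  for (nm in names(free_values)) {
    if (nm %in% names(ctl)) {
      ctl[[nm]] <- free_values[[nm]]
    } else if (nm %in% names(ep)) {
      ep[[nm]] <- free_values[[nm]]
    } else {
      stop("unknown parameter '", nm, "'", call. = FALSE)
    }
  }
  class(ep) <- "epinephrine_parameters"
  class(ctl) <- "controller_parameters"
  model_parameters(ep, ctl, bw = params$bw)
}

#' Fit controller parameters by weighted nonlinear least squares
#'
#' Minimises the weighted sum of squared residuals (see
#' [weighted_residuals()]) over the named free parameters — by default the
#' epinephrine-to-insulin coupling `k5` — using the Levenberg-Marquardt
#' algorithm. Derived constants (elimination constant k, controller offset
#' h) are recomputed inside the objective at every evaluation. Estimate
#' precision is reported as the Fisher-information percent coefficient of
#' variation (see [cv_percent()]).
#'
#' @param obs An [observation_set()] with subject and protocol metadata.
#' @param params Base [model_parameters()]; non-free fields are held fixed.
#' @param free Character vector of free parameter names (default "k5").
#' @param init Named numeric initial values (default: current values in
#'   `params`).
#' @param lower,upper Bounds per free parameter (default `[0, Inf)`).
#' @param glucose Glucose provider.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A list of class `exermet_fit`: `estimates`, `cv_percent`,
#'   `weighted_residuals`, `converged`, `n_iter`, `objective`, `message`.
#' @export
fit_parameters <- function(obs, params = reference_parameters(
                             bw = obs$subject$body_weight),
                           free = "k5", init = NULL,
                           lower = NULL, upper = NULL,
                           glucose = glucose_constant(5),
                           max_iter = 100) {
  stopifnot(inherits(obs, "observation_set"), length(free) >= 1L)
  current <- c(params$controller[setdiff(names(params$controller),
                                         c("phi", "psi"))],
               params$epinephrine)
  if (is.null(init)) init <- unlist(current[free])
  init <- init[free]
  if (anyNA(init)) stop("missing initial value for some free parameter",
                        call. = FALSE)
  if (is.null(lower)) lower <- rep(0, length(free))
  if (is.null(upper)) upper <- rep(Inf, length(free))
  if (any(init < lower | init > upper)) {
    stop("initial values must lie within bounds", call. = FALSE)
  }

  fn <- function(theta) {
    names(theta) <- free
    weighted_residuals(obs, apply_free(params, as.list(theta)), glucose)
  }
  res <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12,
                              ptol = 1e-12))
  est <- res$par
  names(est) <- free
  converged <- res$info %in% 1:4
  resid <- fn(est)
  cvp <- tryCatch(
    cv_percent(est, fn),
    error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      rep(NA_real_, length(free))
    })
  structure(list(estimates = est, cv_percent = cvp,
                 weighted_residuals = resid,
                 converged = converged, n_iter = res$niter,
                 objective = sum(resid^2), message = res$message),
            class = "exermet_fit")
}

#' @export
print.exermet_fit <- function(x, ...) {
  cat("<exermet_fit>", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations; weighted SSE =",
      format(x$objective, digits = 6), "\n")
  for (nm in names(x$estimates)) {
    cat(sprintf("  %s = %.6g  (CV%% = %.3g)\n", nm, x$estimates[[nm]],
                x$cv_percent[[nm]]))
  }
  invisible(x)
}

#' Fisher-information percent coefficient of variation
#'
#' Precision of a weighted least-squares estimate: the residual Jacobian J
#' (sensitivities of the CV-weighted residuals to the free parameters) gives
#' the Fisher information `J' J`; the per-parameter standard deviation is
#' the square root of the diagonal of its inverse, and
#' `CV% = 100 * SD / |estimate|`.
#'
#' @param estimates Named numeric vector of estimates (the optimum).
#' @param residual_fn Function mapping a parameter vector (in the order of
#'   `estimates`) to the weighted residual vector.
#' @param rel_step Relative finite-difference step (default 1e-6).
#' @param centred Use centred differences instead of forward (default
#'   FALSE; centred is the verification mode).
#' @return Named CV% per parameter.
#' @export
cv_percent <- function(estimates, residual_fn, rel_step = 1e-6,
                       centred = FALSE) {
  p <- length(estimates)
  r0 <- residual_fn(estimates)
  J <- matrix(0, length(r0), p)
  for (j in seq_len(p)) {
    hstep <- rel_step * max(abs(estimates[j]), rel_step)
    up <- estimates; up[j] <- up[j] + hstep
    if (centred) {
      dn <- estimates; dn[j] <- dn[j] - hstep
      J[, j] <- (residual_fn(up) - residual_fn(dn)) / (2 * hstep)
    } else {
      J[, j] <- (residual_fn(up) - r0) / hstep
    }
  }
  info <- crossprod(J)
  ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12) {
    bad <- names(estimates)[which.min(abs(diag(info)))]
    stop("rank-deficient sensitivity Jacobian: parameter '", bad,
         "' is not identifiable from this design", call. = FALSE)
  }
  sde <- sqrt(diag(solve(info)))
  out <- 100 * sde / abs(estimates)
  names(out) <- names(estimates)
  out
}
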