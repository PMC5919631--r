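#' Epinephrine model parameters
#'
#' Parameters of the epinephrine secretion/elimination model. Secretion is
#' the sum of a basal term `f1`, a glucose-dependent sigmoid `f2` (rising as
#' arterial glucose falls below `c3`) and an exercise-dependent sigmoid `f3`
#' (rising with relative oxygen uptake past `d3`), all in pmol per kg per
#' minute; the whole-body secretion rate is obtained by multiplying by body
#' weight and diluting into the volume of distribution `Vd`. The elimination
#' constant `k` is never set by the user: it is derived by
#' [elimination_constant()] so that the basal state (epinephrine `CE0`,
#' fasting glucose `cag_star`, no exercise) is an exact fixed point.
#'
#' None of these values are printed in the source study (which inherited
#' them from earlier whole-body models); the packaged reference
#' configuration uses physiologically plausible values chosen and
#' documented by this package. All estimation workflows are
#' simulate-then-recover and hold under any positive configuration.
#'
#' @param Vd Volume of distribution, litres.
#' @param f1 Basal secretion, pmol/kg/min.
#' @param c1,c2,c3 Glucose sigmoid: amplitude (pmol/kg/min), steepness
#'   (L/mmol) and midpoint (mmol/L).
#' @param d1,d2,d3 Exercise sigmoid: amplitude (pmol/kg/min), steepness
#'   (per %VO2max) and midpoint (%VO2max).
#' @param CE0 Basal plasma epinephrine, pM.
#' @param cag_star Fasting arterial glucose, mmol/L (default 5).
#' @return A list of class `epinephrine_parameters`.
#' @export
epinephrine_parameters <- function(Vd = 20, f1 = 8,
                                   c1 = 20, c2 = 1.5, c3 = 3,
                                   d1 = 30, d2 = 0.1, d3 = 40,
                                   CE0 = 200, cag_star = 5) {
  if (Vd <= 0 || c1 <= 0 || d1 <= 0 || CE0 <= 0 || cag_star <= 0) {
    stop("Vd, c1, d1, CE0 and cag_star must all be > 0", call. = FALSE)
  }
  structure(list(Vd = Vd, f1 = f1, c1 = c1, c2 = c2, c3 = c3,
                 d1 = d1, d2 = d2, d3 = d3, CE0 = CE0,
                 cag_star = cag_star),
            class = "epinephrine_parameters")
}

#' Insulin/glucagon controller parameters
#'
#' Parameters of the proportional hormone controller. Insulin and glucagon
#' obey multiplicative balance laws around their basal values `CI0`, `CG0`:
#' deviations of glucagon, insulin and (for insulin) epinephrine from basal
#' feed back through the couplings `k1`--`k5`; `D` is the common
#' degradation-like constant and the offset `h` is derived by
#' [calibrate_h()] so the all-basal state is a fixed point at fasting
#' glucose. `phi` and `psi` are glucose-dependent modulation hooks
#' (functions of arterial glucose in mmol/L), constant 1 by default.
#'
#' @param CI0 Basal insulin, pM.
#' @param CG0 Basal glucagon, pM.
#' @param k1,k2 Glucagon-equation couplings (glucagon, insulin), 1/pM/min.
#' @param k3,k4 Insulin-equation couplings (glucagon, insulin), 1/pM/min.
#' @param k5 Epinephrine-to-insulin coupling, 1/pM/min (>= 0). Default
#'   3.6e-5, the published estimate.
#' @param D Degradation constant, per minute (default 0.1).
#' @param phi,psi Modulation functions of arterial glucose; default
#'   constant 1.
#' @return A list of class `controller_parameters`.
#' @export
controller_parameters <- function(CI0 = 60, CG0 = 28.7,
                                  k1 = 2e-3, k2 = 1e-3,
                                  k3 = 1e-3, k4 = 1.4e-3,
                                  k5 = 3.6e-5, D = 0.1,
                                  phi = function(g) 1,
                                  psi = function(g) 1) {
  if (CI0 <= 0 || CG0 <= 0 || D <= 0) {
    stop("CI0, CG0 and D must be > 0", call. = FALSE)
  }
  if (k5 < 0) stop("k5 must be >= 0", call. = FALSE)
  stopifnot(is.function(phi), is.function(psi))
  structure(list(CI0 = CI0, CG0 = CG0, k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                 k5 = k5, D = D, phi = phi, psi = psi),
            class = "controller_parameters")
}

#' Full model parameter set
#'
#' Bundles the epinephrine and controller parameter blocks with a body
#' weight and derives the two calibration constants: the epinephrine
#' elimination constant `k` and the controller offset `h`. Derived values
#' are recomputed here and must never be set directly; call this again after
#' changing any field.
#'
#' @param epinephrine An [epinephrine_parameters()] block.
#' @param controller A [controller_parameters()] block.
#' @param bw Body weight in kg (used by the secretion term and by `k`).
#' @return A list of class `model_parameters` with elements `epinephrine`,
#'   `controller`, `bw`, and derived `k` (1/min) and `h`.
#' @export
model_parameters <- function(epinephrine = epinephrine_parameters(),
                             controller = controller_parameters(),
                             bw = 70) {
  stopifnot(inherits(epinephrine, "epinephrine_parameters"),
            inherits(controller, "controller_parameters"), bw > 0)
  k <- elimination_constant(bw, epinephrine)
  h <- calibrate_h(controller, epinephrine$cag_star)
  structure(list(epinephrine = epinephrine, controller = controller,
                 bw = bw, k = k, h = h),
            class = "model_parameters")
}

#' Reference model configuration
#'
#' The documented reference parameter set used throughout the package's
#' examples and synthetic studies: package-chosen plausible values for the
#' unpublished auxiliary constants, with the epinephrine-to-insulin coupling
#' `k5` at its published estimate of 3.6e-5 1/pM/min.
#'
#' @param bw Body weight in kg.
#' @param k5 Epinephrine-to-insulin coupling, 1/pM/min.
#' @return A `model_parameters` object.
#' @export
reference_parameters <- function(bw = 70, k5 = 3.6e-5) {
  model_parameters(epinephrine_parameters(),
                   controller_parameters(k5 = k5), bw = bw)
}

# numerically safe logistic: amp / (1 + exp(x)) without overflow
safe_logistic <- function(amp, x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- amp * exp(-x[pos]) / (1 + exp(-x[pos]))
  out[!pos] <- amp / (1 + exp(x[!pos]))
  out
}

#' Glucose-dependent epinephrine secretion term
#'
#' `f2(Ca_g) = c1 / (1 + exp(c2 * (Ca_g - c3)))`: secretion rises as arterial
#' glucose falls (hypoglycaemic counter-regulation). Overflow-safe for any
#' argument magnitude.
#'
#' @param ca_g Arterial glucose, mmol/L (vectorised, >= 0).
#' @param params An [epinephrine_parameters()] block.
#' @return Secretion contribution, pmol/kg/min, in (0, c1).
#' @export
f2_glucose_term <- function(ca_g, params) {
  stopifnot(inherits(params, "epinephrine_parameters"), all(ca_g >= 0))
  safe_logistic(params$c1, params$c2 * (ca_g - params$c3))
}

#' Exercise-dependent epinephrine secretion term
#'
#' `f3(PVO2max) = d1 / (1 + exp(d2 * (d3 - PVO2max)))`: secretion rises with
#' relative exercise intensity. Overflow-safe.
#'
#' @param pvo2max Suprabasal oxygen uptake, %VO2max (vectorised, >= 0).
#' @param params An [epinephrine_parameters()] block.
#' @return Secretion contribution, pmol/kg/min, in (0, d1).
#' @export
f3_exercise_term <- function(pvo2max, params) {
  stopifnot(inherits(params, "epinephrine_parameters"), all(pvo2max >= 0))
  safe_logistic(params$d1, params$d2 * (params$d3 - pvo2max))
}

#' Derived epinephrine elimination constant
#'
#' Imposes the resting steady state on the epinephrine balance: with
#' epinephrine at its basal value `CE0`, glucose at the fasting value
#' `cag_star` and no exercise, secretion and elimination cancel, giving
#' `k = BW / (Vd * CE0) * (f1 + f2(cag_star) + f3(0))`.
#'
#' @param bw Body weight, kg.
#' @param params An [epinephrine_parameters()] block.
#' @return Elimination constant `k`, per minute (> 0).
#' @export
elimination_constant <- function(bw, params) {
  stopifnot(inherits(params, "epinephrine_parameters"), bw > 0)
  f2s <- f2_glucose_term(params$cag_star, params)
  f3s <- f3_exercise_term(0, params)
  k <- bw / (params$Vd * params$CE0) * (params$f1 + f2s + f3s)
  if (!is.finite(k) || k <= 0) {
    stop("derived elimination constant is not positive; check f1 and the ",
         "sigmoid amplitudes", call. = FALSE)
  }
  k
}

#' Epinephrine concentration derivative
#'
#' `dCE/dt = (f1 + f2(Ca_g) + f3(PVO2max)) * BW / Vd - k * CE`.
#'
#' @param ce Plasma epinephrine, pM.
#' @param ca_g Arterial glucose, mmol/L.
#' @param pvo2max Suprabasal oxygen uptake, %VO2max.
#' @param bw Body weight, kg.
#' @param params An [epinephrine_parameters()] block.
#' @param k Elimination constant; derived from `bw` and `params` when
#'   omitted.
#' @return Derivative in pM per minute.
#' @export
epinephrine_derivative <- function(ce, ca_g, pvo2max, bw, params,
                                   k = elimination_constant(bw, params)) {
  stopifnot(all(ce >= 0))
  secretion <- (params$f1 + f2_glucose_term(ca_g, params) +
                  f3_exercise_term(pvo2max, params)) * bw / params$Vd
  secretion - k * ce
}

#' Derived controller offset h
#'
#' Imposes the resting steady state on the glucagon equation at basal
#' glucose: `h = D / phi(cag_basal)`. The insulin equation must share the
#' same fixed point, so the calibration additionally requires
#' `|psi(cag_basal) * h - D| < 1e-9` and fails loudly when the two
#' modulation functions disagree at basal glucose.
#'
#' @param params A [controller_parameters()] block.
#' @param cag_basal Basal arterial glucose, mmol/L (default 5).
#' @return The offset `h`.
#' @export
calibrate_h <- function(params, cag_basal = 5) {
  stopifnot(inherits(params, "controller_parameters"))
  phi0 <- params$phi(cag_basal)
  psi0 <- params$psi(cag_basal)
  if (!is.finite(phi0) || phi0 <= 0) {
    stop("phi(basal glucose) must be positive to calibrate h", call. = FALSE)
  }
  h <- params$D / phi0
  if (abs(psi0 * h - params$D) >= 1e-9) {
    stop("phi and psi disagree at basal glucose (phi = ", phi0, ", psi = ",
         psi0, "): the basal state cannot be a joint fixed point",
         call. = FALSE)
  }
  h
}

#' Insulin concentration derivative
#'
#' Multiplicative controller law:
#' `dCI/dt = CI * [psi * (h - k3*(CG - CG0) - k4*(CI - CI0)
#'  - k5*(CE - CE0)) - D]`.
#' Rising epinephrine (k5 > 0) suppresses insulin; the multiplicative form
#' preserves non-negativity.
#'
#' @param ci Insulin, pM.
#' @param cg Glucagon, pM.
#' @param ce Epinephrine, pM.
#' @param params A [controller_parameters()] block.
#' @param h Calibrated offset (see [calibrate_h()]).
#' @param ca_g Arterial glucose (argument of `psi`), mmol/L.
#' @param ce0 Basal epinephrine, pM (lives in the epinephrine parameter
#'   block; default matches [epinephrine_parameters()]).
#' @return Derivative in pM per minute.
#' @export
insulin_derivative <- function(ci, cg, ce, params, h = calibrate_h(params),
                               ca_g = 5, ce0 = 200) {
  stopifnot(all(ci >= 0))
  bracket <- h - params$k3 * (cg - params$CG0) -
    params$k4 * (ci - params$CI0) - params$k5 * (ce - ce0)
  ci * (params$psi(ca_g) * bracket - params$D)
}

#' Glucagon concentration derivative
#'
#' `dCG/dt = CG * [phi * (h - k1*(CG - CG0) - k2*(CI - CI0)) - D]`.
#' Falling insulin (k2 > 0) raises glucagon.
#'
#' @inheritParams insulin_derivative
#' @return Derivative in pM per minute.
#' @export
glucagon_derivative <- function(cg, ci, params, h = calibrate_h(params),
                                ca_g = 5) {
  stopifnot(all(cg >= 0))
  bracket <- h - params$k1 * (cg - params$CG0) -
    params$k2 * (ci - params$CI0)
  cg * (params$phi(ca_g) * bracket - params$D)
}
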