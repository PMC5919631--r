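test_that("secretion sigmoids have the stated midpoints and saturations", {
  ep <- epinephrine_parameters()
  expect_equal(f2_glucose_term(ep$c3, ep), ep$c1 / 2)
  expect_equal(f3_exercise_term(ep$d3, ep), ep$d1 / 2)
  expect_equal(f2_glucose_term(1e6, ep), 0)
  expect_equal(f3_exercise_term(1e6, ep), ep$d1)
  # rest values used by the calibration
  expect_equal(f2_glucose_term(5, ep),
               ep$c1 / (1 + exp(ep$c2 * (5 - ep$c3))))
  expect_equal(f3_exercise_term(0, ep),
               ep$d1 / (1 + exp(ep$d2 * ep$d3)))
})

test_that("sigmoids are overflow-safe, monotone and bounded", {
  steep <- epinephrine_parameters(c2 = 500, d2 = 500)
  huge <- c(0, 1, 1e3, 1e6)
  expect_true(all(is.finite(f2_glucose_term(huge, steep))))
  expect_true(all(is.finite(f3_exercise_term(huge, steep))))
  set.seed(51)
  for (i in 1:10) {
    ep <- epinephrine_parameters(c1 = runif(1, 1, 50), c2 = runif(1, 0.1, 5),
                                 c3 = runif(1, 1, 6), d1 = runif(1, 1, 50),
                                 d2 = runif(1, 0.01, 1),
                                 d3 = runif(1, 10, 80))
    # grids chosen so the sigmoid argument stays within +/-16, where the
    # strict bounds are representable in double precision
    g <- ep$c3 + seq(-16, 16, by = 2) / ep$c2
    g <- g[g >= 0]
    f2 <- f2_glucose_term(g, ep)
    expect_true(all(diff(f2) < 0))          # strictly decreasing in glucose
    expect_true(all(f2 > 0 & f2 < ep$c1))
    pv <- ep$d3 + seq(-16, 16, by = 2) / ep$d2
    pv <- pv[pv >= 0]
    f3 <- f3_exercise_term(pv, ep)
    expect_true(all(diff(f3) > 0))          # strictly increasing in PVO2max
    expect_true(all(f3 > 0 & f3 < ep$d1))
  }
})

test_that("derived elimination constant makes the rest state a fixed point
          and matches independent hand arithmetic", {
  ep <- epinephrine_parameters()
  bw <- 70
  k <- elimination_constant(bw, ep)

  # independent evaluation of the printed formula, term by term
  f2_star <- 20 / (1 + exp(1.5 * (5 - 3)))
  f3_star <- 30 / (1 + exp(0.1 * 40))
  expect_equal(k, 70 / (20 * 200) * (8 + f2_star + f3_star),
               tolerance = 1e-14)

  # by construction: zero derivative at the calibrated rest state
  expect_equal(epinephrine_derivative(ep$CE0, 5, 0, bw, ep, k = k), 0,
               tolerance = 1e-12)
  # linear in body weight
  expect_equal(elimination_constant(2 * bw, ep), 2 * k)
  # exercise pushes epinephrine up from rest; zero state has positive source
  expect_gt(epinephrine_derivative(ep$CE0, 5, 30, bw, ep, k = k), 0)
  expect_gt(epinephrine_derivative(0, 5, 0, bw, ep, k = k), 0)
})

test_that("controller offset calibration enforces the joint fixed point", {
  expect_equal(calibrate_h(controller_parameters()), 0.1)
  half <- controller_parameters(phi = function(g) 2, psi = function(g) 2)
  expect_equal(calibrate_h(half), 0.05)
  bad <- controller_parameters(phi = function(g) 1, psi = function(g) 1.5)
  expect_error(calibrate_h(bad), "fixed point")
})

test_that("insulin and glucagon derivatives have the controller's signs", {
  ctl <- controller_parameters()
  h <- calibrate_h(ctl)
  ce0 <- 200
  # calibrated basal state is a fixed point
  expect_equal(insulin_derivative(ctl$CI0, ctl$CG0, ce0, ctl, h, ce0 = ce0),
               0, tolerance = 1e-14)
  expect_equal(glucagon_derivative(ctl$CG0, ctl$CI0, ctl, h), 0,
               tolerance = 1e-14)
  # raised epinephrine suppresses insulin
  expect_lt(insulin_derivative(ctl$CI0, ctl$CG0, ce0 + 300, ctl, h,
                               ce0 = ce0), 0)
  # lowered insulin raises glucagon
  expect_gt(glucagon_derivative(ctl$CG0, ctl$CI0 - 20, ctl, h), 0)
  # multiplicative form: zero concentration stays zero
  expect_identical(insulin_derivative(0, ctl$CG0, ce0, ctl, h, ce0 = ce0), 0)
  expect_identical(glucagon_derivative(0, ctl$CI0, ctl, h), 0)
})

test_that("the all-basal state is a fixed point of the full subsystem", {
  params <- reference_parameters(bw = 70)
  ep <- params$epinephrine
  ctl <- params$controller
  derivs <- c(
    pvo2max_derivative(0, 0),
    epinephrine_derivative(ep$CE0, ep$cag_star, 0, 70, ep, k = params$k),
    insulin_derivative(ctl$CI0, ctl$CG0, ep$CE0, ctl, params$h,
                       ca_g = ep$cag_star, ce0 = ep$CE0),
    glucagon_derivative(ctl$CG0, ctl$CI0, ctl, params$h,
                        ca_g = ep$cag_star))
  expect_true(all(abs(derivs) < 1e-10))
})

test_that("parameter configurations round-trip through JSON", {
  params <- model_parameters(
    epinephrine_parameters(Vd = 18, d1 = 25),
    controller_parameters(k5 = 2e-5, CI0 = 65), bw = 80)
  f <- tempfile(fileext = ".json")
  write_parameters(params, f)
  back <- read_parameters(f)
  expect_equal(back$epinephrine, params$epinephrine)
  expect_equal(back$bw, params$bw)
  expect_equal(back$k, params$k)
  expect_equal(back$h, params$h)
  ctl_fields <- setdiff(names(params$controller), c("phi", "psi"))
  expect_equal(back$controller[ctl_fields], params$controller[ctl_fields])
  # the packaged reference configuration equals the in-code constructor
  shipped <- read_parameters(system.file("extdata", "reference_config.json",
                                         package = "exermet"))
  ref <- reference_parameters()
  expect_equal(shipped$epinephrine, ref$epinephrine)
  expect_equal(shipped$controller[ctl_fields], ref$controller[ctl_fields])
  expect_equal(shipped$k, ref$k)
})
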