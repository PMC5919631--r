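test_that("a rest-only protocol stays at basal for 180 minutes", {
  traj <- simulate_protocol(ref_subject(), exercise_protocol(list()),
                            reference_parameters(bw = 70),
                            settings = simulation_settings(t_end = 180))
  basal <- attr(traj, "basal")
  for (col in c("ce_pM", "ci_pM", "cg_pM")) {
    expect_true(all(abs(traj[[col]] - basal[[col]]) / basal[[col]] < 1e-8))
  }
  expect_true(all(abs(traj$pvo2max_pct) < 1e-8))
})

test_that("study-3 exercise gives the expected hormone excursions and
          recovery", {
  sc <- study3_scenario()
  traj <- sc$traj
  ex <- traj$time_min > 30 & traj$time_min <= 90
  expect_true(all(diff(traj$ci_pM[ex]) < 0))   # insulin falls
  expect_true(all(diff(traj$cg_pM[ex]) > 0))   # glucagon rises
  expect_true(all(diff(traj$ce_pM[ex]) > 0))   # epinephrine rises
  # all states return toward basal after exercise
  basal <- attr(traj, "basal")
  final <- traj[nrow(traj), ]
  expect_lt(abs(final$ci_pM - basal["ci_pM"]) / basal["ci_pM"], 0.05)
  expect_lt(abs(final$cg_pM - basal["cg_pM"]) / basal["cg_pM"], 0.05)
  expect_lt(abs(final$ce_pM - basal["ce_pM"]) / basal["ce_pM"], 0.05)
})

test_that("suprabasal view subtracts basals and is invertible", {
  sc <- study3_scenario()
  supra <- to_suprabasal(sc$traj)
  basal <- attr(sc$traj, "basal")
  expect_equal(supra$ce_pM + basal["ce_pM"], sc$traj$ce_pM,
               ignore_attr = TRUE)
  expect_identical(supra$pvo2max_pct, sc$traj$pvo2max_pct)
  # at rest (t <= 30) the suprabasal epinephrine is numerically zero
  expect_true(all(abs(supra$ce_pM[supra$time_min <= 30]) < 1e-6))
})

test_that("solution is insensitive to tolerances and output grid", {
  subj <- ref_subject()
  prot <- get_study_protocol(3)$protocol
  params <- reference_parameters(bw = 70)
  tight <- simulate_protocol(subj, prot, params,
                             settings = simulation_settings(
                               t_end = 210, rel_tol = 5e-9,
                               abs_tol = 5e-11))
  sc <- study3_scenario()
  final_a <- unlist(sc$traj[nrow(sc$traj), -1])
  final_b <- unlist(tight[nrow(tight), -1])
  expect_true(all(abs(final_a - final_b) /
                    pmax(abs(final_a), 1e-6) < 1e-6))

  fine <- simulate_protocol(subj, prot, params,
                            settings = simulation_settings(
                              t_end = 210, output_grid = 0.5))
  shared <- match(sc$traj$time_min, fine$time_min)
  expect_true(all(abs(fine$ci_pM[shared] - sc$traj$ci_pM) < 1e-6))
})

test_that("simulation is deterministic", {
  subj <- ref_subject()
  prot <- get_study_protocol(3)$protocol
  params <- reference_parameters(bw = 70)
  a <- simulate_protocol(subj, prot, params)
  b <- simulate_protocol(subj, prot, params)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("parameter sweeps recompute derived constants and preserve
          ordering properties", {
  subj <- ref_subject()
  prot <- get_study_protocol(3)$protocol
  params <- reference_parameters(bw = 70)
  settings <- simulation_settings(t_end = 120, output_grid = 2)

  # larger Tv gives pointwise-larger suprabasal epinephrine
  tv_sweep <- sweep_parameter("Tv", c(30, 60), subj, prot, params,
                              settings = settings)
  e30 <- to_suprabasal(tv_sweep[["Tv=30"]])$ce_pM
  e60 <- to_suprabasal(tv_sweep[["Tv=60"]])$ce_pM
  on <- tv_sweep[["Tv=30"]]$time_min > 30
  expect_true(all(e60[on] > e30[on]))

  # k5 = 0 decouples insulin from exercise; the default shows a decline
  k5_sweep <- sweep_parameter("k5", c(0, 3.6e-5), subj, prot, params,
                              settings = settings)
  ci0 <- k5_sweep[["k5=0"]]$ci_pM
  expect_true(all(abs(ci0 - 60) < 1e-8))
  expect_lt(min(k5_sweep[["k5=3.6e-05"]]$ci_pM), 55)

  # BW sweep rebuilds the elimination constant per run
  bw_sweep <- sweep_parameter("BW", c(60, 90), subj, prot, params,
                              settings = settings)
  expect_equal(attr(bw_sweep[["BW=90"]], "meta")$k,
               elimination_constant(90, params$epinephrine))

  # a singleton sweep equals a plain simulation
  single <- sweep_parameter("Tv", 60, subj, prot, params,
                            settings = settings)[[1]]
  direct <- simulate_protocol(subj, prot, params, settings = settings)
  expect_equal(as.data.frame(single), as.data.frame(direct))

  expect_error(sweep_parameter("Vd", 10, subj, prot, params), "sweepables")
})

test_that("the closed-loop toy glucose provider feeds back on the
          controller", {
  subj <- ref_subject()
  prot <- get_study_protocol(3)$protocol
  params <- reference_parameters(bw = 70)
  traj <- simulate_protocol(subj, prot, params,
                            glucose = glucose_feedback(),
                            settings = simulation_settings(t_end = 150,
                                                           output_grid = 2))
  expect_true(all(is.finite(traj$cag_mM)) && all(traj$cag_mM > 0))
  # exercise lowers glucose in the toy loop
  expect_lt(min(traj$cag_mM), 5)
  # tabulated provider reproduces its own input
  gl <- glucose_timeseries(c(0, 60, 120), c(5, 4.5, 5))
  traj2 <- simulate_protocol(subj, exercise_protocol(list()), params,
                             glucose = gl,
                             settings = simulation_settings(t_end = 120,
                                                            output_grid = 30))
  expect_equal(traj2$cag_mM[traj2$time_min == 60], 4.5)
})

test_that("simulation guards inconsistent inputs", {
  subj <- ref_subject()
  params80 <- reference_parameters(bw = 80)
  expect_error(simulate_protocol(subj, exercise_protocol(list()), params80),
               "rebuild model_parameters")
  above <- exercise_protocol(list(exercise_segment(0, 10, 90,
                                                   above_lt = TRUE)))
  expect_warning(simulate_protocol(subj, above,
                                   reference_parameters(bw = 70),
                                   settings = simulation_settings(
                                     t_end = 30)),
                 "lactate threshold")
})
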