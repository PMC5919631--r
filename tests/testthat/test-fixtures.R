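test_that("the encoded study designs carry the tabulated values", {
  s3 <- get_study_protocol(3)
  expect_length(s3$protocol$segments, 1L)
  expect_equal(s3$protocol$segments[[1]]$tv, 60)
  expect_equal(s3$protocol$segments[[1]]$t_end -
                 s3$protocol$segments[[1]]$t_start, 60)
  expect_equal(s3$group$vo2max, 44)
  expect_equal(s3$baseline_min, 30)
  expect_equal(s3$recovery_min, 120)
  expect_equal(s3$group$n, 13L)
  expect_equal(s3$group$age_range, c(22, 28))
  expect_equal(s3$group$bw_range, c(66, 85))

  s1 <- get_study_protocol(1)
  expect_equal(vapply(s1$protocol$segments, `[[`, numeric(1), "tv"),
               c(38, 51, 64, 77))
  durs <- vapply(s1$protocol$segments,
                 function(s) s$t_end - s$t_start, numeric(1))
  expect_equal(durs, rep(8, 4))
  # the text variant uses 7-minute bouts
  s1b <- get_study_protocol(1, segment_minutes = 7)
  expect_equal(vapply(s1b$protocol$segments,
                      function(s) s$t_end - s$t_start, numeric(1)),
               rep(7, 4))
  # the final incremental bout is above the lactate threshold
  expect_true(s1$protocol$segments[[4]]$above_lt)
  expect_false(any(vapply(s1$protocol$segments[1:3], `[[`, logical(1),
                          "above_lt")))

  s5f <- get_study_protocol(5, group = 2)
  expect_equal(s5f$group$vo2max, 32)
  expect_equal(s5f$group$sex, "female")
  expect_equal(s5f$protocol$segments[[1]]$tv, 60)

  s6 <- get_study_protocol(6)
  expect_true("muscle_glycogen" %in% s6$unsupported_observables)

  expect_error(get_study_protocol(7), "valid ids")
  expect_error(get_study_protocol(1, segment_minutes = 6), "bout length")
})

test_that("encoded protocols round-trip through JSON unchanged", {
  for (id in 1:6) {
    prot <- get_study_protocol(id)$protocol
    f <- tempfile(fileext = ".json")
    jsonlite::write_json(exermet:::protocol_to_list(prot), f,
                         auto_unbox = TRUE, digits = NA)
    back <- exermet:::protocol_from_list_df(
      jsonlite::read_json(f, simplifyVector = TRUE))
    expect_equal(back, prot)
  }
})

test_that("extremal subjects enumerate the range corners", {
  s3 <- get_study_protocol(3)
  corners <- extremal_subjects(s3)
  expect_length(corners, 4L)   # 2 age levels x 2 body-weight levels
  bws <- sort(unique(vapply(corners, `[[`, numeric(1), "body_weight")))
  expect_equal(bws, c(66, 85))
  expect_true(all(vapply(corners, `[[`, numeric(1), "vo2max") == 44))

  # a degenerate range halves the corner count (study 4 heights aside,
  # its age range per group is non-degenerate; fabricate a degenerate one)
  s_deg <- s3
  s_deg$group$age_range <- c(25, 25)
  expect_length(extremal_subjects(s_deg), 2L)
})

test_that("corner trajectories bound the interior subject (envelope)", {
  s3 <- get_study_protocol(3)
  params_for <- function(bw) reference_parameters(bw = bw)
  settings <- simulation_settings(t_end = 120, output_grid = 5)
  corner_trajs <- lapply(extremal_subjects(s3), function(su) {
    simulate_protocol(su, s3$protocol, params_for(su$body_weight),
                      settings = settings)
  })
  mid <- suppressWarnings(subject_profile(
    "male", 25, mean(s3$group$bw_range), vo2max = s3$group$vo2max))
  interior <- simulate_protocol(mid, s3$protocol,
                                params_for(mid$body_weight),
                                settings = settings)
  for (col in c("ce_pM", "ci_pM", "cg_pM")) {
    mat <- sapply(corner_trajs, `[[`, col)
    lo <- apply(mat, 1, min) - 1e-9
    hi <- apply(mat, 1, max) + 1e-9
    expect_true(all(interior[[col]] >= lo & interior[[col]] <= hi))
  }
})

test_that("synthetic observations follow the constant-CV error model", {
  sc <- study3_scenario()
  times <- estimation_schedule()

  exact <- generate_observations(sc$traj, times, cv = 0)
  sim_ci <- approx(sc$traj$time_min, sc$traj$ci_pM, times)$y
  expect_identical(exact$insulin_obs, sim_ci)

  a <- generate_observations(sc$traj, times, cv = 0.04, seed = 99)
  b <- generate_observations(sc$traj, times, cv = 0.04, seed = 99)
  expect_identical(a$insulin_obs, b$insulin_obs)
  c2 <- generate_observations(sc$traj, times, cv = 0.04, seed = 100)
  expect_false(identical(a$insulin_obs, c2$insulin_obs))
  expect_true(all(a$insulin_obs > 0) && all(a$glucagon_obs > 0))

  # law of large numbers: empirical CV at one time point
  many <- replicate(4000, {
    generate_observations(sc$traj, times[8], cv = 0.04)$insulin_obs
  })
  emp_cv <- sd(many) / mean(many)
  expect_lt(abs(emp_cv - 0.04) / 0.04, 0.05)

  expect_error(generate_observations(sc$traj, c(-10, 0), cv = 0.04),
               "span")
})
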