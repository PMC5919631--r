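#' Encoded validation-study protocols
#'
#' Six published exercise-study designs (cycle-ergometer, fasted healthy
#' subjects, below the lactate threshold) are encoded as fixtures so every
#' layer of the package can be exercised without external data:
#'
#' 1. Incremental exercise, four 8-min bouts at Tv 38, 51, 64, 77 %VO2max;
#'    two groups (trained VO2max 50, untrained VO2max 35). The source table
#'    lists 8-min bouts while the accompanying text describes 7-min bouts;
#'    the table value is the default and `segment_minutes = 7` selects the
#'    text variant. The final bout lies above the lactate threshold and is
#'    tagged `above_lt`.
#' 2. 40 min at Tv 60 (8 males, VO2max 46).
#' 3. 60 min at Tv 60 (13 males, VO2max 44), 30-min baseline before onset
#'    and 120-min recovery after — the design used for estimating the
#'    epinephrine-to-insulin coupling.
#' 4. 120 min at Tv 40, untrained (VO2max 39) and trained (VO2max 58)
#'    groups.
#' 5. 90 min at Tv 60, male (VO2max 42) and female (VO2max 32) variants.
#' 6. 180 min at Tv 31 plus a separate 120 min at Tv 64 (VO2max 61); its
#'    muscle-glycogen observable needs an organ-level metabolic model and is
#'    marked unsupported here.
#'
#' @param study_id Integer 1--6.
#' @param group For multi-group studies, which subject group/variant
#'   (default the first).
#' @param segment_minutes Bout length for study 1 (8, the tabulated value,
#'   or 7, the text variant).
#' @return A list of class `study_protocol` with fields `study_id`,
#'   `groups` (subject ranges), `protocol` (an [exercise_protocol()]),
#'   `baseline_min`, `recovery_min`, `observables`,
#'   `unsupported_observables`.
#' @export
get_study_protocol <- function(study_id, group = 1L, segment_minutes = 8) {
  studies <- study_table()
  if (!is.numeric(study_id) || length(study_id) != 1L ||
      !study_id %in% seq_along(studies)) {
    stop("unknown study id ", study_id, "; valid ids: ",
         paste(seq_along(studies), collapse = ", "), call. = FALSE)
  }
  st <- studies[[study_id]]
  if (study_id == 1L) {
    if (!segment_minutes %in% c(7, 8)) {
      stop("study 1 bout length must be 8 (tabulated) or 7 (text variant)",
           call. = FALSE)
    }
    dur <- segment_minutes
    tvs <- c(38, 51, 64, 77)
    start <- st$baseline_min
    segs <- lapply(seq_along(tvs), function(i) {
      exercise_segment(start + (i - 1) * dur, start + i * dur, tvs[i],
                       above_lt = (i == length(tvs)))
    })
    st$protocol <- exercise_protocol(segs)
  }
  if (group < 1L || group > length(st$groups)) {
    stop("study ", study_id, " has ", length(st$groups), " group(s)",
         call. = FALSE)
  }
  st$group <- st$groups[[group]]
  structure(st, class = "study_protocol")
}

# Subject ranges and designs of the six encoded studies. Heights are stored
# for provenance but no model equation consumes them.
study_table <- function() {
  seg <- function(t0, t1, tv, above_lt = FALSE) {
    exercise_segment(t0, t1, tv, above_lt)
  }
  grp <- function(sex, n, age, bw, height, vo2max, label = sex) {
    list(sex = sex, n = n, age_range = age, bw_range = bw,
         height_range = height, vo2max = vo2max, label = label)
  }
  list(
    list(study_id = 1L, baseline_min = 10, recovery_min = 30,
         groups = list(
           grp("male", 6L, c(28, 30), c(70, 78), c(1.80, 1.88), 35,
               "untrained"),
           grp("male", 6L, c(25, 27), c(65, 73), c(1.72, 1.78), 50,
               "trained")),
         protocol = NULL,  # built per segment_minutes
         observables = c("glucagon", "epinephrine", "insulin", "glucose",
                         "glycerol", "lactate", "ffa", "alanine"),
         unsupported_observables = character(0)),
    list(study_id = 2L, baseline_min = 10, recovery_min = 30,
         groups = list(grp("male", 8L, c(23, 40), c(71, 89),
                           c(1.74, 1.88), 46)),
         protocol = exercise_protocol(list(seg(10, 50, 60))),
         observables = c("glucagon", "glucose", "glycerol", "lactate",
                         "ffa"),
         unsupported_observables = character(0)),
    list(study_id = 3L, baseline_min = 30, recovery_min = 120,
         groups = list(grp("male", 13L, c(22, 28), c(66, 85),
                           c(1.80, 1.80), 44)),
         protocol = exercise_protocol(list(seg(30, 90, 60))),
         observables = c("insulin", "glucagon", "epinephrine", "ffa"),
         unsupported_observables = character(0)),
    list(study_id = 4L, baseline_min = 10, recovery_min = 30,
         groups = list(
           grp("male", 7L, c(21, 23), c(69, 82), c(1.80, 1.80), 39,
               "untrained"),
           grp("male", 7L, c(25, 27), c(69, 82), c(1.80, 1.80), 58,
               "trained")),
         protocol = exercise_protocol(list(seg(10, 130, 40))),
         observables = c("lactate"),
         unsupported_observables = character(0)),
    list(study_id = 5L, baseline_min = 10, recovery_min = 30,
         groups = list(
           grp("male", 8L, c(21, 23), c(76, 81), c(1.73, 1.79), 42),
           grp("female", 8L, c(21, 23), c(64, 70), c(1.64, 1.66), 32)),
         protocol = exercise_protocol(list(seg(10, 100, 60))),
         observables = c("epinephrine", "glycerol", "lactate", "ffa"),
         unsupported_observables = character(0)),
    list(study_id = 6L, baseline_min = 10, recovery_min = 30,
         groups = list(grp("male", 13L, c(20, 30), c(64, 84),
                           c(1.69, 1.93), 61)),
         protocol = exercise_protocol(list(seg(10, 190, 31))),
         alternate_protocol = exercise_protocol(list(seg(10, 130, 64))),
         observables = character(0),
         unsupported_observables = c("muscle_glycogen")))
}

#' @export
print.study_protocol <- function(x, ...) {
  cat("<study_protocol> study", x$study_id, "-", length(x$groups),
      "group(s)\n")
  print(x$protocol)
  invisible(x)
}

#' Extremal subjects of a study's ranges
#'
#' Builds the corner subjects of a study group's (age, body-weight) ranges —
#' every min/max combination — for envelope ("worst-case band") simulations.
#' Degenerate ranges (lo = hi) contribute a single level, halving the corner
#' count.
#'
#' @param study A `study_protocol` from [get_study_protocol()].
#' @param group Group index (default: the group selected at construction).
#' @return A list of [subject_profile()]s with the group's VO2max as
#'   override.
#' @export
extremal_subjects <- function(study, group = NULL) {
  stopifnot(inherits(study, "study_protocol"))
  g <- if (is.null(group)) study$group else study$groups[[group]]
  ages <- unique(g$age_range)
  bws <- unique(g$bw_range)
  corners <- expand.grid(age = ages, bw = bws)
  lapply(seq_len(nrow(corners)), function(i) {
    suppressWarnings(subject_profile(g$sex, corners$age[i], corners$bw[i],
                                     vo2max = g$vo2max))
  })
}

#' Generate synthetic noisy hormone observations
#'
#' Samples a simulated trajectory at given times and perturbs insulin and
#' glucagon with multiplicative Gaussian noise, `observed = simulated *
#' (1 + cv * z)` with z standard normal per point — the constant-percent-CV
#' error model. Non-positive draws are re-sampled so observations stay
#' positive. Reproducible under `seed`.
#'
#' @param traj An `exermet_trajectory`.
#' @param times Sampling times, minutes, within the trajectory span.
#' @param cv Fractional coefficient of variation (default 0.04); `cv = 0`
#'   returns the noise-free samples.
#' @param seed Integer seed (optional).
#' @return An [observation_set()] carrying the trajectory's subject and
#'   protocol metadata.
#' @export
generate_observations <- function(traj, times, cv = 0.04, seed = NULL) {
  stopifnot(inherits(traj, "exermet_trajectory"))
  if (min(times) < min(traj$time_min) || max(times) > max(traj$time_min)) {
    stop("sampling times must lie within the trajectory span [",
         min(traj$time_min), ", ", max(traj$time_min), "] min",
         call. = FALSE)
  }
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ci <- stats::approx(traj$time_min, traj$ci_pM, times)$y
  cg <- stats::approx(traj$time_min, traj$cg_pM, times)$y
  noisy <- function(x) {
    if (cv == 0) return(x)
    y <- x * (1 + cv * stats::rnorm(length(x)))
    while (any(bad <- y <= 0)) {
      y[bad] <- x[bad] * (1 + cv * stats::rnorm(sum(bad)))
    }
    y
  }
  meta <- attr(traj, "meta")
  observation_set(times, noisy(ci), noisy(cg),
                  cv = if (cv > 0) cv else 0.04,
                  subject = meta$subject, protocol = meta$protocol)
}

#' Sampling schedule of the estimation design
#'
#' The coupling-estimation design samples every 10 minutes from 30 minutes
#' before exercise onset to 180 minutes after it (the published study's
#' exact schedule is not printed).
#'
#' @param onset_min Exercise onset on the simulation clock (default 30, the
#'   study-3 baseline).
#' @param spacing_min Sampling interval (default 10).
#' @return Numeric vector of times in minutes.
#' @export
estimation_schedule <- function(onset_min = 30, spacing_min = 10) {
  seq(onset_min - 30, onset_min + 180, by = spacing_min)
}
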