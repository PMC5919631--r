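#' Subject profile
#'
#' Describes the person performing the exercise: gender, age, body weight,
#' cardiorespiratory fitness classification, and optionally a measured
#' maximal oxygen uptake that overrides the normative-table lookup.
#'
#' @param gender "male" or "female".
#' @param age Age in years (integer, 10--100). Values outside 20--40 trigger
#'   a warning: the exercise model was validated on young adults.
#' @param body_weight Body weight in kg (> 0).
#' @param fitness_status One of "poor", "fair", "good", "excellent",
#'   "superior". Ignored when `vo2max` is supplied.
#' @param vo2max Optional measured VO2max in ml O2 per kg per min; when
#'   present it takes precedence over the normative table.
#' @return An object of class `subject_profile`.
#' @examples
#' subject_profile("male", 25, 70, "good")
#' subject_profile("male", 25, 70, vo2max = 44)
#' @export
subject_profile <- function(gender, age, body_weight,
                            fitness_status = "good", vo2max = NULL) {
  gender <- match.arg(gender, c("male", "female"))
  fitness_status <- match.arg(fitness_status, fitness_levels())
  stopifnot(is.numeric(age), length(age) == 1L, is.finite(age))
  stopifnot(is.numeric(body_weight), length(body_weight) == 1L)
  if (body_weight <= 0) stop("body_weight must be > 0 kg", call. = FALSE)
  if (age < 10 || age > 100) {
    stop("age must lie in [10, 100] years", call. = FALSE)
  }
  if (age < 20 || age > 40) {
    warning("subject age ", age,
            " is outside the validated 20-40 year range", call. = FALSE)
  }
  if (!is.null(vo2max)) {
    stopifnot(is.numeric(vo2max), length(vo2max) == 1L)
    if (!is.finite(vo2max) || vo2max <= 0) {
      stop("vo2max override must be a positive number", call. = FALSE)
    }
  }
  structure(
    list(gender = gender, age = as.integer(age), body_weight = body_weight,
         fitness_status = fitness_status, vo2max = vo2max),
    class = "subject_profile")
}

fitness_levels <- function() {
  c("poor", "fair", "good", "excellent", "superior")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile> ", x$gender, ", ", x$age, " y, ",
      x$body_weight, " kg, fitness: ", x$fitness_status, sep = "")
  if (!is.null(x$vo2max)) cat(", VO2max override:", x$vo2max)
  cat("\n")
  invisible(x)
}

#' Normative VO2max table
#'
#' Loads a normative maximal-oxygen-uptake table keyed by gender, decadal age
#' bracket and fitness category. The packaged default
#' (`inst/extdata/vo2max_norms.csv`) carries reference values adapted from
#' standard normative cardiorespiratory-fitness classifications; it is
#' external reference data, not study-derived, and a measured VO2max should
#' be preferred whenever available (see [subject_profile()]).
#'
#' @param path CSV file with columns
#'   `gender,age_lo,age_hi,category,vo2max_ml_kg_min`. Default: the packaged
#'   table.
#' @return A data.frame of class `vo2max_table`.
#' @export
load_vo2max_table <- function(path = system.file("extdata",
                                                 "vo2max_norms.csv",
                                                 package = "exermet")) {
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("gender", "age_lo", "age_hi", "category", "vo2max_ml_kg_min")
  if (!all(need %in% names(tab))) {
    stop("normative table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(tab$vo2max_ml_kg_min <= 0) || anyNA(tab$vo2max_ml_kg_min)) {
    stop("normative VO2max values must be positive and complete",
         call. = FALSE)
  }
  # within each gender x bracket, values must increase with fitness level
  key <- interaction(tab$gender, tab$age_lo, drop = TRUE)
  for (g in split(tab, key)) {
    v <- g$vo2max_ml_kg_min[match(fitness_levels(), g$category)]
    if (anyNA(v) || any(diff(v) <= 0)) {
      stop("normative table must cover all five fitness categories with ",
           "strictly increasing VO2max (gender ", g$gender[1],
           ", bracket ", g$age_lo[1], "-", g$age_hi[1], ")", call. = FALSE)
    }
  }
  class(tab) <- c("vo2max_table", "data.frame")
  tab
}

#' Resolve a subject's maximal oxygen uptake
#'
#' Returns the subject's VO2max override when present, otherwise looks up the
#' normative table by gender, age bracket and fitness category. Ages outside
#' the table's bracket span are clamped to the nearest bracket.
#'
#' @param subject A [subject_profile()].
#' @param table A normative table from [load_vo2max_table()].
#' @return VO2max in ml O2 per kg per min (always > 0).
#' @export
resolve_vo2max <- function(subject, table = load_vo2max_table()) {
  stopifnot(inherits(subject, "subject_profile"))
  if (!is.null(subject$vo2max)) return(subject$vo2max)
  rows <- table[table$gender == subject$gender &
                  table$category == subject$fitness_status, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no normative entry for (", subject$gender, ", age ", subject$age,
         ", ", subject$fitness_status, ")", call. = FALSE)
  }
  age <- min(max(subject$age, min(rows$age_lo)), max(rows$age_hi))
  hit <- rows[rows$age_lo <= age & age <= rows$age_hi, , drop = FALSE]
  if (nrow(hit) != 1L) {
    stop("no normative entry for (", subject$gender, ", age ", subject$age,
         ", ", subject$fitness_status, ")", call. = FALSE)
  }
  hit$vo2max_ml_kg_min
}

#' Target oxygen consumption at a relative intensity
#'
#' Converts a relative exercise intensity Tv (in %VO2max) into the
#' steady-state oxygen consumption it demands: VO2 = Tv * VO2max / 100.
#' The model covers sub-maximal exercise only, so Tv is restricted to
#' \[0, 100\].
#'
#' @param tv Relative intensity in %VO2max.
#' @param vo2max Maximal oxygen uptake in ml O2 per kg per min.
#' @return Oxygen consumption in ml O2 per kg per min.
#' @export
target_vo2 <- function(tv, vo2max) {
  stopifnot(is.numeric(tv), is.numeric(vo2max))
  if (any(vo2max <= 0)) stop("vo2max must be > 0", call. = FALSE)
  if (any(tv < 0 | tv > 100)) {
    stop("tv must lie in [0, 100] %VO2max (sub-maximal exercise only)",
         call. = FALSE)
  }
  tv * vo2max / 100
}
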