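#' Write and read model parameter configurations
#'
#' Parameters round-trip through JSON with the two blocks (`epinephrine`,
#' `controller`) plus `bw`. A `derived` block (elimination constant `k`,
#' controller offset `h`) is emitted for the reader's information but never
#' read back: derived constants are always recomputed from the primary
#' fields. Modulation functions `phi`/`psi` serialize only in their constant
#' form.
#'
#' @param params A [model_parameters()] bundle.
#' @param path Output/input JSON file.
#' @return `read_parameters()` returns a `model_parameters` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  ctl <- params$controller
  phi0 <- ctl$phi(params$epinephrine$cag_star)
  psi0 <- ctl$psi(params$epinephrine$cag_star)
  obj <- list(
    epinephrine = unclass(params$epinephrine),
    controller = c(ctl[setdiff(names(ctl), c("phi", "psi"))],
                   list(phi_constant = phi0, psi_constant = psi0)),
    bw = params$bw,
    derived = list(k = params$k, h = params$h))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- do.call(epinephrine_parameters, obj$epinephrine)
  ctlf <- obj$controller
  phi0 <- if (!is.null(ctlf$phi_constant)) ctlf$phi_constant else 1
  psi0 <- if (!is.null(ctlf$psi_constant)) ctlf$psi_constant else 1
  ctlf <- ctlf[setdiff(names(ctlf), c("phi_constant", "psi_constant"))]
  ctl <- do.call(controller_parameters,
                 c(ctlf, list(phi = function(g) phi0,
                              psi = function(g) psi0)))
  model_parameters(ep, ctl, bw = if (!is.null(obj$bw)) obj$bw else 70)
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' Emits the absolute trajectory, its suprabasal variant and a sidecar
#' recording subject, protocol, solver settings, derived constants and seed.
#' Numeric columns are written at full double precision so the files
#' round-trip exactly.
#'
#' @param traj An `exermet_trajectory`.
#' @param path Base output path; `<path>.csv`, `<path>_suprabasal.csv` and
#'   `<path>_meta.json` are written.
#' @return Invisibly, the three file paths.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "exermet_trajectory"))
  fmt <- function(d) {
    out <- as.data.frame(lapply(d, function(x) {
      format(x, digits = 17, scientific = FALSE, trim = TRUE)
    }))
    names(out) <- names(d)
    out
  }
  f1 <- paste0(path, ".csv")
  f2 <- paste0(path, "_suprabasal.csv")
  f3 <- paste0(path, "_meta.json")
  utils::write.csv(fmt(as.data.frame(traj)), f1, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(fmt(as.data.frame(to_suprabasal(traj))), f2,
                   row.names = FALSE, quote = FALSE)
  meta <- attr(traj, "meta")
  side <- list(
    subject = subject_to_list(meta$subject),
    protocol = protocol_to_list(meta$protocol),
    settings = unclass(meta$settings),
    derived = list(k = meta$k, h = meta$h, k5 = meta$k5),
    basal = as.list(attr(traj, "basal")))
  jsonlite::write_json(side, f3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(f1, f2, f3))
}

protocol_to_list <- function(protocol) {
  list(modality = protocol$modality,
       vo2_rest = protocol$vo2_rest,
       segments = lapply(protocol$segments, function(s) {
         list(t_start_min = s$t_start, t_end_min = s$t_end,
              tv_percent = s$tv, above_lt = s$above_lt)
       }))
}

protocol_from_list <- function(lst) {
  segs <- lapply(lst$segments, function(s) {
    exercise_segment(s$t_start_min, s$t_end_min, s$tv_percent,
                     above_lt = isTRUE(s$above_lt))
  })
  exercise_protocol(segs,
                    modality = if (!is.null(lst$modality)) lst$modality
                    else "leg_cycling",
                    vo2_rest = if (!is.null(lst$vo2_rest)) lst$vo2_rest
                    else 3.5)
}

subject_to_list <- function(subject) {
  list(gender = subject$gender, age = subject$age,
       body_weight_kg = subject$body_weight,
       fitness_status = subject$fitness_status,
       vo2max = subject$vo2max)
}

subject_from_list <- function(lst) {
  if (is.null(lst$body_weight_kg)) lst$body_weight_kg <- lst$body_weight
  subject_profile(lst$gender, lst$age, lst$body_weight_kg,
                  fitness_status = if (!is.null(lst$fitness_status))
                    lst$fitness_status else "good",
                  vo2max = lst$vo2max)
}

#' Write and read observation sets
#'
#' Observations travel as a CSV with columns
#' `time_min,insulin_pM,glucagon_pM` plus a JSON sidecar carrying the
#' measurement CV and the subject/protocol metadata needed to re-simulate.
#'
#' @param obs An [observation_set()].
#' @param path Base path; `<path>.csv` and `<path>_meta.json` are written.
#' @return `read_observations()` returns an `observation_set`.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  d <- data.frame(time_min = obs$times, insulin_pM = obs$insulin_obs,
                  glucagon_pM = obs$glucagon_obs)
  d[] <- lapply(d, function(x) format(x, digits = 17, scientific = FALSE,
                                      trim = TRUE))
  utils::write.csv(d, paste0(path, ".csv"), row.names = FALSE,
                   quote = FALSE)
  side <- list(cv = obs$cv,
               subject = if (!is.null(obs$subject))
                 subject_to_list(obs$subject),
               protocol = if (!is.null(obs$protocol))
                 protocol_to_list(obs$protocol))
  jsonlite::write_json(side, paste0(path, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_observations
#' @param csv_path Path to the observations CSV; the sidecar is looked up
#'   by replacing `.csv` with `_meta.json` (or pass `sidecar_path`).
#' @param sidecar_path Optional explicit sidecar path.
#' @export
read_observations <- function(csv_path, sidecar_path = NULL) {
  d <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("time_min", "insulin_pM", "glucagon_pM")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0L) {
    stop("observations CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    bad <- which(!is.finite(d[[col]]))
    if (length(bad) > 0L) {
      stop("non-numeric or missing value in column '", col, "', row ",
           bad[1], call. = FALSE)
    }
  }
  if (is.null(sidecar_path)) {
    sidecar_path <- sub("\\.csv$", "_meta.json", csv_path)
  }
  cv <- 0.04
  subject <- NULL
  protocol <- NULL
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(side$cv)) cv <- side$cv
    if (!is.null(side$subject)) subject <- subject_from_list(side$subject)
    if (!is.null(side$protocol)) {
      protocol <- protocol_from_list_df(side$protocol)
    }
  }
  observation_set(d$time_min, d$insulin_pM, d$glucagon_pM, cv = cv,
                  subject = subject, protocol = protocol)
}

# jsonlite::read_json(simplifyVector = TRUE) turns the segment list into a
# data.frame; accept both shapes
protocol_from_list_df <- function(lst) {
  if (is.data.frame(lst$segments)) {
    lst$segments <- lapply(seq_len(nrow(lst$segments)), function(i) {
      as.list(lst$segments[i, ])
    })
  }
  protocol_from_list(lst)
}

run_config_schema <- function() {
  list(
    subject = c("gender", "age", "body_weight_kg", "fitness_status",
                "vo2max"),
    protocol = c("modality", "vo2_rest", "segments", "study",
                 "tv_percent", "start_min", "end_min"),
    glucose = c("type", "level", "csv", "a", "b"),
    settings = c("t0", "t_end", "output_grid", "rel_tol", "abs_tol",
                 "seed"),
    params_file = NULL,
    out = NULL)
}

#' Validate a run configuration
#'
#' Checks a simulate/fit/sweep configuration against the package's config
#' schema before any computation: unknown top-level or nested keys are
#' rejected with the offending field path, and required blocks are checked
#' for presence.
#'
#' @param config A named list (usually from JSON).
#' @return The validated config, invisibly; stops with a field path on
#'   violation.
#' @export
validate_run_config <- function(config) {
  schema <- run_config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0L) {
    stop("unknown config key: ", unknown[1], call. = FALSE)
  }
  for (blk in c("subject", "protocol", "glucose", "settings")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), schema[[blk]])
      if (length(bad) > 0L) {
        stop("unknown config key: ", blk, ".", bad[1], call. = FALSE)
      }
    }
  }
  if (is.null(config$subject)) {
    stop("config is missing required block: subject", call. = FALSE)
  }
  for (fld in c("gender", "age", "body_weight_kg")) {
    if (is.null(config$subject[[fld]])) {
      stop("config is missing required field: subject.", fld,
           call. = FALSE)
    }
  }
  invisible(config)
}
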