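#' Run the model over a range of years
#'
#' Iterates the cohort one year at a time, rebuilding the transition matrix
#' each year from the curve values at that year. Year t's flux tally is
#' computed from the state at the start of year t; the state column holds
#' the start-of-year occupancy. 1982 corresponds to year index 0 on the
#' curves; indices beyond the curve horizon are held constant at the horizon
#' value when `extend = TRUE`.
#'
#' @param params a [parameter_set()].
#' @param curves a [curve_set()].
#' @param years integer vector of consecutive calendar years (e.g.
#'   `1982:2013`).
#' @param initial a [state_vector()] for the first year; defaults to the
#'   steady state at the year-0 curve values.
#' @param year0 calendar year mapped to curve index 0.
#' @param extend hold curves constant past their horizon (projections).
#' @return An object of class `melmark_trajectory`: a data frame with one
#'   row per year, the eight state occupancies (start of year) and the six
#'   flux tallies (per 100,000).
#' @export
run_trajectory <- function(params, curves, years, initial = NULL,
                           year0 = 1982L, extend = FALSE) {
  stopifnot(inherits(params, "parameter_set"), inherits(curves, "curve_set"))
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be consecutive")
  idx <- years - year0
  I_t <- evaluate_curve(curves$I, idx, extend = extend)
  D_t <- evaluate_curve(curves$D, idx, extend = extend)
  O_t <- evaluate_curve(curves$O, idx, extend = extend)
  run_schedule(params, years, I_t, D_t, O_t, initial = initial)
}

# core runner on explicit per-year schedules (also used by scenarios)
run_schedule <- function(params, years, I_t, D_t, O_t = rep(0, length(years)),
                         q_t = rep(params$q, length(years)), initial = NULL) {
  n <- length(years)
  stopifnot(length(I_t) == n, length(D_t) == n, length(O_t) == n,
            length(q_t) == n)
  if (is.null(initial))
    initial <- steady_state(params, I_t[1], D_t[1], method = "solve")
  if (!inherits(initial, "state_vector")) initial <- state_vector(initial)

  occ <- matrix(NA_real_, n, 8, dimnames = list(NULL, model_states))
  tal <- matrix(NA_real_, n, 6, dimnames = list(NULL,
    c("stage1_diagnoses", "stage23_diagnoses", "stage4_diagnoses",
      "overdiagnoses", "melanoma_deaths", "other_deaths")))
  st <- initial
  for (k in seq_len(n)) {
    pk <- if (q_t[k] != params$q) update_parameters(params, q = q_t[k]) else params
    M <- build_transition_matrix(pk, I_t[k], D_t[k], O_t[k])
    occ[k, ] <- st
    out <- step_cohort(st, M)
    tal[k, ] <- out$tally
    st <- out$state
  }
  res <- data.frame(year = years, occ, tal)
  structure(res, class = c("melmark_trajectory", "data.frame"),
            params = params, final_state = st)
}

#' Annual output series of a trajectory
#'
#' Converts a trajectory's flux tallies into the model's reporting series,
#' per 100,000: diagnostic incidence (diagnoses of all three stages plus
#' over-diagnoses), melanoma mortality, all-cause mortality, and the
#' prevalence of diagnosed Stage 1 disease.
#'
#' @param traj a [run_trajectory()] result.
#' @return A list of four [annual_series()]: `incidence`, `mortality`,
#'   `all_cause_mortality`, `prevalence_diag_stage1`.
#' @export
annual_outputs <- function(traj) {
  stopifnot(inherits(traj, "melmark_trajectory"), nrow(traj) > 0L)
  inc <- traj$stage1_diagnoses + traj$stage23_diagnoses +
    traj$stage4_diagnoses + traj$overdiagnoses
  list(
    incidence = annual_series(traj$year, inc),
    mortality = annual_series(traj$year, traj$melanoma_deaths),
    all_cause_mortality = annual_series(traj$year,
                                        traj$melanoma_deaths + traj$other_deaths),
    prevalence_diag_stage1 = annual_series(traj$year, traj$diag_stage1 * POP)
  )
}

#' Export a trajectory as CSV
#'
#' Columns: year, the eight state occupancies, the six flux tallies.
#'
#' @param traj a [run_trajectory()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "melmark_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
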