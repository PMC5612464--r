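#' Specify a counterfactual scenario
#'
#' A scenario is a policy overlay on a calibrated model: a detection-curve
#' policy, an optional change of the Stage 4 death probability `q` from a
#' stated year, and an optional over-diagnosis ramp. Policies:
#' \describe{
#'   \item{`fitted`}{D(t) follows its fitted 1982-2013 trajectory (window
#'     must end by 2013).}
#'   \item{`frozen`}{D held constant at `D_value` (default the model's
#'     `D0`) for the whole simulation, 1982 onward.}
#'   \item{`maintain`}{fitted to 2013, then held at its 2013 value.}
#'   \item{`revert`}{fitted to 2013, then reset to the 1982 value.}
#'   \item{`double`}{fitted to 2013, then `min(1, 2 x D(2013))`.}
#' }
#' Projection-era policies (`maintain`, `revert`, `double`, and any `q`
#' change accompanying them) take effect at the 2013 iteration, the final
#' fitted year, mirroring the study's "2013-2028" projection tables; under
#' `maintain` the 2013 iteration coincides with the fitted one. The
#' over-diagnosis fraction ramps
#' linearly from 0 in 1982 to `O_alpha` in 2013 (held constant afterwards):
#' `O_alpha` is the proportion of 2013 Stage 1 diagnoses that are
#' over-diagnoses.
#'
#' @param window length-2 integer range of calendar years to accumulate
#'   over, within 1982-2028.
#' @param D_policy one of `"fitted"`, `"frozen"`, `"maintain"`, `"revert"`,
#'   `"double"`.
#' @param D_value constant detection probability for the `frozen` policy.
#' @param q_value alternative Stage 4 death probability (default: keep the
#'   model's `q`).
#' @param q_from first calendar year at which `q_value` applies (default:
#'   the start of the window for retrospective policies, 2013 for
#'   projection policies).
#' @param O_alpha over-diagnosis proportion reached in 2013, in \[0, 0.1\].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(window = c(1982L, 2013L),
                          D_policy = c("fitted", "frozen", "maintain",
                                       "revert", "double"),
                          D_value = NULL, q_value = NULL, q_from = NULL,
                          O_alpha = 0) {
  D_policy <- match.arg(D_policy)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be c(first_year, last_year)")
  if (window[1] < 1982L || window[2] > 2028L)
    stop("window must lie within 1982-2028")
  if (D_policy == "fitted" && window[2] > 2013L)
    stop("the 'fitted' policy is only defined through 2013; ",
         "use 'maintain', 'revert' or 'double' for projections")
  if (!is.null(q_value) && (q_value <= 0 || q_value >= 1))
    stop("q_value must lie in (0, 1)")
  if (O_alpha < 0 || O_alpha > 0.1)
    stop("O_alpha must lie in [0, 0.1]")
  structure(list(window = window, D_policy = D_policy, D_value = D_value,
                 q_value = q_value, q_from = q_from, O_alpha = O_alpha),
            class = "scenario_spec")
}

#' Run a scenario against a calibrated model
#'
#' Simulates 1982 through the end of the scenario window with the
#' policy-modified schedules (the full history is always simulated so that
#' projection scenarios start from the correct 2014 state) and accumulates
#' total excisions/diagnoses (TE, over-diagnoses included) and total
#' melanoma deaths (TM) per 100,000 over the window.
#'
#' @param model a [fit_model()] result.
#' @param spec a [scenario_spec()].
#' @return An object of class `scenario_result`: `window`, `TE`, `TM`,
#'   `incidence` and `mortality` [annual_series()] over the window, and the
#'   full trajectory.
#' @export
run_scenario <- function(model, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  p <- model$params
  win <- spec$window
  years <- 1982:win[2]
  idx <- years - 1982L
  h <- model$curves$I$horizon        # 31: index of 2013
  retro <- pmin(idx, h)

  I_t <- evaluate_curve(model$curves$I, retro)
  I31 <- evaluate_curve(model$curves$I, h)
  I_t[idx > h] <- model$proj_scale * I31

  D_fit <- evaluate_curve(model$curves$D, retro)
  D31 <- evaluate_curve(model$curves$D, h)
  sw <- idx >= h                      # projection policies switch at 2013
  D_t <- switch(spec$D_policy,
    fitted = D_fit,
    frozen = rep(if (is.null(spec$D_value)) p$D0 else spec$D_value,
                 length(years)),
    maintain = ifelse(sw, D31, D_fit),
    revert = ifelse(sw, p$D0, D_fit),
    double = ifelse(sw, min(1, 2 * D31), D_fit))

  O_t <- spec$O_alpha * retro / h

  q_t <- rep(p$q, length(years))
  if (!is.null(spec$q_value)) {
    from <- spec$q_from
    if (is.null(from))
      from <- if (spec$D_policy %in% c("maintain", "revert", "double"))
        1982L + h else win[1]
    q_t[years >= from] <- spec$q_value
  }

  traj <- run_schedule(p, years, I_t, D_t, O_t, q_t,
                       initial = model$initial_state)
  inwin <- traj$year >= win[1] & traj$year <= win[2]
  diag_flux <- traj$stage1_diagnoses + traj$stage23_diagnoses +
    traj$stage4_diagnoses + traj$overdiagnoses
  structure(list(
    spec = spec, window = win,
    TE = sum(diag_flux[inwin]),
    TM = sum(traj$melanoma_deaths[inwin]),
    incidence = annual_series(traj$year[inwin], diag_flux[inwin]),
    mortality = annual_series(traj$year[inwin],
                              traj$melanoma_deaths[inwin]),
    trajectory = traj
  ), class = "scenario_result")
}

#' Compare two scenarios
#'
#' Pairwise differences of cumulative excisions and melanoma deaths between
#' scenario `a` and comparator `b`, signed into the conventional fields:
#' excess/reduced excisions (EE/RE), reduced/excess mortality (RM/EM), and
#' the ratio of excisions per death averted (computed from unrounded
#' deltas; flagged undefined when the mortality delta is zero).
#'
#' @param a,b [run_scenario()] results over identical windows.
#' @return An object of class `comparison_result`.
#' @export
compare_scenarios <- function(a, b) {
  stopifnot(inherits(a, "scenario_result"), inherits(b, "scenario_result"))
  if (!identical(a$window, b$window))
    stop("scenarios cover different windows; comparison undefined")
  d_exc <- a$TE - b$TE
  d_mort <- a$TM - b$TM
  res <- list(window = a$window, delta_excisions = d_exc,
              delta_mortality = d_mort)
  if (d_exc >= 0) res$excess_excisions <- d_exc else
    res$reduced_excisions <- -d_exc
  if (d_mort <= 0) res$reduced_mortality <- -d_mort else
    res$excess_mortality <- d_mort
  res$ratio <- if (d_mort == 0) NA_real_ else abs(d_exc) / abs(d_mort)
  res$ratio_defined <- d_mort != 0
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("scenario comparison over %d-%d (per 100,000):\n",
              x$window[1], x$window[2]))
  cat(sprintf("  excisions: %+.1f; melanoma deaths: %+.1f; ratio: %s\n",
              x$delta_excisions, x$delta_mortality,
              if (x$ratio_defined) sprintf("%.1f", x$ratio) else "undefined"))
  invisible(x)
}

#' Cumulative over-diagnosis excess
#'
#' Total over-diagnoses per 100,000 over 1982-2013 when the over-diagnosis
#' proportion ramps linearly from 0 to `alpha` (of Stage 1 diagnoses) by
#' 2013. The overlay is a counting correction: the underlying disease
#' dynamics, state occupancies and mortality are untouched, so the excess
#' is exactly linear in `alpha`.
#'
#' @param model a [fit_model()] result.
#' @param alpha 2013 over-diagnosis proportion, in \[0, 0.1\].
#' @return Excess diagnoses per 100,000 (scalar).
#' @export
overdiagnosis_excess <- function(model, alpha) {
  sc <- run_scenario(model, scenario_spec(c(1982L, 2013L), "fitted",
                                          O_alpha = alpha))
  sum(sc$trajectory$overdiagnoses)
}

#' Average mortality reduction from improved Stage 4 survival
#'
#' Mean annual melanoma-mortality reduction per 100,000 over a window when
#' the Stage 4 death probability is reduced from the model's `q` to `q_alt`
#' at the start of the window, all else at fitted values (retrospective
#' windows) or with detection maintained at its 2013 level (projection
#' windows).
#'
#' @param model a [fit_model()] result.
#' For projection windows the reduced `q` applies from the 2013 policy
#' switch while the average is taken over the requested window (2014-2028
#' by convention), so the quoted benefit excludes the overlap year.
#'
#' @param q_alt reduced death probability (must not exceed the model's `q`).
#' @param window length-2 year range.
#' @return Mean annual mortality reduction per 100,000 (scalar).
#' @export
q_mortality_reduction <- function(model, q_alt, window = c(1982L, 2013L)) {
  if (q_alt > model$params$q)
    stop("q_alt must not exceed the baseline q")
  retro <- window[2] <= 2013L
  policy <- if (retro) "fitted" else "maintain"
  q_from <- if (retro) window[1] else NULL
  base <- run_scenario(model, scenario_spec(window, policy))
  alt <- run_scenario(model, scenario_spec(window, policy, q_value = q_alt,
                                           q_from = q_from))
  mean(base$mortality$rate_per_100k - alt$mortality$rate_per_100k)
}

#' Project a policy to 2028
#'
#' Continues the model through 2028 under a detection policy (`maintain`,
#' `revert` or `double`) applied from the 2013 iteration, optionally with a
#' reduced Stage 4 death probability from the same year, and accumulates
#' results over the 2013-2028 window (16 iterations, mirroring the study's
#' projection tables; 2013 itself is re-simulated under the policy). The
#' projection-era intrinsic incidence is the fitted 2013 value times the
#' model's single projection rescaling factor.
#'
#' @param model a [fit_model()] result.
#' @param policy `"maintain"`, `"revert"` or `"double"`.
#' @param q_value optional `q` applying from 2013.
#' @param window accumulation window (default `c(2013, 2028)`).
#' @return A [run_scenario()] result over `window`.
#' @export
project_2028 <- function(model, policy = c("maintain", "revert", "double"),
                         q_value = NULL, window = c(2013L, 2028L)) {
  policy <- match.arg(policy)
  run_scenario(model, scenario_spec(window, policy, q_value = q_value))
}
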