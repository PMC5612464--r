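#' Calibrate and fit one model configuration
#'
#' End-to-end construction of a calibrated model for one (D0, p)
#' configuration: calibrate the 1982 steady state to the anchors, build the
#' detection curve D(t), grid-fit the intrinsic incidence curve I(t) against
#' the emulated observed series, attach the flat 2014-2028 projection
#' series, and solve the single projection rescaling factor applied to
#' I(2013) so that the maintain-at-2013 policy tracks the flat projected
#' incidence (within 1\%).
#'
#' @param D0 1982 detection probability (0.01 or 0.05 in the study design).
#' @param p undiagnosed:diagnosed progression ratio (2, 5, 15, 50 or 125).
#' @param anchors an [anchor_set()].
#' @param observed optional emulated observed series (built from `anchors`
#'   when missing).
#' @param D_family,D_end family and 2013 endpoint of the detection curve
#'   (default: monotone concave-down parabola ending at 0.10).
#' @param n_grid grid points per axis for [grid_fit_I()].
#' @param incidence_anchor passed to [calibrate_1982()].
#' @param template optional [parameter_set()] template; defaults to the
#'   study values with the requested `D0` and `p`.
#' @return An object of class `calibrated_model`.
#' @examples
#' \donttest{
#' m <- fit_model(D0 = 0.05, p = 15, n_grid = 40)
#' m$fit$error
#' }
#' @export
fit_model <- function(D0 = 0.05, p = 15, anchors = anchor_set(),
                      observed = NULL, D_family = "parabola_down",
                      D_end = 0.10, n_grid = 100L,
                      incidence_anchor = c("diagnostic", "intrinsic"),
                      template = NULL) {
  if (is.null(observed)) observed <- build_observed_series(anchors)
  if (is.null(template)) template <- parameter_set(D0 = D0, p = p)
  stopifnot(template$D0 == D0, template$p == p)

  cal <- calibrate_1982(anchors, template,
                        incidence_anchor = incidence_anchor)
  D_curve <- make_curve(D_family, D0, D_end)
  fit <- grid_fit_I(cal$params, D_curve, observed,
                    initial_state = cal$state, n_grid = n_grid)
  projection <- build_projection_series(anchors, observed)

  model <- structure(list(
    params = cal$params,
    curves = curve_set(fit$I_curve, D_curve),
    initial_state = cal$state,
    calibration = cal, fit = fit,
    observed = observed, projection = projection,
    proj_scale = NA_real_,
    config = list(D0 = D0, p = p, D_family = D_family, D_end = D_end)
  ), class = "calibrated_model")
  model$proj_scale <- solve_projection_scale(model)
  model
}

# Single factor applied to I(2013) in the projection era so the
# maintain-at-2013 policy reproduces the flat projected incidence level.
solve_projection_scale <- function(model, tol = 1e-9) {
  level <- mean(model$projection$incidence$rate_per_100k)
  st2014 <- attr(model$fit$trajectory, "final_state")
  p <- model$params
  I31 <- evaluate_curve(model$curves$I, model$curves$I$horizon)
  D31 <- evaluate_curve(model$curves$D, model$curves$D$horizon)
  nyr <- nrow(model$projection$incidence)

  mean_inc <- function(kappa) {
    tr <- run_schedule(p, model$projection$incidence$year,
                       I_t = rep(kappa * I31, nyr), D_t = rep(D31, nyr),
                       initial = st2014)
    mean(tr$stage1_diagnoses + tr$stage23_diagnoses + tr$stage4_diagnoses)
  }
  f <- function(k) mean_inc(k) - level
  lo <- 0.02; hi <- 5
  while (f(hi) < 0 && hi < 1e4) hi <- hi * 4   # weak diagnostic response
  while (f(lo) > 0 && lo > 1e-6) lo <- lo / 4
  if (f(lo) > 0 || f(hi) < 0) {
    warning("projection incidence level not attainable; using nearest scale")
    return(if (abs(f(hi)) < abs(f(lo))) hi else lo)
  }
  kappa <- stats::uniroot(f, interval = c(lo, hi), tol = tol)$root
  if (abs(mean_inc(kappa) - level) / level > 0.01)
    warning("projection incidence matched worse than 1%")
  kappa
}

#' @export
print.calibrated_model <- function(x, ...) {
  cat(sprintf("calibrated melanoma model: D0 = %.3g, p = %g\n",
              x$config$D0, x$config$p))
  cat(sprintf("  D(t): %s to D(31) = %.3g; I(t): %.3g + %.3g u + %.3g u^2\n",
              x$config$D_family, x$config$D_end, x$fit$a, x$fit$b, x$fit$c))
  cat(sprintf("  fit error (pooled RMS relative): %.4f\n", x$fit$error))
  cat(sprintf("  1982 steady state: incidence %.2f, mortality %.2f, ",
              x$calibration$outputs[["incidence"]],
              x$calibration$outputs[["mortality"]]))
  cat(sprintf("Stage-1 prevalence %.0f per 100,000\n",
              x$calibration$outputs[["prevalence_diag_stage1"]]))
  invisible(x)
}

#' Fit all study configurations and pick the best curve per configuration
#'
#' Runs the calibration and grid fit for every (D0, p) configuration,
#' trying each candidate detection-curve family and endpoint, and keeps the
#' (D-curve, I-curve) pair with the smallest [fit_error()] per
#' configuration. The default candidate endpoints follow the study design:
#' D(31) in \{0.075, 0.10, 0.15\} for D0 = 0.05 and \{0.02, 0.05, 0.10\}
#' for D0 = 0.01.
#'
#' @param configs data frame (or list of pairs) of `D0` and `p`; defaults to
#'   the ten study configurations.
#' @param anchors an [anchor_set()].
#' @param observed optional emulated observed series.
#' @param families candidate monotone families for D(t).
#' @param D_end_sets named list (by D0 value) of candidate D(31) endpoints.
#' @param n_grid grid points per axis for [grid_fit_I()].
#' @param incidence_anchor passed to [calibrate_1982()].
#' @param quiet suppress progress messages.
#' @return A list with `models` (list of [fit_model()] results) and
#'   `summary` (data frame: D0, p, family, D_end, error), ordered as
#'   `configs`.
#' @export
select_best_model <- function(configs = NULL, anchors = anchor_set(),
                              observed = NULL,
                              families = c("linear", "parabola_up",
                                           "parabola_down", "sigmoid"),
                              D_end_sets = list(`0.05` = c(0.075, 0.10, 0.15),
                                                `0.01` = c(0.02, 0.05, 0.10)),
                              n_grid = 100L,
                              incidence_anchor = c("diagnostic", "intrinsic"),
                              quiet = TRUE) {
  incidence_anchor <- match.arg(incidence_anchor)
  if (is.null(configs))
    configs <- expand.grid(D0 = c(0.01, 0.05), p = c(2, 5, 15, 50, 125),
                           KEEP.OUT.ATTRS = FALSE)
  configs <- as.data.frame(configs)
  if (is.null(observed)) observed <- build_observed_series(anchors)

  models <- vector("list", nrow(configs))
  rows <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    D0 <- configs$D0[i]; p <- configs$p[i]
    ends <- D_end_sets[[as.character(D0)]]
    if (is.null(ends)) ends <- c(1.5, 2, 3) * D0
    ends <- ends[ends >= D0]   # monotone non-decreasing D(t) only
    best <- NULL
    for (fam in families) for (de in ends) {
      m <- fit_model(D0 = D0, p = p, anchors = anchors, observed = observed,
                     D_family = fam, D_end = de, n_grid = n_grid,
                     incidence_anchor = incidence_anchor)
      if (is.null(best) || m$fit$error < best$fit$error) best <- m
    }
    models[[i]] <- best
    rows[[i]] <- data.frame(D0 = D0, p = p,
                            family = best$config$D_family,
                            D_end = best$config$D_end,
                            error = best$fit$error)
    if (!quiet)
      message(sprintf("D0 = %.2f, p = %3g: %s to %.3g, error %.4f",
                      D0, p, best$config$D_family, best$config$D_end,
                      best$fit$error))
  }
  list(models = models, summary = do.call(rbind, rows))
}
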