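#' One-at-a-time Monte-Carlo parameter sensitivity
#'
#' Perturbs a single parameter around its calibrated 1982 value with
#' normally distributed draws (standard deviation `sd_frac` of the value),
#' re-solves the steady state for each draw with all other parameters
#' fixed, and records the deviations of the three steady-state outputs --
#' diagnostic incidence, melanoma mortality and diagnosed-Stage-1
#' prevalence, per 100,000 -- from the unperturbed state. Draws that
#' produce an inadmissible model (probabilities outside \[0, 1\] or an
#' infeasible matrix row) are redrawn rather than clipped, up to a budget
#' of 50\% of `n` redraws.
#'
#' @param model a [fit_model()] result (or a plain [parameter_set()]).
#' @param param_id one of `"I0"`, `"D0"`, `"O0"`, `"r"`, `"p"`, `"q"`,
#'   `"d"`, `"t4"`, `"t5"`, `"t6"`, `"t7"`.
#' @param n number of Monte-Carlo draws.
#' @param sd_frac standard deviation as a fraction of the 1982 value.
#' @param seed RNG seed (results are reproducible for a given seed).
#' @return An object of class `sensitivity_result`: `param`, `n`, `seed`,
#'   `sd_frac`, `values` (the accepted draws), `deviations` (n x 3 matrix:
#'   incidence, mortality, prevalence deviations per 100,000), `baseline`
#'   (the unperturbed outputs) and `n_redraws`.
#' @export
perturb_parameter <- function(model, param_id, n = 10000L, sd_frac = 0.10,
                              seed = 1L) {
  params <- if (inherits(model, "calibrated_model")) model$params else model
  stopifnot(inherits(params, "parameter_set"))
  ids <- c("I0", "D0", "O0", "r", "p", "q", "d", "t4", "t5", "t6", "t7")
  if (!param_id %in% ids)
    stop("param_id must be one of: ", paste(ids, collapse = ", "))
  base_val <- params[[param_id]]
  base_out <- steady_outputs(params)

  admissible <- function(v) {
    ok <- tryCatch({
      p2 <- set_param(params, param_id, v)
      build_transition_matrix(p2, p2$I0, p2$D0, p2$O0)
      TRUE
    }, error = function(e) FALSE)
    ok
  }

  set.seed(as.integer(seed))
  values <- stats::rnorm(n, base_val, sd_frac * base_val)
  ok <- vapply(values, admissible, logical(1))
  n_redraws <- 0L
  budget <- floor(n / 2)
  while (any(!ok)) {
    k <- sum(!ok)
    n_redraws <- n_redraws + k
    if (n_redraws > budget)
      stop("more than 50% of draws for '", param_id,
           "' were inadmissible; reduce sd_frac")
    values[!ok] <- stats::rnorm(k, base_val, sd_frac * base_val)
    ok[!ok] <- vapply(values[!ok], admissible, logical(1))
  }

  dev <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("incidence", "mortality",
                                        "prevalence_diag_stage1")))
  for (i in seq_len(n)) {
    p2 <- set_param(params, param_id, values[i])
    dev[i, ] <- steady_outputs(p2) - base_out
  }

  structure(list(param = param_id, n = n, seed = seed, sd_frac = sd_frac,
                 values = values, deviations = dev, baseline = base_out,
                 n_redraws = n_redraws),
            class = "sensitivity_result")
}

# replace one named parameter
set_param <- function(params, nm, v)
  do.call(update_parameters, c(list(params), stats::setNames(list(v), nm)))

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("sensitivity of 1982 steady state to '%s' (n = %d, sd = %g%%, seed %d)\n",
              x$param, x$n, 100 * x$sd_frac, x$seed))
  cat(sprintf("  redraws for admissibility: %d\n", x$n_redraws))
  s <- apply(x$deviations, 2, stats::sd)
  for (nm in names(s))
    cat(sprintf("  %-24s deviation SD %.4g per 100,000\n", nm, s[[nm]]))
  invisible(x)
}

#' Summary quantiles of a sensitivity run
#'
#' @param object a [perturb_parameter()] result.
#' @param probs quantile probabilities.
#' @param ... unused.
#' @return A data frame of deviation quantiles per output.
#' @export
summary.sensitivity_result <- function(object,
                                       probs = c(0.025, 0.25, 0.5, 0.75,
                                                 0.975), ...) {
  q <- apply(object$deviations, 2, stats::quantile, probs = probs)
  data.frame(output = colnames(object$deviations),
             t(q), sd = apply(object$deviations, 2, stats::sd),
             row.names = NULL, check.names = FALSE)
}
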