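#' Stationary distribution of the cohort model
#'
#' Solves the steady state of the model for fixed values of the
#' time-dependent probabilities: the distribution left invariant by the
#' transition matrix, with death mass recycling to baseline. Used to set up
#' the pre-1982 equilibrium. Two independent methods are provided: power
#' iteration (the default) and a direct null-space linear solve; they agree
#' to ~1e-10 and cross-check each other.
#'
#' @param params a [parameter_set()].
#' @param i_val,d_val fixed intrinsic incidence and detection probability;
#'   default to `params$I0` and `params$D0`.
#' @param method `"power"` or `"solve"`.
#' @param tol convergence tolerance for power iteration (L-infinity change
#'   per iteration).
#' @param max_iter iteration cap for power iteration.
#' @return A [state_vector()].
#' @examples
#' pars <- parameter_set()
#' pi1 <- steady_state(pars)
#' pi2 <- steady_state(pars, method = "solve")
#' max(abs(pi1 - pi2)) < 1e-10
#' @export
steady_state <- function(params, i_val = params$I0, d_val = params$D0,
                         method = c("power", "solve"),
                         tol = 1e-13, max_iter = 1e6) {
  method <- match.arg(method)
  M <- unclass(build_transition_matrix(params, i_val, d_val, 0))
  if (method == "solve") return(state_vector(stationary_solve(M)))

  v <- c(1, rep(0, 7))
  for (it in seq_len(max_iter)) {
    v2 <- as.numeric(v %*% M)
    if (max(abs(v2 - v)) < tol) return(state_vector(v2))
    v <- v2
  }
  stop("steady_state: power iteration did not converge within ",
       format(max_iter), " iterations")
}

# direct stationary solve: pi' M = pi', sum(pi) = 1
stationary_solve <- function(M) {
  n <- nrow(M)
  A <- t(M) - diag(n)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi <- solve(A, b)
  pi[abs(pi) < 1e-15] <- 0
  pi / sum(pi)
}

#' Steady-state summary outputs
#'
#' Reports the annual diagnostic incidence (flux into the three diagnosed
#' states, plus the over-diagnosis overlay), melanoma mortality (flux from
#' diagnosed Stage 4 to death via `q`) and the occupancy of the diagnosed
#' Stage 1 state, all per 100,000 persons, for a state vector under given
#' parameter values.
#'
#' @param params a [parameter_set()].
#' @param state a [state_vector()]; defaults to the steady state at
#'   (`i_val`, `d_val`).
#' @param i_val,d_val,o_val probability values at which fluxes are evaluated.
#' @return Named numeric: `incidence`, `mortality`, `prevalence_diag_stage1`
#'   (per 100,000).
#' @export
steady_outputs <- function(params, state = NULL, i_val = params$I0,
                           d_val = params$D0, o_val = params$O0) {
  if (is.null(state))
    state <- steady_state(params, i_val, d_val, method = "solve")
  s1 <- state[["undiag_stage1"]] * d_val
  diag_flux <- s1 * (1 + o_val) +
    state[["undiag_stage23"]] * params$t4 +
    state[["undiag_stage4"]] * params$t5
  c(incidence = diag_flux * POP,
    mortality = state[["diag_stage4"]] * params$q * POP,
    prevalence_diag_stage1 = state[["diag_stage1"]] * POP)
}
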