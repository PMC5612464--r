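#' Build the yearly transition matrix
#'
#' Assembles the 8x8 row-stochastic transition matrix of the cohort model for
#' one year, given the current values of the three time-dependent
#' probabilities: the intrinsic incidence `i_val` (baseline ->
#' undiagnosed disease, partitioned by `f1`, `f23`, `f4`), the Stage 1
#' detection probability `d_val` (undiagnosed -> diagnosed Stage 1) and the
#' over-diagnosis fraction `o_val`. Over-diagnosis is a counting overlay: it
#' adds to the diagnosis tally in [step_cohort()] but never moves mass, so it
#' does not appear in the matrix. Diagonal entries absorb the remainder so
#' every row sums to exactly 1; the death row recycles to baseline with
#' probability 1, keeping the population closed.
#'
#' @param params a [parameter_set()].
#' @param i_val,d_val,o_val current intrinsic incidence, detection
#'   probability and over-diagnosis fraction (probabilities).
#' @return An 8x8 matrix of class `transition_matrix` with the parameter
#'   values attached as attributes.
#' @examples
#' M <- build_transition_matrix(parameter_set(), 0.00031, 0.05, 0)
#' rowSums(M)   # all exactly 1
#' @export
build_transition_matrix <- function(params, i_val, d_val, o_val = 0) {
  stopifnot(inherits(params, "parameter_set"))
  for (v in c(i_val, d_val, o_val))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("i_val, d_val and o_val must be single probabilities in [0, 1]")

  n <- length(model_states)
  M <- matrix(0, n, n, dimnames = list(model_states, model_states))
  f1 <- 1 - params$f23 - params$f4
  d <- params$d

  M["baseline", "undiag_stage1"]  <- i_val * f1
  M["baseline", "undiag_stage23"] <- i_val * params$f23
  M["baseline", "undiag_stage4"]  <- i_val * params$f4
  M["baseline", "death"]          <- d

  M["undiag_stage1", "diag_stage1"]    <- d_val
  M["undiag_stage1", "undiag_stage23"] <- params$r
  M["undiag_stage1", "undiag_stage4"]  <- params$r / 3
  M["undiag_stage1", "death"]          <- d

  M["undiag_stage23", "diag_stage23"] <- params$t4
  M["undiag_stage23", "undiag_stage4"] <- params$t6
  M["undiag_stage23", "death"]        <- d

  M["undiag_stage4", "diag_stage4"] <- params$t5
  M["undiag_stage4", "death"]       <- d

  M["diag_stage1", "diag_stage23"] <- params$r / params$p
  M["diag_stage1", "diag_stage4"]  <- params$r / (3 * params$p)
  M["diag_stage1", "death"]        <- d

  M["diag_stage23", "diag_stage4"] <- params$t7
  M["diag_stage23", "death"]       <- d

  M["diag_stage4", "death"] <- params$q + d

  M["death", "baseline"] <- 1

  off <- rowSums(M)
  bad <- which(off > 1 + 1e-12)
  if (length(bad))
    stop("infeasible parameters: off-diagonal probabilities exceed 1 in row(s) ",
         paste(model_states[bad], collapse = ", "))
  diag(M) <- diag(M) + (1 - off)

  structure(M, class = c("transition_matrix", "matrix"),
            params = params, i_val = i_val, d_val = d_val, o_val = o_val)
}

#' Advance the cohort by one year
#'
#' Propagates a state vector through a transition matrix and tallies the
#' fluxes of interest for that year: diagnoses by stage, over-diagnoses,
#' melanoma deaths and other-cause deaths, all per 100,000 persons. Tallies
#' are origin occupancy times edge probability, evaluated on the pre-step
#' state (no intra-year chaining). The over-diagnosis tally is the overlay
#' `o_val` times the Stage 1 diagnosis flux; it adds counted diagnoses
#' without moving any mass, so disease dynamics and mortality are untouched.
#'
#' @param state a [state_vector()] (or numeric length-8 vector).
#' @param tmat a matrix from [build_transition_matrix()].
#' @return A list with elements `state` (next year's [state_vector()]) and
#'   `tally` (named numeric: `stage1_diagnoses`, `stage23_diagnoses`,
#'   `stage4_diagnoses`, `overdiagnoses`, `melanoma_deaths`, `other_deaths`,
#'   per 100,000).
#' @export
step_cohort <- function(state, tmat) {
  if (!inherits(state, "state_vector")) state <- state_vector(state)
  stopifnot(inherits(tmat, "transition_matrix"))
  p <- attr(tmat, "params")
  d_val <- attr(tmat, "d_val")
  o_val <- attr(tmat, "o_val")

  nxt <- as.numeric(state %*% unclass(tmat))

  s1 <- state[["undiag_stage1"]] * d_val * POP
  tally <- c(
    stage1_diagnoses  = s1,
    stage23_diagnoses = state[["undiag_stage23"]] * p$t4 * POP,
    stage4_diagnoses  = state[["undiag_stage4"]] * p$t5 * POP,
    overdiagnoses     = o_val * s1,
    melanoma_deaths   = state[["diag_stage4"]] * p$q * POP,
    other_deaths      = (1 - state[["death"]]) * p$d * POP
  )
  list(state = state_vector(nxt), tally = tally)
}
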