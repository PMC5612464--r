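#' Model states
#'
#' The eight states of the melanoma cohort model, in matrix order:
#' baseline (no invasive melanoma), undiagnosed Stage 1 / Stage 2-3 /
#' Stage 4, diagnosed (treated) Stage 1 / Stage 2-3 / Stage 4, and death.
#' Death recycles to baseline so the population stays closed.
#'
#' @format Character vector of length 8.
#' @export
model_states <- c("baseline",
                  "undiag_stage1", "undiag_stage23", "undiag_stage4",
                  "diag_stage1", "diag_stage23", "diag_stage4",
                  "death")

POP <- 1e5 # reporting scale: rates per 100,000 persons

#' Create a model parameter set
#'
#' Bundles the eleven transition probabilities of the melanoma Markov model
#' plus the partition of the intrinsic incidence among the three undiagnosed
#' disease states. All probabilities are per person per year.
#'
#' @param I0 intrinsic incidence at the start year: yearly probability that a
#'   baseline individual develops undiagnosed invasive melanoma.
#' @param D0 yearly probability of a Stage 1 diagnosis given undiagnosed
#'   Stage 1 disease, at the start year (the level of secondary prevention).
#' @param O0 over-diagnosis fraction at the start year: proportion of Stage 1
#'   diagnoses that are over-diagnoses (counted, but the individual remains
#'   at baseline).
#' @param r yearly probability of undiagnosed Stage 1 progressing to
#'   undiagnosed Stage 2/3; undiagnosed Stage 1 to Stage 4 occurs at `r/3`.
#' @param p ratio (>= 1) of undiagnosed to diagnosed Stage 1 progression:
#'   diagnosed Stage 1 progresses at `r/p` (to Stage 2/3) and `r/(3p)`
#'   (to Stage 4).
#' @param q yearly probability of melanoma death given diagnosed Stage 4.
#' @param d yearly probability of death from causes other than melanoma,
#'   applied in every living state.
#' @param t4 yearly probability undiagnosed Stage 2/3 is diagnosed.
#' @param t5 yearly probability undiagnosed Stage 4 is diagnosed.
#' @param t6 yearly probability undiagnosed Stage 2/3 progresses to
#'   undiagnosed Stage 4.
#' @param t7 yearly probability diagnosed Stage 2/3 progresses to diagnosed
#'   Stage 4.
#' @param f23,f4 fractions of the intrinsic incidence routed directly to
#'   undiagnosed Stage 2/3 and Stage 4 (`f1 = 1 - f23 - f4` goes to
#'   undiagnosed Stage 1).
#'
#' @return An object of class `parameter_set` (a named list).
#' @examples
#' pars <- parameter_set()          # Table-style defaults, D0 = 0.05, p = 15
#' parameter_set(D0 = 0.01, p = 2)
#' @export
parameter_set <- function(I0 = 0.00031, D0 = 0.05, O0 = 0,
                          r = 0.00375, p = 15, q = 0.37, d = 0.006,
                          t4 = 0.2, t5 = 0.9, t6 = 0.1, t7 = 0.168,
                          f23 = 0.03, f4 = 0.01) {
  ps <- list(I0 = I0, D0 = D0, O0 = O0, r = r, p = p, q = q, d = d,
             t4 = t4, t5 = t5, t6 = t6, t7 = t7, f23 = f23, f4 = f4)
  validate_parameter_set(ps)
  structure(ps, class = "parameter_set")
}

validate_parameter_set <- function(ps) {
  probs <- c("I0", "D0", "O0", "r", "q", "d", "t4", "t5", "t6", "t7",
             "f23", "f4")
  for (nm in probs) {
    v <- ps[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("parameter '%s' must be a single probability in [0, 1]", nm))
  }
  if (!is.numeric(ps$p) || length(ps$p) != 1L || ps$p < 1)
    stop("'p' must be a ratio >= 1")
  if (ps$f23 + ps$f4 >= 0.5)
    stop("f23 + f4 must be < 0.5 (Stage 1 is the dominant entry route)")
  # row feasibility for the largest admissible detection probability
  if (ps$r + ps$r / 3 + ps$D0 + ps$d > 1)
    stop("infeasible parameters: r + r/3 + D0 + d exceeds 1 ",
         "(undiagnosed Stage 1 row would not be row-stochastic)")
  if (ps$q + ps$d > 1)
    stop("infeasible parameters: q + d exceeds 1 (diagnosed Stage 4 row)")
  invisible(ps)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Melanoma Markov model parameters (per person per year):\n")
  v <- unlist(x)
  print(signif(v, 6))
  cat(sprintf("derived: f1 = %.4f, r/p = %.6g, r/(3p) = %.6g\n",
              1 - x$f23 - x$f4, x$r / x$p, x$r / (3 * x$p)))
  invisible(x)
}

#' Replace fields of a parameter set
#'
#' @param params a [parameter_set()].
#' @param ... named replacement values.
#' @return A revalidated `parameter_set`.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "parameter_set"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params[names(repl)] <- repl
  validate_parameter_set(params)
  structure(params, class = "parameter_set")
}

#' Validate a state vector
#'
#' A state vector holds the occupancy of the eight model states as fractions
#' of a closed population: entries are non-negative and sum to 1.
#'
#' @param x numeric vector of length 8 (named or unnamed, matrix order).
#' @return The vector, named by [model_states], class `state_vector`.
#' @export
state_vector <- function(x) {
  if (length(x) != 8L) stop("a state vector has 8 entries")
  x <- as.numeric(x)
  if (any(x < -1e-12)) stop("state occupancies must be non-negative")
  if (abs(sum(x) - 1) > 1e-9)
    stop("state occupancies must sum to 1 (got ", format(sum(x)), ")")
  x[x < 0] <- 0
  names(x) <- model_states
  structure(x, class = "state_vector")
}
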