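#' Parametric time courses for the time-dependent probabilities
#'
#' The three time-dependent probabilities of the model -- intrinsic
#' incidence I(t), Stage 1 detection D(t) and over-diagnosis O(t) -- follow
#' simple parametric curves on the rescaled time u = t/31, where t is the
#' year index (t = 0 is 1982, t = 31 is 2013). Four families are supported:
#' straight line, concave-up parabola, concave-down parabola, and sigmoid.
#' Polynomials of degree 3 or more are deliberately not offered, to limit
#' overfitting. Monotone families are constructed to be non-decreasing on
#' the unit interval.
#'
#' @param family one of `"linear"`, `"parabola_up"`, `"parabola_down"`,
#'   `"sigmoid"`, or `"parabola"` (free coefficients, used for fitted I(t)).
#' @param v_start,v_end values at u = 0 and u = 1, both in \[0, 1\].
#' @param shape optional shape parameter: for `"parabola_down"` the vertex
#'   location u0 >= 1 (default 1); for `"parabola_up"` the vertex u0 <= 0
#'   (default 0); for `"sigmoid"` a numeric `c(midpoint, steepness)`
#'   (default `c(0.5, 10)`).
#' @param coef for `family = "parabola"`: numeric `c(a, b, c)` of
#'   v(u) = a + b u + c u^2.
#' @param horizon number of yearly steps spanned by u in \[0, 1\] (31 for
#'   1982-2013).
#' @return An object of class `curve_spec`.
#' @examples
#' D <- make_curve("parabola_down", 0.05, 0.10)   # b = 0.10, c = -0.05
#' evaluate_curve(D, 0)    # 0.05
#' evaluate_curve(D, 31)   # 0.10
#' @export
make_curve <- function(family = c("linear", "parabola_up", "parabola_down",
                                  "sigmoid", "parabola"),
                       v_start = NULL, v_end = v_start, shape = NULL,
                       coef = NULL, horizon = 31L) {
  family <- match.arg(family)
  if (family != "parabola") {
    if (is.null(v_start)) stop("v_start is required for family '", family, "'")
    stopifnot(is.numeric(v_start), is.numeric(v_end),
              v_start >= 0, v_start <= 1, v_end >= 0, v_end <= 1)
  }
  delta <- v_end - v_start
  spec <- list(family = family, v_start = v_start, v_end = v_end,
               horizon = as.integer(horizon), monotone = TRUE)

  if (family == "linear") {
    spec$a <- v_start; spec$b <- delta; spec$c <- 0
  } else if (family == "parabola_down") {
    u0 <- if (is.null(shape)) 1 else shape[[1]]
    if (u0 < 1) stop("monotone concave-down parabola needs vertex u0 >= 1")
    # solve a + b u + c u^2 through both endpoints with vertex at u0
    c_ <- -delta / (2 * u0 - 1)
    b_ <- -2 * c_ * u0
    spec$a <- v_start; spec$b <- b_; spec$c <- c_
  } else if (family == "parabola_up") {
    u0 <- if (is.null(shape)) 0 else shape[[1]]
    if (u0 > 0) stop("monotone concave-up parabola needs vertex u0 <= 0")
    c_ <- delta / (1 - 2 * u0)
    b_ <- -2 * c_ * u0
    spec$a <- v_start; spec$b <- b_; spec$c <- c_
  } else if (family == "sigmoid") {
    if (is.null(shape)) shape <- c(0.5, 10)
    m <- shape[[1]]; k <- shape[[2]]
    if (k <= 0) stop("sigmoid steepness must be positive")
    spec$midpoint <- m; spec$steepness <- k
  } else { # free parabola (fitted I(t))
    if (is.null(coef) || length(coef) != 3L)
      stop("family 'parabola' needs coef = c(a, b, c)")
    spec$a <- coef[[1]]; spec$b <- coef[[2]]; spec$c <- coef[[3]]
    spec$monotone <- FALSE
    spec$v_start <- curve_value(spec, 0)
    spec$v_end <- curve_value(spec, 1)
  }

  spec <- structure(spec, class = "curve_spec")
  if (abs(curve_value(spec, 0) - spec$v_start) > 1e-12)
    stop("curve construction failed to reproduce v_start")
  if (spec$monotone) {
    u <- seq(0, 1, length.out = 1000L)
    dv <- diff(curve_value(spec, u))
    if (any(dv < -1e-12))
      stop("requested monotone curve is not non-decreasing")
  }
  spec
}

# evaluate on rescaled time u (vectorised); internal
curve_value <- function(spec, u) {
  if (spec$family == "sigmoid") {
    s <- function(x) 1 / (1 + exp(-spec$steepness * (x - spec$midpoint)))
    s0 <- s(0); s1 <- s(1)
    spec$v_start + (spec$v_end - spec$v_start) * (s(u) - s0) / (s1 - s0)
  } else {
    spec$a + spec$b * u + spec$c * u^2
  }
}

#' Evaluate a curve at integer year indices
#'
#' Evaluates at u = year_index / horizon. Indices beyond the horizon are an
#' error unless `extend = TRUE`, in which case the curve is held constant at
#' its horizon value (the convention used for projections past 2013).
#'
#' @param curve a [make_curve()] object.
#' @param year_index integer vector, 0-based (0 = 1982).
#' @param extend hold the curve constant past the horizon instead of
#'   erroring.
#' @return Numeric vector of probabilities.
#' @export
evaluate_curve <- function(curve, year_index, extend = FALSE) {
  stopifnot(inherits(curve, "curve_spec"))
  if (any(year_index < 0))
    stop("year_index must be non-negative")
  if (any(year_index > curve$horizon)) {
    if (!extend)
      stop("year_index beyond curve horizon (", curve$horizon,
           "); use extend = TRUE to hold the end value")
    year_index <- pmin(year_index, curve$horizon)
  }
  curve_value(curve, year_index / curve$horizon)
}

#' Bundle the three model time courses
#'
#' @param I_curve,D_curve,O_curve [make_curve()] objects for the intrinsic
#'   incidence, detection probability and over-diagnosis fraction.
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(I_curve, D_curve, O_curve = make_curve("linear", 0, 0)) {
  stopifnot(inherits(I_curve, "curve_spec"), inherits(D_curve, "curve_spec"),
            inherits(O_curve, "curve_spec"))
  h <- c(I_curve$horizon, D_curve$horizon, O_curve$horizon)
  if (length(unique(h)) != 1L)
    stop("all curves in a curve_set must share the same horizon")
  structure(list(I = I_curve, D = D_curve, O = O_curve), class = "curve_set")
}

#' @export
print.curve_spec <- function(x, ...) {
  cat(sprintf("curve_spec: %s, v(0) = %.6g, v(%d) = %.6g\n",
              x$family, x$v_start, x$horizon, x$v_end))
  if (x$family == "sigmoid")
    cat(sprintf("  midpoint %.3g, steepness %.3g\n", x$midpoint, x$steepness))
  else
    cat(sprintf("  v(u) = %.6g + %.6g u + %.6g u^2\n", x$a, x$b, x$c))
  invisible(x)
}
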