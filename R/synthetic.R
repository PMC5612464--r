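#' Registry anchor values
#'
#' Printed anchor values from which the emulated national registry series
#' are reconstructed: the 1982 diagnostic incidence and mortality rates, the
#' 2013 mortality rate, the 32-year cumulative totals, the calendar year at
#' which diagnostic incidence peaks, the 1982 prevalence of diagnosed thin
#' (Stage 1) melanoma, and the flat projection levels for 2014-2028. Rates
#' are per 100,000 persons per year; totals are cumulative per 100,000.
#'
#' @param inc_1982 1982 diagnostic incidence (27.08).
#' @param mort_1982 1982 melanoma mortality (4.76).
#' @param mort_2013 2013 melanoma mortality (~6).
#' @param inc_total_1982_2013 cumulative 1982-2013 diagnoses (1319).
#' @param mort_total_1982_2013 cumulative 1982-2013 melanoma deaths (171).
#' @param inc_peak_year calendar year of the diagnostic-incidence peak.
#' @param prevalence_D1_1982 1982 diagnosed-Stage-1 prevalence per 100,000.
#' @param projection_level_inc,projection_level_mort flat 2014-2028 levels;
#'   `NULL` means "use the 2013 value of the emulated observed series".
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(inc_1982 = 27.08, mort_1982 = 4.76, mort_2013 = 6,
                       inc_total_1982_2013 = 1319,
                       mort_total_1982_2013 = 171,
                       inc_peak_year = 2008,
                       prevalence_D1_1982 = 3215,
                       projection_level_inc = NULL,
                       projection_level_mort = NULL) {
  a <- list(inc_1982 = inc_1982, mort_1982 = mort_1982,
            mort_2013 = mort_2013,
            inc_total_1982_2013 = inc_total_1982_2013,
            mort_total_1982_2013 = mort_total_1982_2013,
            inc_peak_year = inc_peak_year,
            prevalence_D1_1982 = prevalence_D1_1982,
            projection_level_inc = projection_level_inc,
            projection_level_mort = projection_level_mort)
  num <- a[!vapply(a, is.null, logical(1))]
  if (any(unlist(num) <= 0)) stop("all anchor values must be positive")
  if (inc_peak_year < 1982 || inc_peak_year > 2013)
    stop("inc_peak_year must lie within 1982-2013")
  structure(a, class = "anchor_set")
}

#' Year-indexed annual rate series
#'
#' The interchange unit between the synthetic-data generator, the model and
#' reports: consecutive calendar years with a non-negative rate per 100,000.
#'
#' @param year integer vector of consecutive calendar years.
#' @param rate_per_100k numeric vector of non-negative rates.
#' @return A data frame of class `annual_series`.
#' @export
annual_series <- function(year, rate_per_100k) {
  year <- as.integer(year)
  if (length(year) == 0L) stop("an annual series needs at least one year")
  if (length(year) != length(rate_per_100k))
    stop("year and rate_per_100k must have equal length")
  if (length(year) > 1L && any(diff(year) != 1L))
    stop("years must be consecutive")
  if (any(!is.finite(rate_per_100k)) || any(rate_per_100k < 0))
    stop("rates must be finite and non-negative")
  structure(data.frame(year = year, rate_per_100k = as.numeric(rate_per_100k)),
            class = c("annual_series", "data.frame"))
}

#' Emulated observed 1982-2013 registry series
#'
#' Reconstructs smooth stand-ins for the national least-squares-smoothed
#' incidence and mortality data. The incidence series is the unique parabola
#' over t = 0..31 satisfying three linear constraints: the 1982 value, a
#' vertex at the peak year, and the 32-year cumulative total. The mortality
#' series is the unique parabola satisfying the 1982 and 2013 values and its
#' cumulative total. Because the originals are already least-squares
#' smoothed, the generator emits the smooth curves directly; Gaussian noise
#' (seeded) can be added for robustness experiments only.
#'
#' @param anchors an [anchor_set()].
#' @param noise_sd standard deviation of optional additive Gaussian noise
#'   (per 100,000); 0 disables it.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A list with `incidence` and `mortality`, both [annual_series()]
#'   over 1982-2013 (32 values each).
#' @examples
#' obs <- build_observed_series(anchor_set())
#' sum(obs$incidence$rate_per_100k)   # 1319
#' @export
build_observed_series <- function(anchors = anchor_set(), noise_sd = 0,
                                  seed = 1L) {
  stopifnot(inherits(anchors, "anchor_set"))
  t <- 0:31
  St <- sum(t); St2 <- sum(t^2)
  tp <- anchors$inc_peak_year - 1982

  # incidence: a + b t + c t^2 with value at t=0, vertex at tp, sum constraint
  A <- rbind(c(1, 0, 0),
             c(0, 1, 2 * tp),
             c(32, St, St2))
  rhs <- c(anchors$inc_1982, 0, anchors$inc_total_1982_2013)
  ci <- solve(A, rhs)
  inc <- ci[1] + ci[2] * t + ci[3] * t^2

  # mortality: both endpoint values and the sum
  Am <- rbind(c(1, 0, 0),
              c(1, 31, 31^2),
              c(32, St, St2))
  rm_ <- c(anchors$mort_1982, anchors$mort_2013,
           anchors$mort_total_1982_2013)
  cm <- solve(Am, rm_)
  mort <- cm[1] + cm[2] * t + cm[3] * t^2

  if (any(inc < 0) || any(mort < 0))
    stop("anchor constraints produce negative rates; adjust the anchors")

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    inc <- pmax(0, inc + stats::rnorm(32, 0, noise_sd))
    mort <- pmax(0, mort + stats::rnorm(32, 0, noise_sd))
  }

  list(incidence = annual_series(1982:2013, inc),
       mortality = annual_series(1982:2013, mort))
}

#' Flat projected 2014-2028 series
#'
#' National projections indicate a stable incidence rate for the 15 years
#' after 2013; the generator therefore emits flat series at the 2013
#' emulated levels (or at explicit override levels from the anchors).
#'
#' @param anchors an [anchor_set()].
#' @param observed optional output of [build_observed_series()]; built from
#'   `anchors` when missing.
#' @return A list with `incidence` and `mortality` [annual_series()] over
#'   2014-2028 (15 values each).
#' @export
build_projection_series <- function(anchors = anchor_set(), observed = NULL) {
  stopifnot(inherits(anchors, "anchor_set"))
  if (is.null(observed)) observed <- build_observed_series(anchors)
  lvl_i <- anchors$projection_level_inc
  if (is.null(lvl_i)) lvl_i <- utils::tail(observed$incidence$rate_per_100k, 1)
  lvl_m <- anchors$projection_level_mort
  if (is.null(lvl_m)) lvl_m <- utils::tail(observed$mortality$rate_per_100k, 1)
  list(incidence = annual_series(2014:2028, rep(lvl_i, 15)),
       mortality = annual_series(2014:2028, rep(lvl_m, 15)))
}

#' Read / write an annual series as CSV
#'
#' CSV schema: header `year,rate_per_100k`, UTF-8, one row per consecutive
#' year. Reading validates the schema and reports the offending line on
#' malformed input; a write-then-read round trip reproduces the series.
#'
#' @param path file path.
#' @param series an [annual_series()].
#' @return `read_series_csv()` returns an [annual_series()];
#'   `write_series_csv()` returns `path` invisibly.
#' @export
read_series_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty series file: ", path)
  if (trimws(lines[1]) != "year,rate_per_100k")
    stop("line 1: expected header 'year,rate_per_100k'")
  if (length(lines) == 1L) stop("no data rows in ", path)
  years <- numeric(0); rates <- numeric(0)
  for (i in 2:length(lines)) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("line ", i, ": expected two comma-separated fields")
    y <- suppressWarnings(as.numeric(parts[1]))
    r <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(y) || is.na(r))
      stop("line ", i, ": non-numeric year or rate")
    if (y != round(y)) stop("line ", i, ": year must be an integer")
    years <- c(years, y); rates <- c(rates, r)
  }
  if (length(years) > 1L && any(diff(years) != 1))
    stop("line ", which(diff(years) != 1)[1] + 2,
         ": years must be consecutive")
  if (any(rates < 0)) stop("line ", which(rates < 0)[1] + 1,
                           ": negative rate")
  annual_series(years, rates)
}

#' @rdname read_series_csv
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "annual_series"))
  lines <- c("year,rate_per_100k",
             sprintf("%d,%.6f", series$year, series$rate_per_100k))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
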