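test_that("emulated observed series satisfy all anchor constraints", {
  obs <- build_observed_series(anchor_set())
  inc <- obs$incidence$rate_per_100k
  mort <- obs$mortality$rate_per_100k

  expect_length(inc, 32)
  expect_length(mort, 32)
  expect_equal(sum(inc), 1319, tolerance = 1e-9)
  expect_equal(sum(mort), 171, tolerance = 1e-9)
  expect_equal(inc[1], 27.08, tolerance = 1e-9)
  expect_equal(mort[1], 4.76, tolerance = 1e-9)
  expect_equal(mort[32], 6, tolerance = 1e-9)
  expect_equal(obs$incidence$year, 1982:2013)

  # vertex at the peak year, and mortality monotone non-decreasing
  expect_equal(obs$incidence$year[which.max(inc)], 2008)
  expect_true(all(diff(mort) >= 0))
})

test_that("the incidence parabola solves the documented 3x3 linear system", {
  obs <- build_observed_series(anchor_set())
  inc <- obs$incidence$rate_per_100k
  # independent solve of the constraint system (value at t=0, vertex at
  # t=26, 32-year sum) on the per-year scale
  A <- rbind(c(1, 0, 0), c(0, 1, 52), c(32, 496, 10416))
  cf <- solve(A, c(27.08, 0, 1319))
  expect_equal(cf[2], 1.5301040, tolerance = 1e-6)
  expect_equal(cf[3], -0.02942508, tolerance = 1e-6)
  expect_equal(inc, cf[1] + cf[2] * (0:31) + cf[3] * (0:31)^2,
               tolerance = 1e-9)
})

test_that("projection series are flat at the 2013 levels with 15 entries", {
  obs <- build_observed_series(anchor_set())
  proj <- build_projection_series(anchor_set(), obs)
  expect_equal(proj$incidence$year, 2014:2028)
  expect_equal(proj$incidence$rate_per_100k,
               rep(obs$incidence$rate_per_100k[32], 15))
  expect_equal(proj$mortality$rate_per_100k,
               rep(6, 15), tolerance = 1e-9)
  expect_equal(sum(proj$mortality$rate_per_100k), 15 * 6, tolerance = 1e-9)

  over <- build_projection_series(anchor_set(projection_level_inc = 40))
  expect_equal(over$incidence$rate_per_100k, rep(40, 15))
})

test_that("series CSV files round-trip and reject malformed input", {
  obs <- build_observed_series(anchor_set())
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(obs$incidence, path)
  back <- read_series_csv(path)
  expect_equal(back$year, obs$incidence$year)
  expect_equal(back$rate_per_100k, obs$incidence$rate_per_100k,
               tolerance = 1e-6)

  writeLines(character(0), path)
  expect_error(read_series_csv(path), "empty")

  writeLines(c("year,rate_per_100k", "1982,1.5", "1984,2.0"), path)
  expect_error(read_series_csv(path), "consecutive")

  writeLines(c("year,rate_per_100k", "1982,abc"), path)
  expect_error(read_series_csv(path), "line 2")

  writeLines(c("bad,header", "1982,1"), path)
  expect_error(read_series_csv(path), "header")
})

test_that("optional noise is seeded and reproducible", {
  a <- build_observed_series(anchor_set(), noise_sd = 0.5, seed = 11)
  b <- build_observed_series(anchor_set(), noise_sd = 0.5, seed = 11)
  c <- build_observed_series(anchor_set(), noise_sd = 0.5, seed = 12)
  expect_identical(a$incidence$rate_per_100k, b$incidence$rate_per_100k)
  expect_false(identical(a$incidence$rate_per_100k,
                         c$incidence$rate_per_100k))
})

test_that("anchor systems that force negative rates are rejected", {
  expect_error(build_observed_series(anchor_set(inc_total_1982_2013 = 100)),
               "negative")
  expect_error(anchor_set(inc_peak_year = 2030), "1982-2013")
  expect_error(annual_series(c(1982, 1984), c(1, 2)), "consecutive")
})
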