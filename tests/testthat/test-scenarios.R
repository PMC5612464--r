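test_that("a frozen policy with constant intrinsic incidence accumulates 32 steady years", {
  pars <- parameter_set()
  st <- steady_state(pars, method = "solve")
  out0 <- steady_outputs(pars, st)
  model <- structure(list(
    params = pars,
    curves = curve_set(make_curve("parabola", coef = c(pars$I0, 0, 0)),
                       make_curve("linear", pars$D0, pars$D0)),
    initial_state = st, proj_scale = 1,
    projection = build_projection_series(anchor_set()),
    config = list(D0 = pars$D0, p = pars$p)
  ), class = "calibrated_model")
  sc <- run_scenario(model, scenario_spec(c(1982, 2013), "frozen",
                                          D_value = pars$D0))
  expect_equal(sc$TE, 32 * out0[["incidence"]], tolerance = 1e-9)
  expect_equal(sc$TM, 32 * out0[["mortality"]], tolerance = 1e-9)
})

test_that("comparing a scenario with itself gives zero deltas and an undefined ratio", {
  m <- flagship_model()
  a <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted"))
  cmp <- compare_scenarios(a, a)
  expect_equal(cmp$delta_excisions, 0)
  expect_equal(cmp$delta_mortality, 0)
  expect_false(cmp$ratio_defined)
  expect_true(is.na(cmp$ratio))
})

test_that("windows must match for a comparison", {
  m <- flagship_model()
  a <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted"))
  b <- run_scenario(m, scenario_spec(c(1982, 2000), "fitted"))
  expect_error(compare_scenarios(a, b), "window")
})

test_that("identical scenario specs give bit-identical results", {
  m <- flagship_model()
  s1 <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted", O_alpha = 0.03))
  s2 <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted", O_alpha = 0.03))
  expect_identical(s1$TE, s2$TE)
  expect_identical(s1$trajectory$melanoma_deaths, s2$trajectory$melanoma_deaths)
})

test_that("reducing q lowers the mortality series pointwise and only after its start year", {
  m <- flagship_model()
  base <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted"))
  low <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted",
                                       q_value = 0.185))
  expect_true(all(low$mortality$rate_per_100k <=
                    base$mortality$rate_per_100k))
  late <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted",
                                        q_value = 0.185, q_from = 2000))
  expect_equal(late$mortality$rate_per_100k[1:18],
               base$mortality$rate_per_100k[1:18])
  expect_true(all(late$mortality$rate_per_100k[19:32] <
                    base$mortality$rate_per_100k[19:32]))
})

test_that("the enhanced-detection policy dominates the reverted one in the projection", {
  m <- flagship_model()
  maintain <- project_2028(m, "maintain")
  revert <- project_2028(m, "revert")
  expect_gte(maintain$TE, revert$TE)
  expect_lte(maintain$TM, revert$TM)
})

test_that("reverting detection in 2013 drops incidence sharply before it recovers", {
  m <- flagship_model()
  rv <- project_2028(m, "revert")
  fitted13 <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted"))
  inc13_fitted <- utils::tail(fitted13$incidence$rate_per_100k, 1)
  inc <- rv$incidence$rate_per_100k   # 2013..2028 under the revert policy
  expect_lt(inc[1], inc13_fitted)
  expect_true(all(diff(inc) > 0))
})

test_that("the over-diagnosis excess is linear in alpha and never touches mortality", {
  m <- flagship_model()
  expect_equal(overdiagnosis_excess(m, 0), 0)
  e3 <- overdiagnosis_excess(m, 0.03)
  e10 <- overdiagnosis_excess(m, 0.10)
  expect_equal(e10, e3 * 10 / 3, tolerance = 1e-12)
  base <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted"))
  ov <- run_scenario(m, scenario_spec(c(1982, 2013), "fitted",
                                      O_alpha = 0.10))
  expect_identical(base$TM, ov$TM)
  expect_equal(ov$TE - base$TE, e10, tolerance = 1e-12)
})

test_that("scenario specs validate their fields", {
  expect_error(scenario_spec(c(1982, 2030)), "1982-2028")
  expect_error(scenario_spec(c(1982, 2020), "fitted"), "2013")
  expect_error(scenario_spec(q_value = 1.2), "q_value")
  expect_error(scenario_spec(O_alpha = 0.2), "O_alpha")
  m <- flagship_model()
  expect_error(q_mortality_reduction(m, 0.5), "exceed")
})
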