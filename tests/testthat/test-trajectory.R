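make_constant_curves <- function(I0, D0) {
  curve_set(make_curve("parabola", coef = c(I0, 0, 0)),
            make_curve("linear", D0, D0))
}

test_that("constant curves at steady-state inputs reproduce the steady outputs every year", {
  pars <- parameter_set()
  st <- steady_state(pars, method = "solve")
  out0 <- steady_outputs(pars, st)
  traj <- run_trajectory(pars, make_constant_curves(pars$I0, pars$D0),
                         1982:2013, initial = st)
  outs <- annual_outputs(traj)
  expect_equal(nrow(traj), 32L)
  expect_equal(outs$incidence$rate_per_100k,
               rep(out0[["incidence"]], 32), tolerance = 1e-9)
  expect_equal(outs$mortality$rate_per_100k,
               rep(out0[["mortality"]], 32), tolerance = 1e-9)
})

test_that("occupancy stays a probability vector over a century", {
  pars <- parameter_set()
  traj <- run_trajectory(pars, make_constant_curves(pars$I0, pars$D0),
                         1982:2081, initial = NULL, extend = TRUE)
  sums <- rowSums(traj[, model_states])
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(traj[, model_states] >= 0))
})

test_that("annual outputs add up: all-cause = melanoma + other deaths", {
  m <- flagship_model()
  outs <- annual_outputs(m$fit$trajectory)
  expect_equal(outs$all_cause_mortality$rate_per_100k,
               outs$mortality$rate_per_100k +
                 m$fit$trajectory$other_deaths)
  # other-cause deaths are d per person per year on the living population
  expect_equal(outs$all_cause_mortality$rate_per_100k -
                 outs$mortality$rate_per_100k,
               rep(0.006 * 1e5, 32), tolerance = 0.02)
})

test_that("trajectories error when a curve is undefined at a requested year", {
  pars <- parameter_set()
  cs <- make_constant_curves(pars$I0, pars$D0)
  expect_error(run_trajectory(pars, cs, 1982:2020), "horizon")
  expect_silent(run_trajectory(pars, cs, 1982:2020, extend = TRUE))
})

test_that("raising the detection curve never lowers diagnoses nor raises melanoma deaths", {
  pars <- parameter_set()
  st <- steady_state(pars, method = "solve")
  I_c <- make_curve("parabola", coef = c(pars$I0, 2e-4, -1e-4))
  for (top in c(0.075, 0.10, 0.15)) {
    lo <- run_trajectory(pars, curve_set(I_c, make_curve("linear", 0.05, 0.05)),
                         1982:2013, initial = st)
    hi <- run_trajectory(pars, curve_set(I_c, make_curve("linear", 0.05, top)),
                         1982:2013, initial = st)
    diag_lo <- sum(lo$stage1_diagnoses + lo$stage23_diagnoses +
                     lo$stage4_diagnoses)
    diag_hi <- sum(hi$stage1_diagnoses + hi$stage23_diagnoses +
                     hi$stage4_diagnoses)
    expect_gte(diag_hi, diag_lo)
    expect_lte(sum(hi$melanoma_deaths), sum(lo$melanoma_deaths))
  }
})

test_that("the over-diagnosis overlay changes counted incidence only", {
  pars <- parameter_set()
  st <- steady_state(pars, method = "solve")
  I_c <- make_curve("parabola", coef = c(pars$I0, 2e-4, -1e-4))
  D_c <- make_curve("parabola_down", 0.05, 0.10)
  base <- run_trajectory(pars, curve_set(I_c, D_c), 1982:2013, initial = st)
  ov <- run_trajectory(pars, curve_set(I_c, D_c,
                                       make_curve("linear", 0, 0.05)),
                       1982:2013, initial = st)
  # occupancies and deaths bit-identical; only the overlay tally differs
  expect_identical(as.matrix(base[, model_states]),
                   as.matrix(ov[, model_states]))
  expect_identical(base$melanoma_deaths, ov$melanoma_deaths)
  expect_identical(base$stage1_diagnoses, ov$stage1_diagnoses)
  expect_true(all(ov$overdiagnoses[-1] > 0))
  expect_true(all(base$overdiagnoses == 0))
})

test_that("trajectories export to CSV with the documented columns", {
  pars <- parameter_set()
  traj <- run_trajectory(pars, make_constant_curves(pars$I0, pars$D0),
                         1982:1986, initial = NULL)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- utils::read.csv(path)
  expect_equal(dim(back), c(5L, 15L))
  expect_equal(back$year, 1982:1986)
  expect_equal(back$baseline, traj$baseline, tolerance = 1e-12)
})
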