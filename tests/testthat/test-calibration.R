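test_that("calibration is a fixed point when anchors equal the seed model's outputs", {
  seed <- parameter_set()
  out <- steady_outputs(seed)
  anchors <- anchor_set(inc_1982 = out[["incidence"]],
                        mort_1982 = out[["mortality"]],
                        prevalence_D1_1982 = out[["prevalence_diag_stage1"]])
  cal <- calibrate_1982(anchors, seed)
  expect_identical(unlist(cal$params), unlist(seed))
})

test_that("the flagship calibration matches the data anchors and is stationary", {
  m <- flagship_model()
  cal <- m$calibration
  expect_lt(abs(cal$residuals[["incidence"]]), 0.005)
  expect_lt(abs(cal$residuals[["mortality"]]), 0.005)
  # free parameters stay near their seeds
  expect_lt(abs(cal$params$I0 / 0.00031 - 1), 0.5)
  expect_lt(abs(cal$params$r / 0.00375 - 1), 0.5)
  # initial state is stationary for the year-0 curve values
  M <- build_transition_matrix(cal$params, cal$params$I0, cal$params$D0, 0)
  expect_lt(max(abs(as.numeric(cal$state %*% unclass(M)) -
                      as.numeric(cal$state))), 1e-10)
})

test_that("re-calibrating a calibrated model changes nothing", {
  m <- flagship_model()
  again <- calibrate_1982(anchor_set(), m$calibration$params)
  expect_identical(unlist(again$params), unlist(m$calibration$params))
})

test_that("fit_error is the pooled RMS relative deviation", {
  expect_equal(fit_error(1:5, 1:5, 1:5, 1:5), 0)
  expect_equal(fit_error(1.1 * (1:5), 1.1 * (6:10), 1:5, 6:10), 0.1)
  expect_error(fit_error(1:4, 1:5, 1:5, 1:5), "equal length")
  # invariant under a common rescaling of model and observed series
  obs <- build_observed_series(anchor_set())
  mi <- obs$incidence$rate_per_100k * 1.03
  mm <- obs$mortality$rate_per_100k * 0.97
  e1 <- fit_error(mi, mm, obs$incidence, obs$mortality)
  e2 <- fit_error(7 * mi, 7 * mm, 7 * obs$incidence$rate_per_100k,
                  7 * obs$mortality$rate_per_100k)
  expect_equal(e1, e2)
})

test_that("the grid fit recovers on-grid coefficients exactly and off-grid within a cell", {
  m <- flagship_model()
  pars <- m$calibration$params
  st <- m$initial_state
  D_curve <- make_curve("parabola_down", 0.05, 0.10)
  D_t <- evaluate_curve(D_curve, 0:31)
  b_grid <- exp(seq(log(5e-5), log(5e-3), length.out = 24))
  c_grid <- c(-rev(exp(seq(log(5e-5), log(5e-3), length.out = 12))),
              exp(seq(log(5e-5), log(5e-3), length.out = 12)))

  synth_obs <- function(b, c) {
    I_t <- pars$I0 + b * (0:31) / 31 + c * ((0:31) / 31)^2
    tr <- melmark:::run_schedule(pars, 1982:2013, I_t, D_t, initial = st)
    list(incidence = annual_series(1982:2013, tr$stage1_diagnoses +
                                     tr$stage23_diagnoses + tr$stage4_diagnoses),
         mortality = annual_series(1982:2013, tr$melanoma_deaths))
  }

  feasible_truth <- function(b, c) {
    I_t <- pars$I0 + b * (0:31) / 31 + c * ((0:31) / 31)^2
    all(I_t >= 0) && all(I_t + pars$d <= 1)
  }
  set.seed(99)
  for (k in 1:20) {
    repeat {
      b_true <- sample(b_grid, 1)
      c_true <- sample(c_grid, 1)
      if (feasible_truth(b_true, c_true)) break
    }
    fit <- grid_fit_I(pars, D_curve, synth_obs(b_true, c_true),
                      initial_state = st, b_grid = b_grid, c_grid = c_grid)
    expect_identical(fit$b, b_true)
    expect_identical(fit$c, c_true)
    expect_lt(fit$error, 1e-10)
  }

  # a well-identified off-grid truth lands in the adjacent cells
  b_true <- sqrt(b_grid[17] * b_grid[18])
  c_true <- -sqrt(abs(c_grid[5] * c_grid[6]))
  stopifnot(feasible_truth(b_true, c_true))
  fit <- grid_fit_I(pars, D_curve, synth_obs(b_true, c_true),
                    initial_state = st, b_grid = b_grid, c_grid = c_grid)
  expect_true(fit$b %in% b_grid[17:18])
  expect_true(fit$c %in% c_grid[5:6])
})

test_that("a single configuration with a single candidate reduces to the plain grid fit", {
  obs <- build_observed_series(anchor_set())
  sel <- select_best_model(configs = data.frame(D0 = 0.05, p = 15),
                           observed = obs,
                           families = "parabola_down",
                           D_end_sets = list(`0.05` = 0.10),
                           n_grid = 40)
  cal <- calibrate_1982(anchor_set(), parameter_set())
  fit <- grid_fit_I(cal$params, make_curve("parabola_down", 0.05, 0.10),
                    obs, initial_state = cal$state, n_grid = 40)
  expect_equal(sel$summary$error, fit$error)
  expect_equal(sel$models[[1]]$fit$b, fit$b)
})

test_that("infeasible grids are rejected", {
  m <- flagship_model()
  expect_error(grid_fit_I(m$calibration$params,
                          make_curve("parabola_down", 0.05, 0.10),
                          build_observed_series(anchor_set()),
                          initial_state = m$initial_state,
                          b_grid = c(2, 3), c_grid = c(2, 3)),
               "no feasible")
})
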