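test_that("transition matrix is row-stochastic with the documented sparsity", {
  pars <- parameter_set()
  M <- build_transition_matrix(pars, 0.00031, 0.05, 0)

  expect_equal(unname(rowSums(M)), rep(1, 8), tolerance = 1e-14)

  # structurally forbidden transitions are exactly zero
  expect_identical(M["diag_stage4", "baseline"], 0)
  expect_identical(M["diag_stage1", "baseline"], 0)
  expect_identical(M["baseline", "diag_stage1"], 0)
  expect_identical(M["baseline", "diag_stage23"], 0)
  expect_identical(M["baseline", "diag_stage4"], 0)
  expect_identical(M["diag_stage23", "undiag_stage23"], 0)
  expect_identical(unname(M["death", ]),
                   c(1, 0, 0, 0, 0, 0, 0, 0))
})

test_that("diagnosed Stage 4 row is the complement of q + d", {
  M <- build_transition_matrix(parameter_set(q = 0.37, d = 0.006),
                               0.0003, 0.05, 0)
  expect_equal(M["diag_stage4", "diag_stage4"], 0.624)
  expect_equal(M["diag_stage4", "death"], 0.376)
})

test_that("zero incidence and zero background death give an identity baseline row", {
  pars <- parameter_set(d = 0)
  M <- build_transition_matrix(pars, 0, 0, 0)
  expect_equal(unname(M["baseline", ]), c(1, rep(0, 7)))
})

test_that("progression rates derive from r and p as r, r/3, r/p, r/(3p)", {
  M <- build_transition_matrix(parameter_set(r = 0.00375, p = 15),
                               0.0003, 0.05, 0)
  expect_equal(M["undiag_stage1", "undiag_stage23"], 0.00375)
  expect_equal(M["undiag_stage1", "undiag_stage4"], 0.00125)
  expect_equal(M["diag_stage1", "diag_stage23"], 0.00025)
  expect_equal(M["diag_stage1", "diag_stage4"], 0.00375 / 45)
})

test_that("infeasible row sums are rejected with the row named", {
  pars <- parameter_set(t5 = 0.9, d = 0.2, q = 0.37)
  expect_error(build_transition_matrix(pars, 0.0003, 0.05, 0),
               "undiag_stage4")
})

test_that("a step without active transitions leaves living mass in place", {
  pars <- parameter_set(I0 = 0, r = 0, q = 0, d = 0,
                        t4 = 0, t5 = 0, t6 = 0, t7 = 0)
  M <- build_transition_matrix(pars, 0, 0, 0)
  st <- state_vector(c(0.5, 0.1, 0.1, 0.05, 0.15, 0.05, 0.05, 0))
  out <- step_cohort(st, M)
  expect_equal(as.numeric(out$state), as.numeric(st))
  expect_true(all(out$tally == 0))
})

test_that("every step conserves total occupancy", {
  set.seed(42)
  for (k in 1:20) {
    pars <- random_params()
    M <- build_transition_matrix(pars, pars$I0, pars$D0, pars$O0)
    st <- random_state()
    out <- step_cohort(st, M)
    expect_equal(sum(out$state), 1, tolerance = 1e-13)
    expect_true(all(out$state >= 0))
    expect_true(all(out$tally >= 0))
  }
})

test_that("one step matches a hand-worked balance oracle entry by entry", {
  p <- parameter_set()   # study defaults: D0 = 0.05, p = 15
  iv <- 0.00031; dv <- 0.05
  st <- state_vector(c(0.89980, 0.004, 0.0002, 0.00005,
                       0.032, 0.0002, 0.00015, 0.0636))
  out <- step_cohort(st, build_transition_matrix(p, iv, dv, 0))

  # independent pencil-and-paper balance equations, state by state
  b <- st[[1]]; u1 <- st[[2]]; u23 <- st[[3]]; u4 <- st[[4]]
  d1 <- st[[5]]; d23 <- st[[6]]; d4 <- st[[7]]; dd <- st[[8]]
  f1 <- 1 - p$f23 - p$f4
  expected <- c(
    b * (1 - iv - p$d) + dd,
    b * iv * f1 + u1 * (1 - dv - p$r - p$r / 3 - p$d),
    b * iv * p$f23 + u1 * p$r + u23 * (1 - p$t4 - p$t6 - p$d),
    b * iv * p$f4 + u1 * p$r / 3 + u23 * p$t6 + u4 * (1 - p$t5 - p$d),
    u1 * dv + d1 * (1 - p$r / p$p - p$r / (3 * p$p) - p$d),
    u23 * p$t4 + d1 * p$r / p$p + d23 * (1 - p$t7 - p$d),
    u4 * p$t5 + d1 * p$r / (3 * p$p) + d23 * p$t7 + d4 * (1 - p$q - p$d),
    (b + u1 + u23 + u4 + d1 + d23) * p$d + d4 * (p$q + p$d)
  )
  expect_equal(as.numeric(out$state), expected, tolerance = 1e-15)

  expect_equal(out$tally[["stage1_diagnoses"]], u1 * dv * 1e5)
  expect_equal(out$tally[["melanoma_deaths"]], d4 * p$q * 1e5)
  expect_equal(out$tally[["other_deaths"]], (1 - dd) * p$d * 1e5)
})
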