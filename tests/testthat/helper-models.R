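# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

flagship_model <- function() {
  if (is.null(.fixtures$flagship))
    .fixtures$flagship <- fit_model(D0 = 0.05, p = 15, n_grid = 100)
  .fixtures$flagship
}

# random admissible parameter set for property-style loops
random_params <- function() {
  parameter_set(I0 = runif(1, 1e-4, 5e-4),
                D0 = sample(c(0.01, 0.05), 1),
                r = runif(1, 0.001, 0.006),
                p = sample(c(2, 5, 15, 50, 125), 1),
                q = runif(1, 0.15, 0.4),
                d = runif(1, 0.004, 0.01),
                f23 = runif(1, 0.005, 0.05),
                f4 = runif(1, 0.002, 0.02))
}

# random valid occupancy vector
random_state <- function() {
  x <- runif(8)
  state_vector(x / sum(x))
}
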