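# shared fixtures, built in code

table1_low <- function() setting1_params("low")
table1_high <- function() setting1_params("high")

# uniform-kernel parameter set used by several closed-form checks:
# mu = 0.5, phi = 2 makes the Beta part uniform on (0, 1)
uniform_zib_params <- function(delta_zero = 0.2, beta = rep(0, 6),
                               delta = 1) {
  model_params(outcome_params(beta, delta),
               zib_params(0, 0, qlogis(delta_zero), 0, 2))
}

# a quick no-zeros data set (dominant taxon, huge library sizes)
nozero_data <- function(n = 150, seed = 401) {
  p <- model_params(outcome_params(c(-2, 100, 0, 5, 0, 0), 1),
                    zib_params(-1, 0.4, -50, 0, 50))
  sim <- simulate_setting1(n = n, params = p,
                           lib_size_range = c(1e8, 1e9), seed = seed)
  list(data = sim$data, truth = p)
}

random_theta <- function() {
  c(rnorm(6, 0, 2), exp(rnorm(1, 0, 0.3)), rnorm(1, -2, 1),
    rnorm(1, 0, 0.5), exp(rnorm(1, 2, 0.5)), rnorm(1, -1, 0.7),
    rnorm(1, 0, 0.5))
}
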