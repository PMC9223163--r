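test_that("initial_params produces sane moment-based starts", {
  sim <- simulate_setting1(n = 200, seed = 303)
  init <- initial_params(sim$data)
  th <- params_to_vector(init)
  # outcome slope within a factor of 3 of the generating value (100)
  expect_gt(th[["b1"]], 100 / 3)
  expect_lt(th[["b1"]], 100 * 3)
  expect_gt(th[["phi"]], 0)
  expect_gt(th[["delta"]], 0)

  # no zeros observed: the point mass is dropped
  nz <- nozero_data()
  init2 <- initial_params(nz$data)
  expect_identical(init2$mediator$gamma0, -Inf)
  mo <- zib_moments(init2$mediator, 0)
  expect_equal(mo$delta_zero, 0)

  bad <- sim$data
  bad$x <- 1
  expect_error(initial_params(bad), "no variation")
})

test_that("no-zeros fits equal the factorised Beta + linear-model MLEs", {
  nz <- nozero_data(n = 150, seed = 402)
  fit <- suppressWarnings(fit_mle(nz$data, interactions = "none"))
  expect_true(fit$converged)
  expect_equal(fit$n_zero_obs, 0L)
  th <- params_to_vector(fit$params)

  # with no zeros the likelihood factorises: the Beta-regression part can
  # be maximised on its own by direct optimisation
  m <- nz$data$m_obs; x <- nz$data$x; y <- nz$data$y
  beta_nll <- function(v) {
    mu <- plogis(v[1] + v[2] * x); phi <- exp(v[3])
    -sum(dbeta(m, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  ob <- optim(c(-1, 0.4, log(50)), beta_nll, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(th[["alpha0"]], ob$par[1], tolerance = 1e-4)
  expect_equal(th[["alpha1"]], ob$par[2], tolerance = 1e-4)
  expect_equal(th[["phi"]], exp(ob$par[3]), tolerance = 1e-4)

  lmfit <- lm(y ~ m + x)
  expect_equal(unname(th[c("b0", "b1", "b3")]), unname(coef(lmfit)),
               tolerance = 1e-4)
  # presence component is structurally absent
  expect_equal(effects_point(fit$params)$estimate[2], 0)
})

test_that("the MLE recovers the generating parameters and beats the truth
           in likelihood", {
  sim <- simulate_setting1(n = 200, seed = 11)
  fit <- suppressWarnings(fit_mle(sim$data, interactions = "indicator"))
  expect_true(fit$converged)
  th <- params_to_vector(fit$params)
  tt <- params_to_vector(sim$truth)
  se <- sqrt(diag(fit$vcov))
  for (nm in names(se)) {
    expect_lt(abs(th[[nm]] - tt[[nm]]), 3 * se[[nm]],
              label = sprintf("|%s - truth| vs 3 SE", nm))
  }
  # a maximiser can only do better than the generating values
  tt_fit <- sim$truth
  expect_gte(fit$loglik + 1e-8,
             total_loglik(sim$data, tt_fit))
})

test_that("log-transformed and box-constrained optimisation agree", {
  nz <- nozero_data(n = 120, seed = 77)
  fit <- suppressWarnings(fit_mle(nz$data, interactions = "none"))
  y <- nz$data$y; m <- nz$data$m_obs; x <- nz$data$x
  nll <- function(v) {
    mu <- plogis(v[4] + v[5] * x)
    -sum(dnorm(y, v[1] + v[2] * m + v[3] * x, v[6], log = TRUE) +
           dbeta(m, mu * v[7], (1 - mu) * v[7], log = TRUE))
  }
  th <- params_to_vector(fit$params)
  v0 <- c(th[["b0"]], th[["b1"]], th[["b3"]], th[["alpha0"]],
          th[["alpha1"]], 1, 40)
  ob <- optim(v0, nll, method = "L-BFGS-B",
              lower = c(rep(-Inf, 5), 1e-6, 1e-6),
              control = list(maxit = 2000, factr = 10))
  expect_equal(fit$loglik, -ob$value, tolerance = 1e-6)
})

test_that("degenerate designs are rejected", {
  expect_error(
    fit_mle(mediation_data(rnorm(10), rep(0, 10), rep(100, 10),
                           rbinom(10, 1, 0.5))),
    "absent in all samples")
  sim <- simulate_setting1(n = 30, seed = 12)
  expect_warning(fit_mle(sim$data, compute_info = FALSE),
                 "free parameters")
})

test_that("observed information matches a Richardson-extrapolated oracle
           and the linear-model closed form", {
  nz <- nozero_data(n = 120, seed = 55)
  fit <- suppressWarnings(fit_mle(nz$data, interactions = "none"))
  info <- fit$info
  expect_equal(info, t(info))

  # oracle: pracma's Richardson-extrapolated Hessian of the same loglik
  d <- nz$data
  free_idx <- which(fit$free)
  th0 <- params_to_vector(fit$params)
  f <- function(v) {
    th <- th0; th[free_idx] <- v
    total_loglik(d, vector_to_params(th))
  }
  H <- pracma::hessian(f, th0[free_idx])
  expect_equal(info, -(H + t(H)) / 2, tolerance = 1e-3,
               ignore_attr = TRUE)

  # the outcome-coefficient block has the exact linear-model form
  X <- cbind(1, d$m_obs, d$x)
  delta <- fit$params$outcome$delta
  expect_equal(unname(info[c("b0", "b1", "b3"), c("b0", "b1", "b3")]),
               unname(crossprod(X) / delta^2), tolerance = 1e-4)
})

test_that("tidy and glance summarise a fit", {
  sim <- simulate_setting1(n = 120, seed = 21)
  fit <- suppressWarnings(fit_mle(sim$data, interactions = "indicator"))
  td <- tidy(fit)
  expect_setequal(
    td$term,
    c("b0", "b1", "b2", "b3", "b4", "delta", "alpha0", "alpha1", "phi",
      "gamma0", "gamma1"))
  expect_true(all(td$std.error > 0, na.rm = TRUE))
  gl <- glance(fit)
  expect_identical(gl$nobs, 120L)
  expect_identical(gl$df, 11L)
})
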