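test_that("loglik_nonzero decomposes into normal and mediator densities", {
  p <- uniform_zib_params(delta_zero = 0.2)
  d <- mediation_data(y = 0, m_obs = 0.5, lib_size = 10, x = 0)
  expect_equal(loglik_nonzero(d, p), dnorm(0, log = TRUE) + log(0.8),
               tolerance = 1e-9)
  p0 <- uniform_zib_params(delta_zero = 0)
  p0$mediator$gamma0 <- -50
  expect_equal(loglik_nonzero(d, p0), dnorm(0, log = TRUE),
               tolerance = 1e-9)

  # definitional identity against the exported pieces, random inputs
  set.seed(77)
  for (k in 1:20) {
    th <- random_theta()
    pp <- vector_to_params(th)
    dd <- mediation_data(y = rnorm(5), m_obs = runif(5, 0.01, 0.95),
                         lib_size = rep(1e5, 5), x = rnorm(5))
    expect_equal(
      loglik_nonzero(dd, pp),
      dnorm(dd$y, outcome_mean(pp$outcome, dd$m_obs, dd$x),
            pp$outcome$delta, log = TRUE) +
        zib_logpdf(dd$m_obs, pp$mediator, dd$x),
      tolerance = 1e-10
    )
  }

  expect_error(loglik_nonzero(
    mediation_data(0, 0, 10, 0), p), "m > 0")
  expect_warning(loglik_nonzero(
    mediation_data(0, 1e-6, 10, 0), p), "treated as 1")
})

test_that("integrate_h matches closed forms and adaptive quadrature", {
  p <- uniform_zib_params(delta_zero = 0.2)
  d0 <- mediation_data(y = 0, m_obs = 0, lib_size = 10, x = 0)
  expect_equal(integrate_h(d0, p), 0.1, tolerance = 1e-10)
  d1 <- mediation_data(y = 1, m_obs = 0, lib_size = 10, x = 0)
  expect_equal(integrate_h(d1, p), exp(-0.5) * 0.1, tolerance = 1e-10)

  # strong endpoint singularity (mu * phi = 0.1) against stats::integrate
  set.seed(13)
  for (k in 1:10) {
    th <- random_theta()
    th[8] <- qlogis(0.1 / th[10])  # force a = mu * phi = 0.1 at x = 0
    pp <- vector_to_params(th)
    y <- rnorm(1); L <- round(runif(1, 50, 1e5))
    dd <- mediation_data(y = y, m_obs = 0, lib_size = L, x = 0)
    a <- 0.1; b <- (1 - plogis(th[8])) * th[10]
    f <- function(m) {
      m^(a - 1) * (1 - m)^(b - 1) *
        exp(-(y - th[1] - th[2] * m - th[3])^2 / (2 * th[7]^2))
    }
    oracle <- integrate(f, 0, 1 / L, rel.tol = 1e-13)$value
    expect_equal(integrate_h(dd, pp), oracle, tolerance = 1e-8)
  }
})

test_that("quadrature order 32 agrees with order 128", {
  set.seed(29)
  q32 <- quad_spec(32); q128 <- quad_spec(128)
  for (k in 1:10) {
    pp <- vector_to_params(random_theta())
    dd <- mediation_data(y = rnorm(1), m_obs = 0,
                         lib_size = round(runif(1, 20, 1e6)), x = 0)
    i32 <- integrate_h(dd, pp, q32)
    i128 <- integrate_h(dd, pp, q128)
    expect_equal(i32, i128, tolerance = 1e-9)
  }
  expect_error(quad_spec(4), "at least 8")
})

test_that("loglik_zero combines the structural and false-zero branches", {
  p <- uniform_zib_params(delta_zero = 0.2)
  d <- mediation_data(y = 0, m_obs = 0, lib_size = 10, x = 0)
  expect_equal(loglik_zero(d, p),
               dnorm(0, log = TRUE) + log(0.2 + 0.8 * 0.1),
               tolerance = 1e-9)

  # point mass at one: reduces to the normal density at b0 + b3 x
  p1 <- model_params(outcome_params(c(0.7, 1, 2, -0.4, 0, 0), 1.5),
                     zib_params(0, 0, 50, 0, 2))
  d1 <- mediation_data(y = 1.2, m_obs = 0, lib_size = 100, x = 1)
  expect_equal(loglik_zero(d1, p1),
               dnorm(1.2, 0.7 - 0.4, 1.5, log = TRUE), tolerance = 1e-8)

  # detection window shrinks to nothing as L grows
  dL <- mediation_data(y = 0, m_obs = 0, lib_size = 1e12, x = 0)
  expect_equal(loglik_zero(dL, p),
               dnorm(0, log = TRUE) + log(0.2), tolerance = 1e-6)
})

test_that("the observed-zero density integrates to the zero probability", {
  # integrating exp(loglik_zero) over the outcome equals
  # Delta + (1 - Delta) * P(M < 1/L): total mass of the zero group
  cases <- list(
    list(th = c(0.5, 2, 1, -0.5, 0.3, 0.1, 1.2, qlogis(0.3), 0.2,
                5, qlogis(0.25), -0.4), L = 20, x = 1),
    list(th = c(0, 3, -1, 0.8, 0, 0, 0.8, qlogis(0.05), 0.5,
                0.8, qlogis(0.4), 0.3), L = 8, x = 0)
  )
  for (cs in cases) {
    pp <- vector_to_params(cs$th)
    f <- function(y) {
      vapply(y, function(yy) {
        exp(loglik_zero(mediation_data(yy, 0, cs$L, cs$x), pp))
      }, numeric(1))
    }
    tot <- integrate(f, -30, 30, rel.tol = 1e-9)$value
    mo <- zib_moments(pp$mediator, cs$x)
    expected <- mo$delta_zero + (1 - mo$delta_zero) *
      pbeta(1 / cs$L, mo$mu * pp$mediator$phi,
            (1 - mo$mu) * pp$mediator$phi)
    expect_equal(tot, expected, tolerance = 1e-6)
  }
})

test_that("total_loglik is the sum of per-subject contributions", {
  set.seed(99)
  pp <- vector_to_params(c(-1, 5, 2, 0.5, 0.3, 0.1, 1, qlogis(0.1),
                           0.3, 10, qlogis(0.3), -0.5))
  sim <- simulate_setting1(n = 10, params = pp,
                           lib_size_range = c(20, 200), seed = 1)
  d <- sim$data
  pos <- d[d$r == 1, ]; zer <- d[d$r == 0, ]
  expect_gt(nrow(zer), 0)
  manual <- sum(loglik_nonzero(pos, pp)) + sum(loglik_zero(zer, pp))
  expect_equal(total_loglik(d, pp), manual, tolerance = 1e-10)

  # additivity under duplication
  d2 <- dplyr::bind_rows(d, d)
  expect_equal(total_loglik(d2, pp), 2 * total_loglik(d, pp),
               tolerance = 1e-10)

  # no zeros: reduces to the detected-group sum
  expect_equal(total_loglik(pos, pp), sum(loglik_nonzero(pos, pp)),
               tolerance = 1e-10)
})

test_that("loglik_zero is smooth in the parameters", {
  pp <- vector_to_params(c(-1, 5, 2, 0.5, 0.3, 0.1, 1, qlogis(0.1),
                           0.3, 10, qlogis(0.3), -0.5))
  d <- mediation_data(y = 0.4, m_obs = 0, lib_size = 100, x = 1)
  f <- function(th) loglik_zero(d, vector_to_params(th))
  th0 <- params_to_vector(pp)
  for (i in c(1, 2, 8, 11)) {  # b0, b1, alpha0, gamma0
    g <- function(h) {
      tp <- th0; tp[i] <- tp[i] + h
      tm <- th0; tm[i] <- tm[i] - h
      (f(tp) - f(tm)) / (2 * h)
    }
    # central differences at two step sizes agree: derivative exists
    expect_equal(g(1e-4), g(1e-5), tolerance = 1e-4)
  }
})
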