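test_that("the detection rule censors below one expected read", {
  expect_equal(apply_lod(0.002, 31607), 0.002)   # SAA = 63.2
  expect_equal(apply_lod(1e-6, 1e5), 0)          # SAA = 0.1
  expect_equal(apply_lod(0, 123), 0)
  expect_equal(apply_lod(c(0.5, 1e-9), c(10, 10)), c(0.5, 0))
})

test_that("the univariate generator reproduces its design conditions", {
  sim1 <- simulate_setting1(n = 500, seed = 42)
  sim2 <- simulate_setting1(n = 500, seed = 42)
  expect_identical(sim1$data, sim2$data)

  big <- simulate_setting1(n = 2e4, seed = 7)
  # structural zeros: average of Delta(0), Delta(1) ~ 0.199
  p_struct <- mean(big$data$m_true == 0)
  expect_lt(abs(p_struct - 0.1992), 3 * sqrt(0.2 * 0.8 / 2e4))
  # false zeros among all reads ~ 30% (within 5 points)
  p_false <- mean(big$data$m_true > 0 & big$data$m_obs == 0)
  expect_lt(abs(p_false - 0.30), 0.05)

  # dominant taxon: every truly present taxon is detected
  bigh <- simulate_setting1(n = 2e4, params = setting1_params("high"),
                            seed = 8)
  expect_identical(sum(bigh$data$m_true > 0 & bigh$data$m_obs == 0), 0L)

  # huge library sizes: observed zeros are exactly the structural zeros
  # (dominant-taxon Beta; the rare-taxon Beta is so spiked at zero that a
  # detection limit always censors part of it)
  hl <- simulate_setting1(n = 2000, params = setting1_params("high"),
                          lib_size_range = c(1e12, 1e12), seed = 9)
  expect_identical(hl$data$m_obs == 0, hl$data$m_true == 0)

  # outcome residuals at the generating parameters are Gaussian
  r <- big$data$y -
    outcome_mean(big$truth$outcome, big$data$m_true, big$data$x)
  expect_gt(shapiro.test(sample(r, 3000))$p.value, 0.01)
  expect_lt(abs(sd(r) - 1), 0.05)

  # analytic true effects ride along
  expect_equal(big$true_effects$estimate[3], 0.65176, tolerance = 1e-4)
})

test_that("the composition generator closes and hits its target means", {
  sim <- simulate_setting2(n = 300, seed = 5)
  expect_identical(sim$composition, sim$counts / sim$lib_size)
  expect_equal(unname(rowSums(sim$composition)), rep(1, 300),
               tolerance = 1e-12)
  expect_identical(unname(rowSums(sim$counts)), as.numeric(sim$lib_size))

  rep2 <- simulate_setting2(n = 300, seed = 5)
  expect_identical(rep2$composition, sim$composition)

  big <- simulate_setting2(n = 1e4, seed = 6)
  target <- c(0.196, 0.250, 0.220, 0.146, 0.188)
  mc_se <- apply(big$composition, 2, sd) / sqrt(1e4)
  expect_true(all(abs(colMeans(big$composition) - target) < 3 * mc_se))
  # zero fraction of the zero-inflated taxon ~ mean of Delta(0), Delta(1)
  dz <- mean(plogis(-0.5 + c(0, -1.5)))
  expect_lt(abs(mean(big$composition[, 2] == 0) - dz),
            3 * sqrt(dz * (1 - dz) / 1e4))
  # only the designated taxon is zero-inflated at these abundances
  expect_true(all(big$composition[, -2] > 0))

  # a null configuration carries no mediation labels
  null <- simulate_setting2(n = 50, exposure_shift = 0,
                            presence_coef = c(-0.5, 0), seed = 2)
  expect_false(any(null$truth$nie1_true))
  expect_false(any(null$truth$nie2_true))
  expect_identical(sim$truth$nie1_true, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(sim$truth$nie2_true, c(FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("null taxa keep exposure-independent means", {
  big <- simulate_setting2(n = 2e4, seed = 31)
  for (j in 3:5) {
    m0 <- big$composition[big$x == 0, j]
    m1 <- big$composition[big$x == 1, j]
    se <- sqrt(var(m0) / length(m0) + var(m1) / length(m1))
    expect_lt(abs(mean(m1) - mean(m0)), 3 * se)
  }
  # while the mediating pair trades abundance between arms
  d2 <- mean(big$composition[big$x == 1, 2]) -
    mean(big$composition[big$x == 0, 2])
  expect_lt(abs(d2 - 0.085), 0.02)
})

test_that("marginal coefficients follow the compositional identity", {
  sp <- full_model_spec(betas = c(10, 2), dirichlet_means = c(0.3, 0.7))
  mc <- marginal_coeffs(sp, 1)
  expect_equal(mc$value, c(2, 8, 0, 0))

  sp2 <- full_model_spec(betas = rep(4, 5),
                         dirichlet_means = rep(0.2, 5))
  for (j in 1:5) {
    expect_equal(marginal_coeffs(sp2, j)$value[2], 0)
  }
  expect_error(marginal_coeffs(sp, 3), "out of range")
})

test_that("marginal coefficients match a large-sample regression on the
           joint model", {
  set.seed(1234)
  n <- 1e5
  mu <- c(0.3, 0.5, 0.2); conc <- 40
  betas <- c(12, 3, -5); inter <- c(2, 0, -1); beta_x <- 1.5
  sp <- full_model_spec(betas, inter, beta_x, mu, conc)
  g <- matrix(rgamma(n * 3, shape = rep(conc * mu, each = n)), n, 3)
  M <- g / rowSums(g)
  x <- rbinom(n, 1, 0.5)
  y <- as.vector(M %*% betas + beta_x * x + (M %*% inter) * x) + rnorm(n)
  for (j in c(1, 3)) {
    mj <- M[, j]
    cf <- coef(lm(y ~ mj + x + x:mj))
    ses <- coef(summary(lm(y ~ mj + x + x:mj)))[, 2]
    expected <- marginal_coeffs(sp, j)$value
    expect_true(all(abs(cf - expected) < 3 * ses),
                label = sprintf("taxon %d marginal coefficients", j))
  }
})

test_that("simulated studies round-trip through the TSV writers", {
  dir <- withr::local_tempdir()
  sim <- simulate_setting2(n = 30, seed = 1)
  paths <- write_simulation(sim, dir, prefix = "s2")
  expect_length(paths, 3L)
  comp <- read_feature_table(paths[1])
  expect_equal(unname(comp), unname(sim$composition), tolerance = 1e-12)
  meta <- read_metadata(paths[2])
  expect_equal(meta$y, sim$y)
  expect_equal(meta$lib_size, sim$lib_size)
})
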