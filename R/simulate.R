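#' Limit-of-detection censoring rule
#'
#' A taxon with true relative abundance `m` in a sample of library size `L`
#' is observed as zero whenever its sample absolute abundance `m * L` falls
#' below one read: `P(M* = 0 | M, L) = 1(M L < 1)`. True zeros stay zero.
#'
#' @param m_true True relative abundance(s) in `[0, 1]`.
#' @param lib_size Library size(s), recycled.
#' @return Observed relative abundance(s): `0` where `m * L < 1`, else `m`.
#' @examples
#' apply_lod(c(0.002, 1e-6, 0), c(31607, 1e5, 1e5))
#' @export
apply_lod <- function(m_true, lib_size) {
  stopifnot(all(m_true >= 0 & m_true <= 1))
  ifelse(m_true * lib_size < 1, 0, m_true)
}

# draw zero-inflated Beta variates at per-draw mu / delta
rzib <- function(n, mu, phi, delta_zero) {
  z <- rbinom(n, 1L, delta_zero)
  m <- numeric(n)
  k <- z == 0L
  if (any(k)) {
    m[k] <- rbeta(sum(k), rep_len(mu, n)[k] * phi,
                  (1 - rep_len(mu, n)[k]) * phi)
  }
  m
}

# library sizes: log-uniform on a printed range, or resampled from a list
draw_lib_sizes <- function(n, lib_size_range, lib_sizes = NULL) {
  if (!is.null(lib_sizes)) {
    return(sample(lib_sizes, n, replace = TRUE))
  }
  stopifnot(length(lib_size_range) == 2L, all(lib_size_range > 0),
            lib_size_range[1] <= lib_size_range[2])
  round(exp(runif(n, log(lib_size_range[1]), log(lib_size_range[2]))))
}

#' True parameter sets of the univariate simulation scenarios
#'
#' Returns the generating parameters of the two univariate zero-inflated
#' Beta scenarios used for validation: a rare taxon (mean positive relative
#' abundance about 0.0025) and a dominant taxon (mean positive relative
#' abundance about 0.5). Both share the outcome coefficients
#' `beta = (-2, 100, 4, 5, 3, 0)`, `delta = 1`, `phi = 50` and the presence
#' model `gamma = (-1.16, -0.5)`; they differ in the abundance intercept
#' (`alpha0 = -6.2` vs `-1.0`, both with `alpha1 = 0.4`).
#'
#' @param scenario `"low"` or `"high"` relative abundance.
#' @return A [model_params()] object.
#' @export
setting1_params <- function(scenario = c("low", "high")) {
  scenario <- match.arg(scenario)
  model_params(
    outcome = outcome_params(beta = c(-2, 100, 4, 5, 3, 0), delta = 1),
    mediator = zib_params(
      alpha0 = if (scenario == "low") -6.2 else -1.0, alpha1 = 0.4,
      gamma0 = -1.16, gamma1 = -0.5, phi = 50)
  )
}

#' Simulate a univariate zero-inflated Beta mediation study
#'
#' Generates one taxon under the marginal model: binary exposure
#' `X ~ Bernoulli(0.5)`, library sizes log-uniform on `lib_size_range` (or
#' resampled from `lib_sizes`), latent relative abundance from the
#' zero-inflated Beta model at `params`, observed abundance censored by the
#' limit-of-detection rule ([apply_lod()]), and outcome from the outcome
#' regression evaluated at the *latent* mediator (false zeros distort only
#' what is observed, not the biology that generated the outcome).
#'
#' @param n Sample size.
#' @param params Generating truth as a [model_params()] object (default:
#'   the low-abundance scenario of [setting1_params()]).
#' @param lib_size_range Range for the log-uniform library-size law
#'   (default `c(31607, 911652)`).
#' @param lib_sizes Optional vector of empirical library sizes to resample
#'   instead of the log-uniform law.
#' @param seed Optional integer seed.
#' @param spec Contrast at which the analytic true effects are returned.
#' @return A list with `data` (a [mediation_data()] tibble with the extra
#'   latent column `m_true`), `truth` (the generating [model_params()]) and
#'   `true_effects` (closed-form effects at `spec`).
#' @export
simulate_setting1 <- function(n = 200, params = setting1_params("low"),
                              lib_size_range = c(31607, 911652),
                              lib_sizes = NULL, seed = NULL,
                              spec = effect_spec()) {
  stopifnot(inherits(params, "model_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  med <- params$mediator
  x <- rbinom(n, 1L, 0.5)
  L <- draw_lib_sizes(n, lib_size_range, lib_sizes)
  mu <- expit(med$alpha0 + med$alpha1 * x)
  dz <- expit(med$gamma0 + med$gamma1 * x)
  m_true <- rzib(n, mu, med$phi, dz)
  m_obs <- apply_lod(m_true, L)
  y <- outcome_mean(params$outcome, m_true, x) +
    rnorm(n, 0, params$outcome$delta)
  data <- mediation_data(y, m_obs, L, x)
  data$m_true <- m_true
  list(data = data, truth = params,
       true_effects = effects_point(params, spec))
}

#' Simulate a zero-inflated Dirichlet-multinomial composition study
#'
#' Generates a small community of `K + 1` taxa with a nested
#' (generalized-Dirichlet) composition, one designated zero-inflated taxon
#' whose presence follows a logistic model in the exposure, and read counts
#' drawn from a multinomial at the sampled library size (relative
#' abundances are counts over library size, so multinomial sampling can
#' create additional observed zeros for rare taxa).
#'
#' The community splits into a mediating pair (`shift_taxon`, `zi_taxon`)
#' and the remaining taxa. A Beta draw allocates total abundance between
#' pair and rest; within the pair, the zero-inflated taxon is present with
#' probability `1 - Delta(x) = 1 - expit(g0 + g1 x)` and, when present,
#' takes a Beta-distributed share of the pair mass whose mean moves with
#' the exposure; the remaining taxa divide the rest by a Dirichlet draw.
#' All parameters are solved from the target observed mean relative
#' abundances, so the exposure moves `exposure_shift` of mean abundance
#' from `shift_taxon` to `zi_taxon` while every other taxon's mean is
#' exactly exposure-free: only the designated pair carries abundance-scale
#' mediation and only the zero-inflated taxon carries presence-scale
#' mediation. The nesting also makes the pair strongly anticorrelated --
#' abundance lost by one member is gained by the other, as in a
#' competitive subcommunity -- while the null taxa are untouched by the
#' pair's internal rearrangement.
#'
#' The outcome depends on the latent abundances of the pair:
#' `Y = b0 + b11*M1 + b12*M2 + b2*1(M2>0) + b3*X + b4*X*1(M2>0) +
#' b5*X*M2 + e`, `e ~ N(0, sigma^2)`, with `M1` the shift taxon and `M2`
#' the zero-inflated taxon.
#'
#' @param n Sample size.
#' @param mean_ra Target observed mean relative abundances (sums to 1);
#'   default `c(0.196, 0.250, 0.220, 0.146, 0.188)`.
#' @param exposure_shift Difference in mean relative abundance moved from
#'   `shift_taxon` to `zi_taxon` between the two exposure arms (default
#'   0.085; 0 gives a no-abundance-mediation configuration).
#' @param zi_taxon Index of the zero-inflated taxon (default 2).
#' @param shift_taxon Index of the taxon donating abundance (default 1).
#' @param presence_coef Logistic coefficients `(g0, g1)` of the
#'   zero-probability of `zi_taxon`: `Delta(x) = expit(g0 + g1 x)`
#'   (default `c(-0.5, -1.5)`; `g1 = 0` gives no presence mediation).
#' @param conc_split Beta precision of the pair-versus-rest mass split
#'   (default 2000; the pair occupies a tightly regulated share of the
#'   community, so its members trade abundance with each other rather
#'   than with the null taxa).
#' @param conc_pair Beta precision of the within-pair share of the
#'   zero-inflated taxon (default 8; small, so the pair members trade
#'   abundance visibly across samples).
#' @param conc_rest Dirichlet precision of the remaining taxa (default
#'   50).
#' @param outcome_coef Outcome coefficients
#'   `(b0, b11, b12, b2, b3, b4, b5)` (default `c(1, 80, 2, 3, 1, 1, 1)`).
#' @param sigma Outcome residual SD (default 1).
#' @param lib_size_range,lib_sizes Library-size law as in
#'   [simulate_setting1()].
#' @param seed Optional integer seed.
#' @return A list with `composition` (n x (K+1) matrix of observed relative
#'   abundances, rows summing to 1), `counts`, `y`, `x`, `lib_size`,
#'   `truth` (tibble of per-taxon `nie1_true` / `nie2_true` labels) and
#'   `m_latent` (the latent proportions used for the outcome).
#' @export
simulate_setting2 <- function(n = 200,
                              mean_ra = c(0.196, 0.250, 0.220, 0.146,
                                          0.188),
                              exposure_shift = 0.085,
                              zi_taxon = 2L, shift_taxon = 1L,
                              presence_coef = c(-0.5, -1.5),
                              conc_split = 2000,
                              conc_pair = 8,
                              conc_rest = 50,
                              outcome_coef = c(1, 80, 2, 3, 1, 1, 1),
                              sigma = 1,
                              lib_size_range = c(31607, 911652),
                              lib_sizes = NULL, seed = NULL) {
  K1 <- length(mean_ra)
  stopifnot(K1 >= 3, abs(sum(mean_ra) - 1) < 1e-8,
            zi_taxon != shift_taxon,
            zi_taxon <= K1, shift_taxon <= K1,
            length(outcome_coef) == 7L, sigma > 0,
            conc_split > 0, conc_pair > 0, conc_rest > 0)
  if (!is.null(seed)) set.seed(seed)
  x <- rbinom(n, 1L, 0.5)
  L <- draw_lib_sizes(n, lib_size_range, lib_sizes)
  dz <- expit(presence_coef[1] + presence_coef[2] * x)

  pair_mass <- mean_ra[zi_taxon] + mean_ra[shift_taxon]
  rest <- setdiff(seq_len(K1), c(zi_taxon, shift_taxon))
  q_rest <- mean_ra[rest] / (1 - pair_mass)

  # within-pair mean share of the zero-inflated taxon, per arm, solved so
  # that E(M_zi | x) = mean + exposure_shift * (x - 1/2) including zeros
  share_for <- function(xv, dzv) {
    tgt <- mean_ra[zi_taxon] + exposure_shift * (xv - 0.5)
    s <- tgt / (pair_mass * (1 - dzv))
    if (s <= 0 || s >= 1) {
      abort("Infeasible configuration: within-pair share outside (0, 1).")
    }
    s
  }
  share <- vapply(c(0, 1), function(xv) {
    share_for(xv, expit(presence_coef[1] + presence_coef[2] * xv))
  }, numeric(1))
  share_i <- ifelse(x == 1, share[2], share[1])

  present <- rbinom(n, 1L, 1 - dz)
  t_mass <- rbeta(n, conc_split * pair_mass, conc_split * (1 - pair_mass))
  b_share <- rbeta(n, conc_pair * share_i, conc_pair * (1 - share_i))

  m_latent <- matrix(0, n, K1)
  m_latent[, zi_taxon] <- ifelse(present == 1L, t_mass * b_share, 0)
  m_latent[, shift_taxon] <- t_mass - m_latent[, zi_taxon]
  g <- matrix(stats::rgamma(n * length(rest),
                            shape = rep(conc_rest * q_rest, each = n),
                            rate = 1), n, length(rest))
  m_latent[, rest] <- (1 - t_mass) * g / rowSums(g)

  counts <- matrix(0L, n, K1)
  for (i in seq_len(n)) {
    counts[i, ] <- rmultinom(1L, L[i], m_latent[i, ])
  }
  composition <- counts / L
  colnames(composition) <- colnames(counts) <-
    paste0("taxon", seq_len(K1))

  oc <- outcome_coef
  m1 <- m_latent[, shift_taxon]
  m2 <- m_latent[, zi_taxon]
  y <- oc[1] + oc[2] * m1 + oc[3] * m2 + oc[4] * as.numeric(m2 > 0) +
    oc[5] * x + oc[6] * x * as.numeric(m2 > 0) + oc[7] * x * m2 +
    rnorm(n, 0, sigma)

  nie1_true <- rep(FALSE, K1)
  nie2_true <- rep(FALSE, K1)
  if (exposure_shift != 0) {
    nie1_true[c(shift_taxon, zi_taxon)] <- TRUE
  }
  if (presence_coef[2] != 0) nie2_true[zi_taxon] <- TRUE
  truth <- tibble(taxon = colnames(composition),
                  nie1_true = nie1_true, nie2_true = nie2_true)

  list(composition = composition, counts = counts, y = y, x = x,
       lib_size = L, truth = truth, m_latent = m_latent)
}

#' Full joint-model specification for the marginal-coefficient identity
#'
#' Describes the joint outcome model
#' `Y = sum_k beta_k M_k + beta_X X + sum_k beta_kk X M_k + e` with a
#' Dirichlet-distributed composition `M`, used to compute the implied
#' marginal (per-taxon) regression coefficients.
#'
#' @param betas Per-taxon outcome coefficients.
#' @param inter Per-taxon exposure-interaction coefficients (default 0).
#' @param beta_x Exposure main-effect coefficient.
#' @param dirichlet_means Dirichlet mean parameters (must sum to 1).
#' @param dispersion Dirichlet precision (positive).
#' @return An object of class `full_model_spec`.
#' @export
full_model_spec <- function(betas, inter = rep(0, length(betas)),
                            beta_x = 0, dirichlet_means,
                            dispersion = 50) {
  stopifnot(length(betas) == length(dirichlet_means),
            length(inter) == length(betas),
            abs(sum(dirichlet_means) - 1) < 1e-8, dispersion > 0)
  structure(list(betas = betas, inter = inter, beta_x = beta_x,
                 mu = dirichlet_means, dispersion = dispersion),
            class = "full_model_spec")
}

#' Marginal regression coefficients implied by the joint model
#'
#' For taxon `j` under a [full_model_spec()], the marginal association
#' `E(Y | M_j, X) = b0* + b1* M_j + b2* X + b3* X M_j` has
#' `b0* = sum_{k != j} beta_k mu_k / sum_{l != j} mu_l`,
#' `b1* = beta_j - b0*`,
#' `b2* = beta_X + sum_{k != j} beta_kk mu_k / sum_{l != j} mu_l`,
#' `b3* = beta_jj - sum_{k != j} beta_kk mu_k / sum_{l != j} mu_l`.
#' This is how a marginal per-taxon model remains consistent with the
#' compositional structure of the full model.
#'
#' @param spec A [full_model_spec()] object.
#' @param j Taxon index.
#' @return A tibble with columns `term` (`b0s`, `b1s`, `b2s`, `b3s`) and
#'   `value`.
#' @export
marginal_coeffs <- function(spec, j) {
  stopifnot(inherits(spec, "full_model_spec"))
  K1 <- length(spec$betas)
  if (j < 1 || j > K1) abort("`j` out of range.")
  denom <- sum(spec$mu[-j])
  if (denom <= 0) abort("Remaining Dirichlet mass is zero.")
  b0s <- sum(spec$betas[-j] * spec$mu[-j]) / denom
  w <- sum(spec$inter[-j] * spec$mu[-j]) / denom
  tibble(
    term = c("b0s", "b1s", "b2s", "b3s"),
    value = c(b0s, spec$betas[j] - b0s, spec$beta_x + w,
              spec$inter[j] - w)
  )
}

#' Write a simulated study to tab-separated files
#'
#' Writes a feature table (samples x taxa), a metadata table
#' (`sample_id`, `y`, `x`, `lib_size`) and, when available, truth labels.
#'
#' @param sim Result of [simulate_setting1()] or [simulate_setting2()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(sim$composition)) {
    comp <- as.data.frame(sim$composition)
    meta <- data.frame(sample_id = paste0("s", seq_along(sim$y)),
                       y = sim$y, x = sim$x, lib_size = sim$lib_size)
  } else {
    comp <- data.frame(taxon1 = sim$data$m_obs)
    meta <- data.frame(sample_id = paste0("s", seq_len(nrow(sim$data))),
                       y = sim$data$y, x = sim$data$x,
                       lib_size = sim$data$lib_size)
  }
  comp <- cbind(sample_id = meta$sample_id, comp)
  paths <- file.path(dir, paste0(prefix, c("_features.tsv",
                                           "_metadata.tsv",
                                           "_truth.tsv")))
  utils::write.table(comp, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(meta, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(sim$truth) && is.data.frame(sim$truth)) {
    utils::write.table(as.data.frame(sim$truth), paths[3], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    paths <- paths[1:2]
  }
  invisible(paths)
}
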