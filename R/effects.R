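#' Exposure contrast specification
#'
#' Describes the contrast for which mediation effects are computed:
#' exposure moving from `x1` to `x2`, the controlled mediator value for the
#' controlled direct effect, and the confidence level.
#'
#' @param x1 Reference exposure (default 0).
#' @param x2 Comparison exposure (default 1).
#' @param cde_level Controlled mediator value `m` in `[0, 1)` for the CDE
#'   (default 0, i.e. absence).
#' @param ci_level Confidence level in (0, 1) (default 0.95).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(x1 = 0, x2 = 1, cde_level = 0, ci_level = 0.95) {
  if (cde_level < 0 || cde_level >= 1) {
    abort("`cde_level` must lie in [0, 1).")
  }
  if (ci_level <= 0 || ci_level >= 1) {
    abort("`ci_level` must lie in (0, 1).")
  }
  structure(list(x1 = x1, x2 = x2, cde_level = cde_level,
                 ci_level = ci_level),
            class = "effect_spec")
}

# effect values as a named vector, for a canonical theta vector
effect_values <- function(theta, spec) {
  b <- theta[1:6]
  mu1 <- expit(theta[8] + theta[9] * spec$x1)
  mu2 <- expit(theta[8] + theta[9] * spec$x2)
  g1 <- theta[11] + theta[12] * spec$x1
  g2 <- theta[11] + theta[12] * spec$x2
  d1 <- ifelse(is.finite(g1), expit(g1), 0)
  d2 <- ifelse(is.finite(g2), expit(g2), 0)
  em1 <- (1 - d1) * mu1
  em2 <- (1 - d2) * mu2
  nie1 <- (b[2] + b[6] * spec$x2) * (em2 - em1)
  nie2 <- (b[3] + b[5] * spec$x2) * (d1 - d2)
  nde <- (spec$x2 - spec$x1) * (b[4] + b[5] * (1 - d1) + b[6] * em1)
  cde <- (spec$x2 - spec$x1) *
    (b[4] + b[5] * as.numeric(spec$cde_level > 0) + b[6] * spec$cde_level)
  c(NIE1 = unname(nie1), NIE2 = unname(nie2), NIE = unname(nie1 + nie2),
    NDE = unname(nde), CDE = unname(cde))
}

#' Closed-form mediation effects at given parameter values
#'
#' Computes the natural indirect effect and its decomposition under the
#' potential-outcomes framework for the exposure contrast in `spec`:
#'
#' * `NIE1 = (b1 + b5*x2) * (E(M(x2)) - E(M(x1)))` with
#'   `E(M(x)) = (1 - Delta(x)) * mu(x)` -- the mediation effect carried by
#'   the numeric change of the relative abundance;
#' * `NIE2 = (b2 + b4*x2) * (Delta(x1) - Delta(x2))` -- the effect carried
#'   by the mediator switching between absence and presence;
#' * `NIE = NIE1 + NIE2`;
#' * `NDE = (x2 - x1) * (b3 + b4*(1 - Delta(x1)) + b5*E(M(x1)))` (mediator
#'   held at its `x1`-world distribution);
#' * `CDE = (x2 - x1) * (b3 + b4*1(m>0) + b5*m)` at the controlled value
#'   `m = cde_level`.
#'
#' @param params A [model_params()] object.
#' @param spec An [effect_spec()] object.
#' @return A tibble of class `marzic_effects` with columns `effect` and
#'   `estimate`.
#' @examples
#' truth <- setting1_params("low")
#' effects_point(truth)
#' @export
effects_point <- function(params, spec = effect_spec()) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "effect_spec"))
  vals <- effect_values(params_to_vector(params), spec)
  out <- tibble(effect = names(vals), estimate = unname(vals))
  attr(out, "spec") <- spec
  class(out) <- c("marzic_effects", class(out))
  out
}

#' Delta-method confidence intervals for mediation effects
#'
#' For each effect `g(theta)` the standard error is
#' `sqrt(grad(g)' V grad(g))` where `V` is the inverse observed information
#' of the fit and the gradient is taken by central finite differences
#' (relative step `1e-6`) over the free parameters on the original scale.
#' Wald intervals and two-sided normal p-values follow. An effect whose
#' gradient vanishes identically (e.g. the presence component when the
#' data contain no zeros) gets `se = 0` and `p = 1`.
#'
#' @param fit A converged `marzic_fit`.
#' @param spec An [effect_spec()] object.
#' @return A tibble of class `marzic_effects` with columns `effect`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`, `p.value`.
#' @export
effects_ci <- function(fit, spec = effect_spec()) {
  stopifnot(inherits(fit, "marzic_fit"), inherits(spec, "effect_spec"))
  if (!fit$converged) abort("Fit did not converge; refusing inference.")
  if (is.null(fit$vcov)) {
    abort("Observed information is singular; cannot form intervals.")
  }
  kap <- kappa(fit$info, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    wc <- which.min(abs(diag(fit$info)))
    abort(sprintf(
      "Observed information is ill-conditioned (kappa = %.2e); weakest direction near `%s`.",
      kap, colnames(fit$info)[wc]))
  }
  theta <- params_to_vector(fit$params)
  free <- fit$free
  idx <- which(free)
  est <- effect_values(theta, spec)
  G <- matrix(0, length(est), length(idx),
              dimnames = list(names(est), names(theta)[idx]))
  for (j in seq_along(idx)) {
    h <- 1e-6 * max(abs(theta[idx[j]]), 1)
    tp <- theta; tp[idx[j]] <- tp[idx[j]] + h
    tm <- theta; tm[idx[j]] <- tm[idx[j]] - h
    G[, j] <- (effect_values(tp, spec) - effect_values(tm, spec)) / (2 * h)
  }
  V <- fit$vcov
  se <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  zero_grad <- rowSums(abs(G)) == 0
  se[zero_grad] <- 0
  z <- qnorm(1 - (1 - spec$ci_level) / 2)
  pv <- ifelse(se > 0, 2 * pnorm(-abs(est / se)),
               ifelse(est == 0, 1, 0))
  out <- tibble(
    effect = names(est),
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se),
    p.value = unname(pv)
  )
  attr(out, "spec") <- spec
  class(out) <- c("marzic_effects", class(out))
  out
}

#' Nonparametric bootstrap intervals for mediation effects
#'
#' Case-resampling bootstrap: subjects are resampled with replacement, the
#' model is refitted, and percentile intervals are formed from the
#' successfully converged refits. Refits that fail are dropped and counted;
#' more than 20 percent failures is an error.
#'
#' @param data A [mediation_data()] tibble.
#' @param spec An [effect_spec()] object.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Integer seed for reproducibility.
#' @param quad A [quad_spec()] object.
#' @param interactions Interaction configuration, see [initial_params()].
#' @return A tibble of class `marzic_effects` with percentile intervals,
#'   bootstrap standard errors and normal-approximation p-values; the
#'   number of failed refits is stored in the `n_failed` attribute.
#' @export
effects_bootstrap <- function(data, spec = effect_spec(), n_boot = 500,
                              seed = 1L, quad = quad_spec(),
                              interactions = "both") {
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  set.seed(seed)
  full <- fit_mle(data, quad = quad, interactions = interactions,
                  compute_info = FALSE)
  est <- effect_values(params_to_vector(full$params), spec)
  draws <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
  failed <- 0L
  for (bidx in seq_len(n_boot)) {
    rows <- sample.int(nrow(data), replace = TRUE)
    bd <- data[rows, , drop = FALSE]
    fb <- tryCatch(
      fit_mle(bd, quad = quad, init = full$params,
              interactions = interactions, compute_info = FALSE),
      error = function(e) NULL
    )
    if (is.null(fb) || !fb$converged) {
      failed <- failed + 1L
      next
    }
    draws[bidx, ] <- effect_values(params_to_vector(fb$params), spec)
  }
  if (failed > 0.2 * n_boot) {
    abort(sprintf("%d of %d bootstrap refits failed.", failed, n_boot))
  }
  draws <- draws[complete.cases(draws), , drop = FALSE]
  alpha <- 1 - spec$ci_level
  se <- apply(draws, 2, sd)
  lo <- apply(draws, 2, quantile, probs = alpha / 2, names = FALSE)
  hi <- apply(draws, 2, quantile, probs = 1 - alpha / 2, names = FALSE)
  pv <- ifelse(se > 0, 2 * pnorm(-abs(est / se)),
               ifelse(est == 0, 1, 0))
  out <- tibble(
    effect = names(est),
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(lo),
    conf.high = unname(hi),
    p.value = unname(pv)
  )
  attr(out, "spec") <- spec
  attr(out, "n_failed") <- failed
  attr(out, "n_boot") <- n_boot
  class(out) <- c("marzic_effects", class(out))
  out
}

#' @method tidy marzic_effects
#' @export
tidy.marzic_effects <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Forest plot of mediation effect estimates
#'
#' @param object A `marzic_effects` tibble with interval columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marzic_effects
#' @export
autoplot.marzic_effects <- function(object, ...) {
  if (!all(c("conf.low", "conf.high") %in% names(object))) {
    abort("Intervals missing; use `effects_ci()` or `effects_bootstrap()`.")
  }
  ggplot(object, aes(x = .data$effect, y = .data$estimate)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_pointrange(aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    labs(x = NULL, y = "Effect estimate") +
    theme_minimal()
}
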