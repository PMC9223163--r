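#' Moment-based starting values
#'
#' Builds a starting point for the maximum-likelihood fit: outcome
#' coefficients by least squares of `y` on the design
#' `(1, m, 1(m>0), x, x*1(m>0), x*m)` (restricted by the interaction
#' configuration), residual SD for `delta`, a logit-link quasi-likelihood
#' moment fit on the positive abundances for `(alpha0, alpha1)`, Beta
#' method-of-moments for `phi`, and logistic regression of the zero
#' indicator on `x` for `(gamma0, gamma1)`.
#'
#' @param data A [mediation_data()] tibble.
#' @param interactions Which exposure-mediator interaction terms to keep:
#'   `"both"` (default), `"indicator"` (only `x * 1(m>0)`), `"abundance"`
#'   (only `x * m`), or `"none"`.
#' @return A [model_params()] object.
#' @export
initial_params <- function(data,
                           interactions = c("both", "indicator",
                                            "abundance", "none")) {
  interactions <- match.arg(interactions)
  if (length(unique(data$x)) < 2L) {
    abort("exposure has no variation")
  }
  pos <- data$m_obs > 0
  if (!any(pos)) abort("taxon absent in all samples")
  has_zeros <- any(!pos)
  free <- free_mask(interactions, has_zeros)

  # outcome regression
  X <- cbind(1, data$m_obs, as.numeric(pos), data$x,
             data$x * as.numeric(pos), data$x * data$m_obs)
  colnames(X) <- param_names()[1:6]
  Xf <- X[, free[1:6], drop = FALSE]
  fit <- lm.fit(Xf, data$y)
  beta <- setNames(numeric(6), param_names()[1:6])
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  beta[colnames(Xf)] <- cf
  delta <- max(sd(fit$residuals), 1e-3)

  # abundance model on positive observations
  mp <- data$m_obs[pos]
  xp <- data$x[pos]
  if (length(unique(xp)) >= 2L) {
    gq <- suppressWarnings(
      glm(mp ~ xp, family = stats::quasibinomial("logit"))
    )
    alpha <- unname(coef(gq))
    muhat <- stats::fitted(gq)
  } else {
    alpha <- c(qlogis(min(max(mean(mp), 1e-8), 1 - 1e-8)), 0)
    muhat <- rep(mean(mp), length(mp))
  }
  alpha[!is.finite(alpha)] <- 0
  v <- mean((mp - muhat)^2)
  phi <- mean(muhat * (1 - muhat)) / max(v, 1e-12) - 1
  phi <- min(max(phi, 0.5), 1e4)

  # presence model
  if (has_zeros) {
    gz <- suppressWarnings(glm(I(1 - as.numeric(pos)) ~ data$x,
                               family = binomial()))
    gamma <- unname(coef(gz))
    gamma[!is.finite(gamma)] <- 0
    gamma <- pmin(pmax(gamma, -10), 10)
  } else {
    gamma <- c(-Inf, 0)
  }

  model_params(
    outcome = outcome_params(beta = unname(beta), delta = delta),
    mediator = zib_params(alpha0 = alpha[1], alpha1 = alpha[2],
                          gamma0 = gamma[1], gamma1 = gamma[2], phi = phi)
  )
}

# central-difference gradient with relative step
num_gradient <- function(f, theta, rel_step = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    h <- rel_step * max(abs(theta[i]), 1)
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    g[i] <- (f(tp) - f(tm)) / (2 * h)
  }
  g
}

#' Maximum-likelihood fit of the mediation model for one taxon
#'
#' Maximises the complete log-likelihood (detected subjects plus the
#' false-zero-integrated contribution of observed zeros) by quasi-Newton
#' (BFGS) optimisation on an unconstrained scale (`delta` and `phi` are
#' log-transformed), with a numerical central-difference gradient and up to
#' three jittered restarts on failure. When the data contain no observed
#' zeros the point mass is not identifiable and the zero part of the model
#' (`gamma0`, `gamma1`, `b2`, `b4`) is dropped, which reduces to the
#' no-zeros marginal model; the presence component of the mediation effect
#' is then structurally zero.
#'
#' @param data A [mediation_data()] tibble (see [mediation_data()]).
#' @param quad A [quad_spec()] object.
#' @param init Optional [model_params()] starting point; defaults to
#'   [initial_params()].
#' @param interactions Interaction configuration, see [initial_params()].
#' @param compute_info Compute the observed information matrix at the
#'   optimum (default `TRUE`; needed for delta-method intervals).
#' @return An object of class `marzic_fit` with elements `params`
#'   ([model_params()] at the MLE), `loglik`, `converged`, `n_obs`,
#'   `n_zero_obs`, `free` (logical mask of estimated parameters in the
#'   canonical ordering), `info` (observed information over the free
#'   parameters, original scale) and `vcov` (its inverse).
#' @examples
#' sim <- simulate_setting1(n = 150, seed = 7)
#' fit <- fit_mle(sim$data, interactions = "indicator")
#' glance(fit)
#' @export
fit_mle <- function(data, quad = quad_spec(), init = NULL,
                    interactions = c("both", "indicator", "abundance",
                                     "none"),
                    compute_info = TRUE) {
  interactions <- match.arg(interactions)
  stopifnot(inherits(quad, "quad_spec"))
  if (!all(c("y", "m_obs", "r", "lib_size", "x") %in% names(data))) {
    data <- mediation_data(data$y, data$m_obs, data$lib_size, data$x)
  }
  pos <- data$m_obs > 0
  if (!any(pos)) abort("taxon absent in all samples")
  has_zeros <- any(!pos)
  free <- free_mask(interactions, has_zeros)
  p_free <- sum(free)
  if (nrow(data) < 5 * p_free) {
    warn(sprintf("Only %d observations for %d free parameters.",
                 nrow(data), p_free))
  }
  init <- init %||% initial_params(data, interactions)
  theta0 <- params_to_vector(init)
  theta0[!free & !(names(theta0) %in% c("gamma0", "gamma1"))] <- 0
  if (!has_zeros) { theta0["gamma0"] <- -Inf; theta0["gamma1"] <- 0 }

  y <- data$y; m <- data$m_obs; r <- data$r
  L <- data$lib_size; x <- data$x

  # transformed free vector: log(delta), log(phi); others identity
  trans_names <- names(theta0)[free]
  to_opt <- function(theta) {
    v <- theta[free]
    v[trans_names == "delta"] <- log(v[trans_names == "delta"])
    v[trans_names == "phi"] <- log(v[trans_names == "phi"])
    v
  }
  from_opt <- function(v) {
    v[trans_names == "delta"] <- exp(v[trans_names == "delta"])
    v[trans_names == "phi"] <- exp(v[trans_names == "phi"])
    theta <- theta0
    theta[free] <- v
    theta
  }
  negll <- function(v) {
    theta <- from_opt(v)
    val <- tryCatch(
      -ll_total_kernel(y, m, r, L, x, theta, quad, zero_model = has_zeros),
      error = function(e) Inf
    )
    if (!is.finite(val)) val <- 1e10
    val
  }
  grad <- function(v) num_gradient(negll, v)

  v0 <- to_opt(theta0)
  best <- NULL
  for (attempt in 0:3) {
    v_start <- if (attempt == 0) v0 else {
      v0 + rnorm(length(v0), 0, 0.1 * pmax(abs(v0), 0.5))
    }
    opt <- tryCatch(
      optim(v_start, negll, gr = grad, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    ok <- opt$convergence == 0 &&
      max(abs(grad(opt$par))) < 1e-3 * max(1, abs(opt$value))
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$ok <- ok
    }
    if (ok) break
  }
  if (is.null(best)) {
    abort("Optimization failed on all attempts.")
  }
  theta_hat <- from_opt(best$par)
  params_hat <- vector_to_params_safe(theta_hat)
  out <- structure(
    list(params = params_hat, loglik = -best$value,
         converged = isTRUE(best$ok), n_obs = nrow(data),
         n_zero_obs = sum(!pos), free = free,
         interactions = interactions, has_zeros = has_zeros,
         data = data, quad = quad, info = NULL, vcov = NULL),
    class = "marzic_fit"
  )
  if (compute_info) {
    out$info <- observed_info(data, params_hat, quad, free = free)
    out$vcov <- tryCatch(solve(out$info), error = function(e) NULL)
  }
  out
}

# vector_to_params that tolerates gamma0 = -Inf (dropped zero model)
vector_to_params_safe <- function(theta) {
  model_params(
    outcome = outcome_params(beta = unname(theta[1:6]),
                             delta = unname(theta[7])),
    mediator = structure(
      list(alpha0 = unname(theta[8]), alpha1 = unname(theta[9]),
           gamma0 = unname(theta[11]), gamma1 = unname(theta[12]),
           phi = unname(theta[10])),
      class = "zib_params")
  )
}

#' Observed Fisher information
#'
#' Negative Hessian of the complete log-likelihood by central finite
#' differences on the original parameter scale (relative step `1e-4`),
#' symmetrised as `(H + t(H)) / 2`, restricted to the free parameters.
#'
#' @param data A [mediation_data()] tibble.
#' @param params A [model_params()] object (at or near the optimum).
#' @param quad A [quad_spec()] object.
#' @param free Logical mask (canonical ordering) of free parameters;
#'   defaults to all twelve when the data contain zeros.
#' @param rel_step Relative finite-difference step (default `1e-4`).
#' @return Symmetric matrix with dimnames from the canonical parameter
#'   names.
#' @export
observed_info <- function(data, params, quad = quad_spec(), free = NULL,
                          rel_step = 1e-4) {
  theta <- params_to_vector(params)
  has_zeros <- any(data$m_obs == 0)
  free <- free %||% free_mask("both", has_zeros)
  y <- data$y; m <- data$m_obs; r <- data$r
  L <- data$lib_size; x <- data$x
  f <- function(th) {
    ll_total_kernel(y, m, r, L, x, th, quad, zero_model = has_zeros)
  }
  idx <- which(free)
  p <- length(idx)
  h <- rel_step * pmax(abs(theta[idx]), 1e-2)
  H <- matrix(NA_real_, p, p)
  f0 <- f(theta)
  for (i in seq_len(p)) {
    ei <- idx[i]
    tp <- theta; tp[ei] <- tp[ei] + h[i]
    tm <- theta; tm[ei] <- tm[ei] - h[i]
    H[i, i] <- (f(tp) + f(tm) - 2 * f0) / h[i]^2
    if (i < p) {
      for (j in seq((i + 1), p)) {
        ej <- idx[j]
        tpp <- theta; tpp[ei] <- tpp[ei] + h[i]; tpp[ej] <- tpp[ej] + h[j]
        tpm <- theta; tpm[ei] <- tpm[ei] + h[i]; tpm[ej] <- tpm[ej] - h[j]
        tmp <- theta; tmp[ei] <- tmp[ei] - h[i]; tmp[ej] <- tmp[ej] + h[j]
        tmm <- theta; tmm[ei] <- tmm[ei] - h[i]; tmm[ej] <- tmm[ej] - h[j]
        H[i, j] <- H[j, i] <-
          (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h[i] * h[j])
      }
    }
  }
  if (any(!is.finite(H))) {
    bad <- which(!is.finite(H), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite information entry for (%s, %s).",
                  param_names()[idx[bad[1]]], param_names()[idx[bad[2]]]))
  }
  info <- -(H + t(H)) / 2
  dimnames(info) <- list(param_names()[idx], param_names()[idx])
  info
}

#' @export
print.marzic_fit <- function(x, ...) {
  cat("<marzic_fit> ", if (x$converged) "converged" else "NOT converged",
      "\n", sep = "")
  cat("  n =", x$n_obs, "(", x$n_zero_obs, "observed zeros ), logLik =",
      format(x$loglik, digits = 6), "\n")
  cat("  free parameters:", paste(names(x$free)[x$free], collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy a mediation model fit
#'
#' @param x A `marzic_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy marzic_fit
#' @export
tidy.marzic_fit <- function(x, ...) {
  est <- params_to_vector(x$params)[x$free]
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else
    rep(NA_real_, sum(x$free))
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se)))
  )
}

#' One-row summary of a mediation model fit
#'
#' @param x A `marzic_fit` object.
#' @param ... Unused.
#' @return A tibble with `logLik`, `df`, `converged`, `nobs`, `n_zero_obs`.
#' @method glance marzic_fit
#' @export
glance.marzic_fit <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    df = sum(x$free),
    converged = x$converged,
    nobs = x$n_obs,
    n_zero_obs = x$n_zero_obs
  )
}
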