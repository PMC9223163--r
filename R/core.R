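#' Moments of the zero-inflated Beta mediator at an exposure value
#'
#' Evaluates the link functions of the mediator model at exposure `x`:
#' the Beta mean `mu(x)`, the zero probability `Delta(x)`, the presence
#' probability `1 - Delta(x)` and the overall mean of the zero-inflated
#' distribution `E(M | x) = (1 - Delta(x)) * mu(x)` (the point mass at zero
#' contributes nothing to the mean).
#'
#' @param params A [zib_params()] object.
#' @param x Exposure value(s); vectorised.
#' @return A tibble with columns `x`, `mu`, `delta_zero`, `prob_positive`,
#'   `mean_m`.
#' @examples
#' p <- zib_params(-6.2, 0.4, -1.16, -0.5, phi = 50)
#' zib_moments(p, x = c(0, 1))
#' @export
zib_moments <- function(params, x) {
  stopifnot(inherits(params, "zib_params"))
  mu <- expit(params$alpha0 + params$alpha1 * x)
  dz <- expit(params$gamma0 + params$gamma1 * x)
  tibble(
    x = x,
    mu = mu,
    delta_zero = dz,
    prob_positive = 1 - dz,
    mean_m = (1 - dz) * mu
  )
}

#' Log-density of the zero-inflated Beta distribution
#'
#' Two-part density: probability mass `Delta(x)` at zero and, on (0, 1),
#' `(1 - Delta(x))` times a Beta density with shapes `mu(x) * phi` and
#' `(1 - mu(x)) * phi`.
#'
#' @param m Observed relative abundance(s) in `[0, 1)`.
#' @param params A [zib_params()] object.
#' @param x Exposure value(s), recycled against `m`.
#' @return Log-density values.
#' @export
zib_logpdf <- function(m, params, x) {
  stopifnot(inherits(params, "zib_params"))
  if (any(m < 0 | m >= 1)) {
    abort("`m` must lie in [0, 1).")
  }
  k <- pmax(length(m), length(x))
  m <- rep_len(m, k); x <- rep_len(x, k)
  mu <- expit(params$alpha0 + params$alpha1 * x)
  dz <- expit(params$gamma0 + params$gamma1 * x)
  out <- numeric(k)
  z <- m == 0
  out[z] <- log(dz[z])
  if (any(!z)) {
    out[!z] <- log1p(-dz[!z]) +
      dbeta(m[!z], mu[!z] * params$phi, (1 - mu[!z]) * params$phi, log = TRUE)
  }
  out
}

#' Conditional mean of the outcome regression
#'
#' `E(Y | M = m, X = x) = b0 + b1*m + b2*1(m>0) + b3*x + b4*x*1(m>0) +
#' b5*x*m`.
#'
#' @param params An [outcome_params()] object.
#' @param m Mediator value(s) in `[0, 1)`.
#' @param x Exposure value(s), recycled.
#' @return Numeric vector of conditional means.
#' @export
outcome_mean <- function(params, m, x) {
  stopifnot(inherits(params, "outcome_params"))
  b <- params$beta
  pos <- as.numeric(m > 0)
  b[1] + b[2] * m + b[3] * pos + b[4] * x + b[5] * x * pos + b[6] * x * m
}

#' Assemble a per-taxon mediation data set
#'
#' Validates and aligns the observed vectors for one taxon: outcome `y`,
#' observed relative abundance `m_obs`, library size `lib_size` and exposure
#' `x`. The presence indicator `r = 1(m_obs > 0)` is derived. Relative
#' abundances numerically at (or above) 1 are clamped to `1 - 1e-10` with a
#' warning since the Beta support is open.
#'
#' @param y Continuous outcome vector.
#' @param m_obs Observed relative abundances in `[0, 1]`.
#' @param lib_size Positive library sizes (sequencing depths).
#' @param x Exposure vector.
#' @return A tibble of class `mediation_data` with columns
#'   `y`, `m_obs`, `r`, `lib_size`, `x`.
#' @export
mediation_data <- function(y, m_obs, lib_size, x) {
  n <- length(y)
  if (n < 1L) abort("Need at least one observation.")
  if (length(m_obs) != n || length(lib_size) != n || length(x) != n) {
    abort("`y`, `m_obs`, `lib_size` and `x` must have equal length.")
  }
  if (any(!is.finite(y)) || any(!is.finite(m_obs)) || any(!is.finite(x))) {
    abort("Non-finite values in `y`, `m_obs` or `x`.")
  }
  if (any(m_obs < 0) || any(m_obs > 1)) {
    abort("`m_obs` must lie in [0, 1].")
  }
  if (any(lib_size <= 0)) abort("`lib_size` must be positive.")
  hi <- m_obs >= 1 - 1e-10
  if (any(hi)) {
    warn(sprintf(
      "%d relative abundance value(s) at 1 clamped to 1 - 1e-10.", sum(hi)))
    m_obs[hi] <- 1 - 1e-10
  }
  out <- tibble(
    y = as.numeric(y),
    m_obs = as.numeric(m_obs),
    r = as.integer(m_obs > 0),
    lib_size = as.numeric(lib_size),
    x = as.numeric(x)
  )
  class(out) <- c("mediation_data", class(out))
  out
}
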