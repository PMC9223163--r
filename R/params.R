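#' Zero-inflated Beta mediator parameters
#'
#' Container for the marginal mediator model of one taxon. The positive part
#' of the relative abundance follows a Beta distribution with mean
#' `mu(x) = expit(alpha0 + alpha1 * x)` and dispersion `phi` (shapes
#' `mu * phi` and `(1 - mu) * phi`); the point mass at zero has probability
#' `Delta(x) = expit(gamma0 + gamma1 * x)`. `alpha1` carries the
#' exposure-to-abundance association and `gamma1` the exposure-to-presence
#' association.
#'
#' @param alpha0,alpha1 Intercept and exposure slope of the logit-linked
#'   Beta mean.
#' @param gamma0,gamma1 Intercept and exposure slope of the logit-linked
#'   zero probability.
#' @param phi Beta dispersion parameter (must be positive). Sometimes
#'   written xi in summaries of the same model.
#' @return An object of class `zib_params`.
#' @examples
#' zib_params(alpha0 = -6.2, alpha1 = 0.4, gamma0 = -1.16, gamma1 = -0.5,
#'            phi = 50)
#' @export
zib_params <- function(alpha0, alpha1, gamma0, gamma1, phi) {
  stopifnot(is.numeric(phi), length(phi) == 1L)
  if (!is.finite(phi) || phi <= 0) {
    abort("`phi` (Beta dispersion) must be a positive finite number.")
  }
  structure(
    list(alpha0 = as.numeric(alpha0), alpha1 = as.numeric(alpha1),
         gamma0 = as.numeric(gamma0), gamma1 = as.numeric(gamma1),
         phi = as.numeric(phi)),
    class = "zib_params"
  )
}

#' Outcome regression parameters
#'
#' Coefficients of the marginal outcome model
#' `Y = b0 + b1*M + b2*1(M>0) + b3*X + b4*X*1(M>0) + b5*X*M + e`,
#' with `e ~ N(0, delta^2)`; `delta` is the residual standard deviation.
#'
#' @param beta Numeric vector of length 6: `(b0, b1, b2, b3, b4, b5)`.
#' @param delta Residual standard deviation (positive).
#' @return An object of class `outcome_params`.
#' @export
outcome_params <- function(beta, delta) {
  beta <- as.numeric(beta)
  if (length(beta) != 6L) {
    abort("`beta` must have length 6: (b0, b1, b2, b3, b4, b5).")
  }
  if (!is.finite(delta) || delta <= 0) {
    abort("`delta` (residual SD) must be a positive finite number.")
  }
  structure(list(beta = beta, delta = as.numeric(delta)),
            class = "outcome_params")
}

#' Full model parameters
#'
#' Bundles the outcome regression and the zero-inflated Beta mediator model.
#' The canonical parameter ordering used for gradients, the observed
#' information matrix and delta-method computations is
#' `(b0, b1, b2, b3, b4, b5, delta, alpha0, alpha1, phi, gamma0, gamma1)`.
#'
#' @param outcome An [outcome_params()] object.
#' @param mediator A [zib_params()] object.
#' @return An object of class `model_params`.
#' @export
model_params <- function(outcome, mediator) {
  stopifnot(inherits(outcome, "outcome_params"),
            inherits(mediator, "zib_params"))
  structure(list(outcome = outcome, mediator = mediator),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat("  outcome beta:", format(x$outcome$beta, digits = 4), "\n")
  cat("  delta:", format(x$outcome$delta, digits = 4), "\n")
  cat("  mediator: alpha = (", x$mediator$alpha0, ",", x$mediator$alpha1,
      "), gamma = (", x$mediator$gamma0, ",", x$mediator$gamma1,
      "), phi =", x$mediator$phi, "\n")
  invisible(x)
}

# canonical names of the full parameter vector
param_names <- function() {
  c("b0", "b1", "b2", "b3", "b4", "b5", "delta",
    "alpha0", "alpha1", "phi", "gamma0", "gamma1")
}

#' Flatten model parameters to the canonical vector
#'
#' @param params A [model_params()] object.
#' @return Named numeric vector of length 12 in the canonical ordering.
#' @export
params_to_vector <- function(params) {
  stopifnot(inherits(params, "model_params"))
  setNames(
    c(params$outcome$beta, params$outcome$delta,
      params$mediator$alpha0, params$mediator$alpha1, params$mediator$phi,
      params$mediator$gamma0, params$mediator$gamma1),
    param_names()
  )
}

#' Rebuild model parameters from the canonical vector
#'
#' @param theta Numeric vector of length 12 in the canonical ordering.
#' @return A [model_params()] object.
#' @export
vector_to_params <- function(theta) {
  stopifnot(length(theta) == 12L)
  model_params(
    outcome = outcome_params(beta = theta[1:6], delta = theta[7]),
    mediator = zib_params(alpha0 = theta[8], alpha1 = theta[9],
                          gamma0 = theta[11], gamma1 = theta[12],
                          phi = theta[10])
  )
}

# Free-parameter mask for a given interaction / zero-model configuration.
# interactions: "both", "indicator" (drop b5), "abundance" (drop b2?? no --
# keep naming by which interaction is retained), "none".
free_mask <- function(interactions = c("both", "indicator", "abundance",
                                       "none"),
                      has_zeros = TRUE) {
  interactions <- match.arg(interactions)
  free <- rep(TRUE, 12L)
  names(free) <- param_names()
  if (interactions %in% c("indicator", "none")) free["b5"] <- FALSE
  if (interactions %in% c("abundance", "none")) free["b4"] <- FALSE
  if (!has_zeros) {
    # point mass not identifiable: drop the zero link and the indicator terms
    free[c("b2", "b4", "gamma0", "gamma1")] <- FALSE
  }
  free
}
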