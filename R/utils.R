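#' Inverse logit
#'
#' `expit(z) = 1 / (1 + exp(-z))`, the inverse of the logit link used by both
#' the abundance (mean) and presence (zero-probability) submodels.
#'
#' @param z Numeric vector.
#' @return Numeric vector in (0, 1).
#' @export
expit <- function(z) stats::plogis(z)

# log(sum(exp(x))) with the usual max-factoring guard; accepts -Inf entries.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# pairwise log(exp(a) + exp(b)), vectorised
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
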