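#' Round half away from zero
#'
#' Display rounding used throughout the condition tables: exact halves round
#' up (`963.75` -> `963.8`), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' roundHalfUp(963.75, 1)  # 963.8
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Lower-truncated normal sampler (inverse CDF); lengths are >= lower.
rnormTruncLower <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  pLow <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, pLow, 1)
  stats::qnorm(u, mean, sd)
}

## Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Name of the pseudo-reference carrying exogenous (non-aligning) templates.
UNMAPPED <- "unmapped"
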