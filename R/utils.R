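#' Round half away from zero
#'
#' Rounds with ties going upward (0.125 -> 0.13 at two digits), the
#' convention used for all printed percentages in cohort summaries. Base
#' [round()] uses round-half-even, which disagrees on exact ties.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# percentage of part in whole, half-up at 2 decimals
pct2 <- function(part, whole) {
  if (whole <= 0) stop("denominator must be positive")
  roundHalfUp(100 * part / whole, 2)
}

# inverse-CDF sampler for a normal truncated to (lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# random nucleotide sequence of length L
randomGenome <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
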