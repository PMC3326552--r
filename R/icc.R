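#' One-way random-effects intraclass correlation between two effect vectors
#'
#' Treats each locus as a random group with two ratings (the effect estimate
#' in each of the two carrier groups) and computes the one-way
#' random-effects ICC from the ANOVA decomposition,
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` with `k = 2` ratings per locus.
#' Used to quantify how similar per-allele hazard-ratio profiles across a
#' panel of loci are between two strata (e.g. BRCA1 vs BRCA2 carriers, or
#' ER-positive vs ER-negative disease).
#'
#' @param x,y Equal-length numeric vectors of per-locus effect estimates
#'   (at least 3 loci).
#' @return The intraclass correlation (can be negative for anticorrelated
#'   profiles).
#' @export
icc_oneway <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 loci")
  if (any(!is.finite(c(x, y)))) stop("effects must be finite")
  k <- 2
  m <- cbind(x, y)
  rmean <- rowMeans(m)
  msb <- k * sum((rmean - mean(m))^2) / (n - 1)
  msw <- sum((m - rmean)^2) / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}
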