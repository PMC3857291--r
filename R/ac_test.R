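# Audic-Claverie exact test for a count observed in two libraries.
#
# For a tag counted x times among N1 clean tags in one library, the
# conditional distribution of the count y among N2 tags in a second
# library (flat prior on the unknown rate) is
#
#   p(y | x) = (N2/N1)^y * (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)),
#
# a negative-binomial in y with size x+1 and success probability
# N1/(N1+N2). The one-sided evidence for enrichment in library 2 is the
# upper tail P(Y >= y | x) of this distribution; the evidence for
# depletion is, symmetrically, the upper tail P(X >= x | y) of the same
# distribution with the roles of the libraries exchanged. The two-sided
# p-value doubles the smaller of the two and caps at 1. Computing each
# direction's tail under its own orientation makes the p-value exactly
# invariant under swapping (x, N1) <-> (y, N2), which a doubled
# lower/upper tail taken from a single orientation is not.
#
# Everything is evaluated in log space with log-gamma: library sizes in
# the millions make direct factorials overflow immediately.

ac_log_pmf <- function(k, x, r) {
  k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
}

# P(Y >= y | x) with r = N2/N1; scalar, full relative precision on both
# branches: the 1 - lower complement is only used when the result is >= 0.5,
# small upper tails are summed directly until the terms are negligible.
ac_upper_tail <- function(x, y, r) {
  if (y == 0) return(1)
  lower <- sum(exp(ac_log_pmf(0:(y - 1), x, r)))
  if (lower < 0.5) return(1 - lower)
  acc <- 0
  k <- y
  mode <- (x + 1) * r
  repeat {
    ks <- k:(k + 255L)
    t <- exp(ac_log_pmf(ks, x, r))
    acc <- acc + sum(t)
    if ((t[256L] < acc * 1e-17 && ks[256L] > mode) || t[256L] == 0) break
    k <- k + 256L
  }
  acc
}

ac_pvalue_scalar <- function(x, N1, y, N2) {
  up <- ac_upper_tail(x, y, N2 / N1)   # treatment enriched
  down <- ac_upper_tail(y, x, N1 / N2) # treatment depleted
  min(1, 2 * min(up, down))
}

#' Audic-Claverie two-sided p-value
#'
#' Exact conditional test comparing a count between two libraries of known
#' sizes. Vectorized over `x` and `y` (and `N1`/`N2`); repeated
#' (x, y, N1, N2) tuples are computed once.
#'
#' @param x,y non-negative integer tag counts in the two libraries.
#' @param N1,N2 positive library sizes (total clean tags).
#' @return two-sided p-values in \[0, 1\], exactly symmetric under
#'   exchanging `(x, N1)` with `(y, N2)`.
#' @export
ac_pvalue <- function(x, N1, y, N2) {
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)))
    stopf("counts 'x' and 'y' must be non-negative integers")
  if (any(N1 < 1) || any(N2 < 1)) stopf("library sizes must be >= 1")

  key <- paste(x, y, N1, N2)
  first <- which(!duplicated(key))
  pv <- vapply(first, function(i) ac_pvalue_scalar(x[i], N1[i], y[i], N2[i]),
               numeric(1))
  pv[match(key, key[first])]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: the error ratio Q = V/R
#' (expected fraction of false positives V among R rejections) is
#' controlled at level q when rejecting all hypotheses with adjusted
#' value <= q.
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return adjusted values, elementwise >= the input, in \[0, 1\].
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0L) stopf("'p_values' must be non-empty")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
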