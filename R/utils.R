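# Small internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
TAG_LENGTH <- 21L
TAG_ANCHOR <- "CATG"
TAG_EXTENSION <- 17L # nt retained downstream of the anchor

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with ties going up (half-up),
#' the convention used when reporting percentages in tables. Base `round()`
#' uses banker's rounding, which maps e.g. 14.45 to 14.4.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# log(sum(exp(lx))) without overflow; lx may contain -Inf
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# Derive a per-stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 10007) %% (.Machine$integer.max - 1L)) + 1L
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)

assert_scalar_number <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
}
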