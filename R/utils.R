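#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages and fold
#' changes use conventional half-up rounding instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (a == b to machine precision)
logdiff <- function(a, b) {
  if (b > a) stop("logdiff requires a >= b")
  if (b == -Inf) return(a)
  d <- 1 - exp(b - a)
  if (d <= 0) return(-Inf)
  a + log(d)
}

# derive a reproducible 32-bit sub-seed from a base seed and a stream label
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483647L
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single positive integer", name))
  }
}
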