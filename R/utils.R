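## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## match.arg that reports the offending value
.matchArg <- function(x, choices, what) {
  if (length(x) != 1L || !x %in% choices) {
    .stopf("%s must be one of: %s (got '%s')", what,
           paste(choices, collapse = ", "), paste(x, collapse = ","))
  }
  x
}

.isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

.isPositiveScalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}

## rational approximation p/q of a rate ratio, for polyphase resampling
.rationalRatio <- function(ratio, max_denom = 10000L) {
  p <- round(ratio * max_denom)
  q <- max_denom
  g <- .gcd(p, q)
  c(p = p / g, q = q / g)
}

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

## deterministic child seed below 2^31, derived from a base seed and a tag
.childSeed <- function(seed, tag) {
  (as.integer(seed) * 1009L + as.integer(tag) * 101L) %% 2147483647L
}
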