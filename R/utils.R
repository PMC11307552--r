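# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g", name, lower)
  if (x > upper)
    stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

assert_prob <- function(x, name) assert_scalar_num(x, name, 0, 1)

# Seeds are combined additively and kept inside the 32-bit integer range.
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483646 + 1)
}

with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Runs of TRUE in a logical vector -> matrix of (start, end) indices.
true_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
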