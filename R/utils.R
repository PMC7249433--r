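# Shared error signalling. Every error raised by the package carries the
# "superrec_error" class plus a specific subclass so callers (and tests) can
# distinguish, e.g., an order inconsistency from a tree inconsistency.
stop_superrec <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "superrec_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Popcount for small non-negative integers (masks over <= 25 positions).
bit_count <- function(x) {
  n <- 0L
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

# Positions (1-based, increasing) of the set bits of a single mask.
mask_bits <- function(x) {
  out <- integer(0)
  p <- 1L
  while (x > 0L) {
    if (x %% 2L == 1L) out <- c(out, p)
    x <- x %/% 2L
    p <- p + 1L
  }
  out
}

mask_from_bits <- function(pos) {
  if (length(pos) == 0L) return(0L)
  as.integer(sum(2L^(pos - 1L)))
}
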