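`%||%` <- function(a, b) if (is.null(a)) b else a

## trailing rolling mean over up to `w` values ending at each position;
## with w = 1 this is the identity.
rolling_mean_trailing <- function(x, w) {
  n <- length(x)
  if (n == 0L || w <= 1L) return(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(0L, i - w)
  (cs[i + 1L] - cs[lo + 1L]) / (i - lo)
}

## consecutive-TRUE run length starting at each position (0 where FALSE)
consecutive_run_length <- function(b) {
  n <- length(b)
  out <- integer(n)
  run <- 0L
  for (i in rev(seq_len(n))) {
    run <- if (isTRUE(b[i])) run + 1L else 0L
    out[i] <- run
  }
  out
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x, min = -Inf) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > min
}
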