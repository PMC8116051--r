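# Independent brute-force oracle for the hysteresis trigger/release rules.
# Deliberately written as a per-timepoint state machine with counters --
# a different formulation from the run-length scanner in the package -- so
# that agreement between the two is informative.
oracle_hysteresis <- function(r, B, delta_high = 0.2, delta_low = 0.1,
                              nmin = 2L) {
  thr_hi <- B + delta_high
  thr_lo <- B + delta_low
  starts <- integer(0); ends <- integer(0)
  state <- "idle"; hi_run <- 0L; lo_run <- 0L; start <- NA_integer_
  for (t in seq_along(r)) {
    if (state == "idle") {
      hi_run <- if (r[t] >= thr_hi) hi_run + 1L else 0L
      if (hi_run == nmin) {
        start <- t - nmin + 1L
        state <- "active"
        lo_run <- 0L
      }
    } else {
      lo_run <- if (r[t] < thr_lo) lo_run + 1L else 0L
      if (lo_run == nmin) {
        starts <- c(starts, start)
        ends <- c(ends, t - nmin + 1L)
        state <- "idle"
        hi_run <- 0L
      }
    }
  }
  if (state == "active") {
    starts <- c(starts, start)
    ends <- c(ends, NA_integer_)
  }
  data.frame(start = starts, end = ends)
}

# random ratio traces: random walks around B with occasional excursions
random_trace <- function(n, B = 0.675) {
  drift <- cumsum(stats::rnorm(n, 0, 0.05))
  bumps <- numeric(n)
  n_bump <- stats::rpois(1, 1.5)
  for (b in seq_len(n_bump)) {
    s <- sample.int(n, 1L)
    len <- sample.int(8L, 1L)
    idx <- s:min(n, s + len - 1L)
    bumps[idx] <- bumps[idx] + stats::runif(1, 0.1, 0.4)
  }
  pmax(B + drift - mean(drift) + bumps + stats::rnorm(n, 0, 0.02), 0.01)
}
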