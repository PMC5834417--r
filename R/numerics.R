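# Internal numerical kernels shared by the simulator and the fitters.
# All time grids are uniform with step `dt` minutes starting at t = 0.

# Convolution y(t) = (x %conv% exp(-k t))(t) on a uniform grid, treating x
# as piecewise linear between samples. Exact per-step update
#   y[n+1] = E y[n] + c0 x[n] + c1 x[n+1],  E = exp(-k dt)
# evaluated with a C-level recursive filter, so the cost is O(n).
# expm1 keeps the step coefficients accurate down to k*dt ~ 1e-8.
exp_conv <- function(x, k, dt) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  if (k < 0) stop("rate constant must be non-negative")
  if (k == 0) {
    # degenerate kernel exp(0) = 1: plain running integral
    return(c(0, cumsum((x[-n] + x[-1]) / 2 * dt)))
  }
  E <- exp(-k * dt)
  one_m_e <- -expm1(-k * dt)
  a <- one_m_e / k
  c0 <- (one_m_e - k * dt * E) / (k * k * dt)
  c1 <- a - c0
  inc <- c0 * x[-n] + c1 * x[-1]
  c(0, as.numeric(stats::filter(inc, E, method = "recursive")))
}

# Cumulative trapezoidal integral on a uniform grid, anchored at 0.
cum_int <- function(x, dt) {
  n <- length(x)
  c(0, cumsum((x[-n] + x[-1]) / 2 * dt))
}

# Average of a finely sampled curve over each frame of `schedule`.
# Uses linear interpolation of the cumulative integral at the frame
# boundaries, i.e. the curve is treated as piecewise linear.
frame_average <- function(fine_t, fine_x, schedule) {
  if (scan_end(schedule) > fine_t[length(fine_t)] + 1e-9) {
    stop(sprintf(
      "schedule extends to %.4g min but the fine grid ends at %.4g min: inconsistent simulation horizon",
      scan_end(schedule), fine_t[length(fine_t)]
    ))
  }
  dt <- fine_t[2] - fine_t[1]
  cint <- cum_int(fine_x, dt)
  at <- function(t) stats::approx(fine_t, cint, xout = t, rule = 2)$y
  (at(schedule$ends) - at(schedule$starts)) / frame_durations(schedule)
}

# Fine time grid covering a schedule.
fine_grid <- function(schedule, dt = 0.01) {
  seq(0, scan_end(schedule) + dt, by = dt)
}

# Duration-weighted overlap of each frame with the window [a, b).
window_overlap <- function(schedule, a, b) {
  pmax(0, pmin(schedule$ends, b) - pmax(schedule$starts, a))
}
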