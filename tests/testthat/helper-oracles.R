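# Independent oracle implementations used to check the package's
# numerical paths. They deliberately take different routes: FFT-based
# discrete convolution instead of the recursive exact-step filter, plain
# sample means instead of interpolated cumulative integrals, and a
# direct nonlinear least-squares fit instead of the basis-function
# linearisation.

# (x conv exp(-k t)) on a uniform grid via FFT convolution
oracle_exp_conv <- function(x, k, dt) {
  kern <- exp(-k * (seq_along(x) - 1) * dt)
  full <- stats::convolve(x, rev(kern), type = "open") * dt
  full[seq_along(x)]
}

# reference-tissue forward model via the FFT route
oracle_srtm_curve <- function(fine_t, fine_cr, R1, k2, bpnd) {
  theta <- k2 / (1 + bpnd)
  dt <- fine_t[2] - fine_t[1]
  R1 * fine_cr + (k2 - R1 * theta) * oracle_exp_conv(fine_cr, theta, dt)
}

# frame time-averages by per-frame trapezoid over the fine samples,
# with the frame edges interpolated explicitly
oracle_frame_average <- function(fine_t, fine_x, schedule) {
  vapply(seq_len(n_frames(schedule)), function(i) {
    a <- schedule$starts[i]
    b <- schedule$ends[i]
    inside <- fine_t > a & fine_t < b
    xs <- c(a, fine_t[inside], b)
    ys <- stats::approx(fine_t, fine_x, xout = xs, rule = 2)$y
    pracma::trapz(xs, ys) / (b - a)
  }, numeric(1))
}

# direct NLLS fit of the reference-tissue model (independent of the
# basis-function solver); requires the reference's fine grid
oracle_srtm_nlls <- function(target, reference,
                             start = c(R1 = 1, k2 = 0.1, bpnd = 1)) {
  ft <- reference$fine_t
  fx <- reference$fine_x
  sched <- target$schedule
  model <- function(R1, k2, bpnd) {
    oracle_frame_average(ft, oracle_srtm_curve(ft, fx, R1, k2, bpnd), sched)
  }
  fit <- minpack.lm::nlsLM(
    y ~ model(R1, k2, bpnd),
    data = list(y = target$values),
    start = as.list(start),
    lower = c(R1 = 0.05, k2 = 1e-4, bpnd = -0.99),
    upper = c(R1 = 5, k2 = 2, bpnd = 50),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  as.list(stats::coef(fit))
}
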