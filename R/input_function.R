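#' Analytic arterial-like input functions for the simulator
#'
#' The simulator needs a plasma input internally to drive the
#' one-tissue reference region and produce bolus-like reference TACs;
#' the quantification methods themselves never see it (they are
#' reference-tissue methods). Two forms are provided:
#'
#' * `"gamma_biexp"` — a gamma-variate first-pass peak plus a
#'   biexponential recirculation tail that rises smoothly from zero.
#'   This gives a sharp bolus peaking at `peak_time` minutes followed
#'   by a slowly clearing tail, the shape typical of a bolus injection.
#' * `"constant_infusion"` — a saturating ramp
#'   `amplitude * (1 - exp(-t / ramp))`, driving the system towards
#'   true secular equilibrium, where the ratio of target to reference
#'   concentration tends to `1 + BP_ND`.
#'
#' Both forms are zero at `t = 0` and non-negative for all `t >= 0`.
#'
#' @param kind `"gamma_biexp"` (default) or `"constant_infusion"`.
#' @param peak_time Time of the first-pass peak, minutes (gamma form).
#' @param peak_amplitude Peak plasma concentration, kBq/mL (gamma form)
#'   or plateau amplitude (infusion form).
#' @param alpha Gamma-variate shape (dimensionless, > 0).
#' @param tail_fracs Amplitudes of the two recirculation exponentials as
#'   fractions of `peak_amplitude`.
#' @param tail_rates Washout rate constants of the two tail
#'   exponentials, 1/min.
#' @param ramp Time constant of the infusion ramp, minutes.
#' @param fun For `kind = "custom"`: a vectorised function of time
#'   (minutes) returning non-negative concentrations, 0 at t = 0.
#'
#' @return An object of class `input_function`; call it on a vector of
#'   times with [if_values()].
#' @examples
#' ifn <- input_function()
#' if_values(ifn, c(0, 0.8, 10))
#' @export
input_function <- function(kind = c("gamma_biexp", "constant_infusion",
                                    "custom"),
                           peak_time = 0.8, peak_amplitude = 40,
                           alpha = 3,
                           tail_fracs = c(0.15, 0.08),
                           tail_rates = c(0.2, 0.015),
                           ramp = 2, fun = NULL) {
  kind <- match.arg(kind)
  stopifnot(peak_time > 0, peak_amplitude >= 0, alpha > 0, ramp > 0)
  if (kind == "custom" && !is.function(fun)) {
    stop("kind = 'custom' needs a function of time in `fun`")
  }
  obj <- list(
    kind = kind, peak_time = peak_time, peak_amplitude = peak_amplitude,
    alpha = alpha, tail_fracs = tail_fracs, tail_rates = tail_rates,
    ramp = ramp, fun = fun
  )
  structure(obj, class = "input_function")
}

#' Evaluate an input function
#'
#' @param ifn An [input_function()].
#' @param t Numeric vector of times, minutes p.i. (t >= 0).
#' @return Plasma concentration at `t`, kBq/mL; 0 at t = 0.
#' @export
if_values <- function(ifn, t) {
  stopifnot(inherits(ifn, "input_function"), all(t >= 0))
  if (ifn$kind == "custom") return(ifn$fun(t))
  if (ifn$kind == "constant_infusion") {
    return(ifn$peak_amplitude * (1 - exp(-t / ifn$ramp)))
  }
  # gamma variate normalised to peak 1 at peak_time
  g <- (t / ifn$peak_time)^ifn$alpha * exp(ifn$alpha * (1 - t / ifn$peak_time))
  tail <- (1 - exp(-t / ifn$peak_time)) *
    (ifn$tail_fracs[1] * exp(-ifn$tail_rates[1] * t) +
       ifn$tail_fracs[2] * exp(-ifn$tail_rates[2] * t))
  ifn$peak_amplitude * (g + tail)
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function> %s, amplitude %.3g kBq/mL\n",
              x$kind, x$peak_amplitude))
  invisible(x)
}
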