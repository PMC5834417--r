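#' Fit the reference Logan graphical analysis
#'
#' Linearises the integrated TACs: for frame midpoints `t > t_star`,
#' `int_0^t C_T / C_T(t)` is regressed on `int_0^t C_R / C_T(t)` by
#' ordinary least squares; the slope equals `1 + BP_ND` once the system
#' has passed its equilibrium time `t_star`, and `int` is the regression
#' intercept (minutes). Cumulative integrals are trapezoidal over the
#' frame midpoints with an implicit (0, 0) anchor (activity is zero at
#' injection).
#'
#' @param target,reference [tac()] objects on a shared schedule.
#' @param t_star Equilibrium time, minutes p.i.; only frames with
#'   midpoint beyond it enter the regression (at least 3 required).
#' @return An object of class `logan_fit`: `bpnd`, `int` (min),
#'   `t_star`, `n_used`, `r2` of the fitted line.
#' @export
fit_reference_logan <- function(target, reference, t_star) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"),
            is.numeric(t_star), length(t_star) == 1)
  if (!same_schedule(target$schedule, reference$schedule)) {
    stop("target and reference must share one frame schedule")
  }
  mid <- frame_midpoints(target$schedule)
  use <- which(mid > t_star + 1e-9)
  if (length(use) < 3) {
    stop(sprintf(
      "only %d frame midpoint(s) beyond t* = %g min; at least 3 needed",
      length(use), t_star
    ))
  }
  ct <- target$values
  cr <- reference$values
  int_t <- cum_int_mid(mid, ct)
  int_r <- cum_int_mid(mid, cr)
  tiny <- 1e-6 * max(abs(ct))
  bad <- use[abs(ct[use]) < tiny]
  if (length(bad)) {
    stop("target activity near zero in frame(s) ",
         paste(bad, collapse = ", "), "; Logan transform undefined")
  }
  x <- int_r[use] / ct[use]
  y <- int_t[use] / ct[use]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(
    list(bpnd = unname(slope) - 1, int = unname(fit$coefficients[1]),
         t_star = t_star, n_used = length(use),
         r2 = max(0, min(1, r2)), region = target$region),
    class = "logan_fit"
  )
}

# trapezoid cumulative integral of frame values at their midpoints,
# anchored at (0, 0)
cum_int_mid <- function(mid, v) {
  as.numeric(pracma::cumtrapz(c(0, mid), c(0, v)))[-1]
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf(
    "<logan_fit> %s: BP_ND = %.3f, int = %.3g min (t* = %g, %d frames, R2 = %.4f)\n",
    x$region, x$bpnd, x$int, x$t_star, x$n_used, x$r2
  ))
  invisible(x)
}
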