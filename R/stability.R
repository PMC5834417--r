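#' Time-stability sweeps of the quantification outcomes
#'
#' These operations mirror the classic acquisition-design questions for
#' reference-tissue PET: how short can the dynamic scan be before
#' BP_ND drifts ([bpnd_vs_duration()]); how late must the Logan
#' equilibrium time t* be ([logan_tstar_sweep()]); and which static
#' window gives a stable SUVR ([suvr_window_sweep()]). Each returns a
#' `stability_curve`: per region and sweep value, the mean outcome
#' across subjects and its between-subject SD.
#'
#' @param cohort A [generate_cohort()] result (or a named list of
#'   [regional_tac_set()] per subject under `sets[[tracer]]`).
#' @param tracer Tracer name; required when the cohort holds several.
#' @param durations Scan durations to truncate to, minutes, increasing.
#' @param method `"srtm"` (default) or `"logan"` for the duration sweep.
#' @param t_star Equilibrium time used when `method = "logan"`.
#' @param min_frames Durations keeping fewer frames are skipped with a
#'   warning (default 5).
#' @param ... SRTM basis settings (`theta_grid`, `dt`).
#' @return A tibble of class `stability_curve` with columns `tracer`,
#'   `region`, `sweep_value`, `mean`, `sd`, `n`; attribute `sweep` names
#'   the swept variable.
#' @export
bpnd_vs_duration <- function(cohort, durations, tracer = NULL,
                             method = c("srtm", "logan"), t_star = NULL,
                             min_frames = 5, ...) {
  method <- match.arg(method)
  sets <- cohort_tracer_sets(cohort, tracer)
  durations <- sort(durations)
  rows <- list()
  for (dur in durations) {
    sched <- tryCatch(truncate_schedule(sets[[1]]$tacs[[1]]$schedule, dur),
                      error = function(e) NULL)
    if (is.null(sched) || n_frames(sched) < min_frames) {
      warning(sprintf("duration %g min keeps fewer than %d frames; skipped",
                      dur, min_frames))
      next
    }
    for (s in sets) {
      ref <- truncate_tac(s$tacs[[s$reference]], dur)
      # one basis per subject x duration, shared across that subject's regions
      basis <- if (method == "srtm") srtm_basis(ref, ...)
      for (nm in setdiff(names(s$tacs), s$reference)) {
        tgt <- truncate_tac(s$tacs[[nm]], dur)
        bp <- if (method == "srtm") {
          srtm_fit_core(basis, tgt$values)$bpnd
        } else {
          fit_reference_logan(tgt, ref, t_star)$bpnd
        }
        rows[[length(rows) + 1L]] <- data.frame(
          tracer = s$tracer, region = nm, sweep_value = dur,
          subject = s$subject, value = bp
        )
      }
    }
  }
  aggregate_sweep(rows, "scan_duration")
}

#' @rdname bpnd_vs_duration
#' @param t_stars Equilibrium times to sweep, minutes, increasing.
#' @export
logan_tstar_sweep <- function(cohort, t_stars, tracer = NULL) {
  sets <- cohort_tracer_sets(cohort, tracer)
  rows <- list()
  for (ts in sort(t_stars)) {
    for (s in sets) {
      ref <- s$tacs[[s$reference]]
      for (nm in setdiff(names(s$tacs), s$reference)) {
        bp <- fit_reference_logan(s$tacs[[nm]], ref, ts)$bpnd
        rows[[length(rows) + 1L]] <- data.frame(
          tracer = s$tracer, region = nm, sweep_value = ts,
          subject = s$subject, value = bp
        )
      }
    }
  }
  aggregate_sweep(rows, "t_star")
}

#' @rdname bpnd_vs_duration
#' @param window_starts Static-window start times, minutes, increasing.
#' @param width Static-window width, minutes (default 20, the usual
#'   short static acquisition).
#' @export
suvr_window_sweep <- function(cohort, window_starts, width = 20,
                              tracer = NULL) {
  sets <- cohort_tracer_sets(cohort, tracer)
  rows <- list()
  for (ws in sort(window_starts)) {
    for (s in sets) {
      sv <- compute_suvr(s, c(ws, ws + width))
      for (i in seq_len(nrow(sv))) {
        rows[[length(rows) + 1L]] <- data.frame(
          tracer = s$tracer, region = sv$region[i], sweep_value = ws,
          subject = s$subject, value = sv$suvr[i]
        )
      }
    }
  }
  aggregate_sweep(rows, "window_start")
}

cohort_tracer_sets <- function(cohort, tracer = NULL) {
  if (inherits(cohort, "cohort_dataset")) cohort <- cohort$sets
  if (is.list(cohort) && all(vapply(cohort, inherits, logical(1),
                                    "regional_tac_set"))) {
    return(cohort)
  }
  if (is.null(tracer)) {
    if (length(cohort) != 1L) {
      stop("cohort holds tracers ", paste(names(cohort), collapse = ", "),
           "; pick one with `tracer = `")
    }
    tracer <- names(cohort)[1]
  }
  if (!tracer %in% names(cohort)) stop("no such tracer: ", tracer)
  cohort[[tracer]]
}

aggregate_sweep <- function(rows, sweep) {
  if (!length(rows)) stop("sweep produced no fittable values")
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ tracer + region + sweep_value, d,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  out <- tibble::tibble(
    tracer = agg$tracer, region = agg$region, sweep_value = agg$sweep_value,
    mean = agg$value[, "mean"],
    sd = ifelse(is.na(agg$value[, "sd"]), 0, agg$value[, "sd"]),
    n = as.integer(agg$value[, "n"])
  )
  out <- out[order(out$region, out$sweep_value), ]
  structure(out, sweep = sweep, subject_values = tibble::as_tibble(d),
            class = c("stability_curve", class(out)))
}

#' Band-entry (stabilisation) time of a stability curve
#'
#' The sweep value from which a region's mean outcome enters, and stays
#' within, a relative band around its final (full-information) value.
#' Mirrors the by-eye "becomes stable after ..." reading of
#' stability plots, made operational.
#'
#' @param curve A `stability_curve`.
#' @param band Half-width of the relative band (default 0.05, i.e.
#'   +/-5% of the final value).
#' @return Tibble `tracer`, `region`, `onset` (NA if the curve never
#'   settles).
#' @export
stability_onset <- function(curve, band = 0.05) {
  stopifnot(inherits(curve, "stability_curve"), band > 0)
  keys <- unique(curve[, c("tracer", "region")])
  onset <- numeric(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    cc <- curve[curve$tracer == keys$tracer[i] &
                  curve$region == keys$region[i], ]
    cc <- cc[order(cc$sweep_value), ]
    final <- cc$mean[nrow(cc)]
    ok <- abs(cc$mean - final) <= band * abs(final)
    inside <- rev(cumprod(rev(ok))) > 0  # within band from here onwards
    onset[i] <- if (any(inside)) cc$sweep_value[which(inside)[1]] else NA_real_
  }
  tibble::tibble(tracer = keys$tracer, region = keys$region, onset = onset)
}

#' Agreement regression between static and dynamic outcomes
#'
#' Ordinary least squares of the static measure (SUVR) on the dynamic
#' one (BP_ND), pooling all region-subject pairs jointly, as done when
#' static acquisition protocols are validated against full kinetic
#' modelling.
#'
#' @param static Tibble with columns `subject`, `region`, `value`
#'   (SUVR), or a named numeric vector matched by position.
#' @param dynamic Same layout for BP_ND.
#' @return An object of class `agreement_result`: `slope`, `intercept`,
#'   `r2`, `n`, `pair` label.
#' @export
regress_static_vs_dynamic <- function(static, dynamic) {
  if (is.data.frame(static) && is.data.frame(dynamic)) {
    m <- merge(as.data.frame(static), as.data.frame(dynamic),
               by = c("subject", "region"), suffixes = c("_static", "_dynamic"))
    y <- m$value_static
    x <- m$value_dynamic
  } else {
    y <- as.numeric(static)
    x <- as.numeric(dynamic)
    if (length(x) != length(y)) stop("measure vectors differ in length")
  }
  if (length(x) < 3) stop("need at least 3 matched (region, subject) pairs")
  if (stats::var(x) == 0) stop("zero variance in the dynamic measure")
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = suppressWarnings(summary(fit)$r.squared), n = length(x),
         pair = "suvr_vs_bpnd"),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> static = %.3f x dynamic %+.3f, R2 = %.3f (n = %d)\n",
    x$slope, x$intercept, x$r2, x$n
  ))
  invisible(x)
}
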