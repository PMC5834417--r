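#' Standardized uptake value ratios over a static window
#'
#' `SUVR = SUV_target / SUV_reference` where each SUV is the
#' duration-weighted mean activity over the acquisition window; frames
#' partially inside the window contribute their overlapping duration.
#' Because injected dose and body weight cancel in the ratio, activity
#' concentrations are used directly.
#'
#' @param tacs A [regional_tac_set()].
#' @param window `c(start, end)` in minutes p.i.; must overlap the scan.
#' @return An object of class `suvr_result`: tibble of `region`, `suvr`
#'   plus attributes `window` and `reference`. The reference region's
#'   SUVR is identically 1.
#' @export
compute_suvr <- function(tacs, window) {
  stopifnot(inherits(tacs, "regional_tac_set"),
            length(window) == 2, window[2] > window[1])
  sched <- tacs$tacs[[1]]$schedule
  w <- window_overlap(sched, window[1], window[2])
  if (sum(w) <= 0) {
    stop(sprintf("window [%g, %g] min does not overlap the scan (0-%g min)",
                 window[1], window[2], scan_end(sched)))
  }
  wmean <- function(v) sum(w * v) / sum(w)
  ref <- wmean(tacs$tacs[[tacs$reference]]$values)
  if (ref <= 0) stop("reference activity in the window is not positive")
  out <- tibble::tibble(
    region = names(tacs$tacs),
    suvr = unname(vapply(tacs$tacs, function(tc) wmean(tc$values),
                         numeric(1))) / ref
  )
  structure(out, window = window, reference = tacs$reference,
            subject = tacs$subject, tracer = tacs$tracer,
            class = c("suvr_result", class(out)))
}

#' @export
print.suvr_result <- function(x, ...) {
  cat(sprintf("<suvr_result> window %g-%g min, reference '%s'\n",
              attr(x, "window")[1], attr(x, "window")[2],
              attr(x, "reference")))
  print(tibble::as_tibble(x))
  invisible(x)
}
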