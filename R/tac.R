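#' Time-activity curves and regional TAC sets
#'
#' A `tac` holds one region's frame-binned activity concentration
#' (kBq/mL) on a [frame_schedule()]. Simulated TACs additionally carry
#' the internal fine-grid curve they were frame-averaged from (elements
#' `fine_t`, `fine_x`), which the fitters use to rebuild convolution
#' bases exactly; measured TACs have `fine_t = NULL` and the fitters
#' fall back to interpolation.
#'
#' @param schedule A [frame_schedule()].
#' @param values Numeric activity per frame, kBq/mL; finite, one per frame.
#' @param region Region label.
#' @param fine_t,fine_x Optional fine time grid (minutes, uniform, from 0)
#'   and the curve sampled on it.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, region = "region",
                fine_t = NULL, fine_x = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != n_frames(schedule)) {
    stop(sprintf("expected %d frame values, got %d",
                 n_frames(schedule), length(values)))
  }
  if (!all(is.finite(values))) stop("TAC values must be finite")
  if (xor(is.null(fine_t), is.null(fine_x))) {
    stop("fine_t and fine_x must be supplied together")
  }
  structure(
    list(schedule = schedule, values = values, region = as.character(region),
         fine_t = fine_t, fine_x = fine_x),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> region '%s', %d frames, peak %.3g kBq/mL%s\n",
              x$region, n_frames(x$schedule), max(x$values),
              if (is.null(x$fine_t)) "" else " (+fine grid)"))
  invisible(x)
}

#' Convert a TAC to a tidy tibble
#' @param x A [tac()].
#' @param ... Unused.
#' @return Tibble with columns `region`, `frame_start`, `frame_end`,
#'   `midpoint`, `activity`.
#' @method as_tibble tac
#' @export
as_tibble.tac <- function(x, ...) {
  tibble::tibble(
    region = x$region,
    frame_start = x$schedule$starts,
    frame_end = x$schedule$ends,
    midpoint = frame_midpoints(x$schedule),
    activity = x$values
  )
}

# Drop frames outside a truncated scan; keeps any fine grid (it always
# spans at least the original schedule, hence also the shorter one).
truncate_tac <- function(x, duration) {
  sched <- truncate_schedule(x$schedule, duration)
  tac(sched, x$values[seq_len(n_frames(sched))], x$region,
      fine_t = x$fine_t, fine_x = x$fine_x)
}

#' Bundle regional TACs for one subject and tracer
#'
#' @param tacs Named list of [tac()] objects (names = region labels), or an
#'   unnamed list (regions taken from each TAC).
#' @param reference Name of the reference region (must be present);
#'   conventionally cerebellum grey matter.
#' @param subject,tracer Identifiers carried through tidy outputs.
#' @return An object of class `regional_tac_set`.
#' @export
regional_tac_set <- function(tacs, reference, subject = "s01",
                             tracer = "tracer") {
  stopifnot(is.list(tacs), length(tacs) > 0)
  if (is.null(names(tacs)) || any(names(tacs) == "")) {
    names(tacs) <- vapply(tacs, function(t) t$region, character(1))
  }
  for (nm in names(tacs)) {
    if (!inherits(tacs[[nm]], "tac")) stop("all elements must be tac objects")
    tacs[[nm]]$region <- nm
  }
  if (!reference %in% names(tacs)) {
    stop(sprintf("reference region '%s' not among TACs (%s)",
                 reference, paste(names(tacs), collapse = ", ")))
  }
  sched <- tacs[[1]]$schedule
  ok <- vapply(tacs, function(t) same_schedule(t$schedule, sched), logical(1))
  if (!all(ok)) stop("all TACs in a set must share one frame schedule")
  structure(
    list(tacs = tacs, reference = reference,
         subject = as.character(subject), tracer = as.character(tracer)),
    class = "regional_tac_set"
  )
}

#' @export
print.regional_tac_set <- function(x, ...) {
  cat(sprintf(
    "<regional_tac_set> subject %s, tracer %s: %d regions (ref '%s'), %d frames\n",
    x$subject, x$tracer, length(x$tacs), x$reference,
    n_frames(x$tacs[[1]]$schedule)
  ))
  invisible(x)
}

#' @method as_tibble regional_tac_set
#' @export
as_tibble.regional_tac_set <- function(x, ...) {
  out <- do.call(rbind, lapply(x$tacs, as_tibble.tac))
  tibble::tibble(subject = x$subject, tracer = x$tracer, out)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
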