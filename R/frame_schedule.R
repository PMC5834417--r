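#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule holds the start and end times (minutes post-injection)
#' of every frame of a dynamic acquisition. Frames must be non-overlapping,
#' in increasing order, and are treated as half-open intervals `[start, end)`.
#'
#' @param starts Numeric vector of frame start times, minutes p.i.
#' @param ends Numeric vector of frame end times, minutes p.i.
#'
#' @return An object of class `frame_schedule`: a list with elements
#'   `starts` and `ends`.
#' @examples
#' fs <- frame_schedule(c(0, 1, 2), c(1, 2, 5))
#' frame_midpoints(fs)
#' @export
frame_schedule <- function(starts, ends) {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) != length(ends) || length(starts) == 0L) {
    stop("starts and ends must be non-empty vectors of equal length")
  }
  if (anyNA(starts) || anyNA(ends)) stop("frame times must be finite")
  if (starts[1] < 0) stop("first frame start must be >= 0")
  if (any(ends <= starts)) stop("every frame end must exceed its start")
  if (is.unsorted(starts, strictly = TRUE)) {
    stop("frame starts must be strictly increasing")
  }
  if (length(starts) > 1L && any(starts[-1] < ends[-length(ends)] - 1e-9)) {
    stop("frames must not overlap")
  }
  structure(list(starts = starts, ends = ends), class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "<frame_schedule> %d frames, %.3g-%.3g min\n",
    n_frames(x), x$starts[1], x$ends[n_frames(x)]
  ))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A [frame_schedule()].
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$starts)

#' Frame midpoint times
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of frame midpoints, minutes p.i.
#' @export
frame_midpoints <- function(schedule) (schedule$starts + schedule$ends) / 2

#' Frame durations
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of frame lengths in minutes.
#' @export
frame_durations <- function(schedule) schedule$ends - schedule$starts

#' End of the scan covered by a schedule
#' @param schedule A [frame_schedule()].
#' @return Last frame end, minutes p.i.
#' @export
scan_end <- function(schedule) schedule$ends[n_frames(schedule)]

#' Build a schedule from a run-length frame pattern
#'
#' @param n_per_block Integer vector, number of frames per block.
#' @param seconds_per_frame Frame length in seconds for each block.
#' @param start Start of the first frame, minutes p.i. (default 0).
#' @return A [frame_schedule()].
#' @export
frame_pattern <- function(n_per_block, seconds_per_frame, start = 0) {
  durs <- rep(seconds_per_frame / 60, times = n_per_block)
  ends <- start + cumsum(durs)
  frame_schedule(c(start, ends[-length(ends)]), ends)
}

#' Default dynamic schedules for the fast and slow tracer protocols
#'
#' `fs_av45()` returns the default 60-min fast-kinetics (amyloid,
#' AV45-like) acquisition: 6x10 s, 3x20 s, 3x30 s, 4x60 s, 1x150 s,
#' 10x300 s (27 frames). `fs_av1451()` extends the same early framing to
#' the 120-min slow-kinetics (tau, AV1451-like) protocol with 22x300 s
#' late frames (39 frames). Framing is a protocol choice, not a constant:
#' pass any [frame_schedule()] where one is accepted.
#'
#' @return A [frame_schedule()].
#' @export
fs_av45 <- function() {
  frame_pattern(c(6, 3, 3, 4, 1, 10), c(10, 20, 30, 60, 150, 300))
}

#' @rdname fs_av45
#' @export
fs_av1451 <- function() {
  frame_pattern(c(6, 3, 3, 4, 1, 22), c(10, 20, 30, 60, 150, 300))
}

#' Restrict a schedule to frames wholly inside a scan duration
#'
#' Frames straddling `duration` are dropped, not clipped.
#'
#' @param schedule A [frame_schedule()].
#' @param duration Scan duration in minutes.
#' @return A shorter [frame_schedule()] (frames with end <= duration).
#' @export
truncate_schedule <- function(schedule, duration) {
  keep <- schedule$ends <= duration + 1e-9
  if (!any(keep)) stop("no frame ends within the requested duration")
  frame_schedule(schedule$starts[keep], schedule$ends[keep])
}

same_schedule <- function(a, b, tol = 1e-6) {
  n_frames(a) == n_frames(b) &&
    max(abs(a$starts - b$starts), abs(a$ends - b$ends)) <= tol
}
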