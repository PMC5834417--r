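#' Voxelwise parametric images
#'
#' Applies a regional quantification method to every voxel time series
#' inside a mask. Voxels outside the mask, and voxels whose fit fails
#' (e.g. an identically zero time series), are set to `NA` and counted;
#' a failing voxel never aborts the image.
#'
#' @param img 4D array (x, y, z, frame) or a [generate_phantom()] result.
#' @param schedule A [frame_schedule()] (from the phantom if omitted).
#' @param reference Reference-region [tac()] on the same schedule.
#' @param method `"srtm"`, `"logan"` or `"suvr"`.
#' @param mask Logical/0-1 3D array; default: voxels with any non-zero
#'   frame.
#' @param t_star Equilibrium time for `method = "logan"`, minutes.
#' @param window `c(start, end)` minutes for `method = "suvr"`.
#' @param theta_grid,weights,refine Passed to the SRTM engine.
#' @param dt Fine-grid step for SRTM bases, minutes.
#' @return A list of class `parametric_maps`: 3D arrays (`bpnd`, `R1`,
#'   `k2` for SRTM; `bpnd`, `int` for Logan; `suvr`) plus `n_fit`,
#'   `n_failed` and a `failures` character log.
#' @export
fit_parametric <- function(img, schedule = NULL, reference,
                           method = c("srtm", "logan", "suvr"),
                           mask = NULL, t_star = NULL, window = NULL,
                           theta_grid = default_theta_grid(),
                           weights = NULL, refine = TRUE, dt = 0.01) {
  method <- match.arg(method)
  if (inherits(img, "dynamic_phantom")) {
    if (is.null(schedule)) schedule <- img$schedule
    img <- img$img
  }
  img <- as.array(img)
  stopifnot(length(dim(img)) == 4, inherits(reference, "tac"))
  if (!same_schedule(reference$schedule, schedule)) {
    stop("reference TAC schedule does not match the image frame schedule")
  }
  d3 <- dim(img)[1:3]
  nf <- dim(img)[4]
  imat <- matrix(img, ncol = nf)
  if (is.null(mask)) {
    mask <- array(rowSums(abs(imat)) > 0, d3)
  } else {
    mask <- array(as.logical(mask), d3)
    if (!all(dim(mask) == d3)) stop("mask grid does not match the image grid")
  }
  vox <- which(mask)
  empty <- function() array(NA_real_, d3)
  maps <- switch(method,
    srtm = list(bpnd = empty(), R1 = empty(), k2 = empty()),
    logan = list(bpnd = empty(), int = empty()),
    suvr = list(suvr = empty())
  )
  failures <- character(0)

  if (method == "srtm") {
    basis <- srtm_basis(reference, theta_grid, dt)
  } else if (method == "suvr") {
    if (is.null(window)) stop("method 'suvr' needs a window")
    w <- window_overlap(schedule, window[1], window[2])
    if (sum(w) <= 0) stop("window does not overlap the scan")
    ref_mean <- sum(w * reference$values) / sum(w)
    if (ref_mean <= 0) stop("reference activity in the window is not positive")
  } else if (is.null(t_star)) {
    stop("method 'logan' needs t_star")
  }

  for (v in vox) {
    y <- imat[v, ]
    res <- tryCatch({
      if (all(y == 0)) stop("all-zero time series")
      switch(method,
        srtm = {
          core <- srtm_fit_core(basis, y, weights, refine)
          maps$bpnd[v] <- core$bpnd
          maps$R1[v] <- core$R1
          maps$k2[v] <- core$k2
        },
        logan = {
          f <- fit_reference_logan(tac(schedule, y, "voxel"), reference,
                                   t_star)
          maps$bpnd[v] <- f$bpnd
          maps$int[v] <- f$int
        },
        suvr = {
          maps$suvr[v] <- (sum(w * y) / sum(w)) / ref_mean
        }
      )
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) failures <- c(failures, sprintf("voxel %d: %s", v, res))
  }
  structure(
    c(maps, list(method = method, mask = mask,
                 n_fit = length(vox) - length(failures),
                 n_failed = length(failures), failures = failures)),
    class = "parametric_maps"
  )
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("<parametric_maps> method %s: %d voxels fit, %d failed\n",
              x$method, x$n_fit, x$n_failed))
  invisible(x)
}

#' Write parametric maps as NIfTI volumes
#'
#' One float volume per parameter, named `<prefix>_<parameter>.nii.gz`;
#' missing voxels stay `NA`.
#'
#' @param maps A [fit_parametric()] result.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_parametric_maps <- function(maps, prefix) {
  pars <- intersect(c("bpnd", "R1", "k2", "int", "suvr"), names(maps))
  paths <- vapply(pars, function(p) {
    path <- sprintf("%s_%s.nii.gz", prefix, p)
    RNifti::writeNifti(RNifti::asNifti(maps[[p]]), path)
    path
  }, character(1))
  invisible(paths)
}
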