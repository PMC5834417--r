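#' Build a labelled 4D dynamic phantom
#'
#' Every voxel carrying atlas label `l` receives the frame values of
#' that label's TAC, plus independent frame-count noise; background
#' (label 0) stays zero. Together with [extract_tacs()] and
#' [fit_parametric()] this gives an end-to-end voxelwise test bed with
#' known ground truth.
#'
#' @param atlas 3D integer array of region labels (0 = background).
#' @param regional_tacs Named list of [tac()] objects; names are the
#'   atlas labels as strings (e.g. `"1"`), or region names if
#'   `label_map` is given.
#' @param label_map Optional named integer vector mapping region name ->
#'   label.
#' @param noise_scale Unitless noise magnitude (>= 0).
#' @param seed Optional integer seed.
#' @return A list of class `dynamic_phantom`: `img` (4D array x,y,z,frame),
#'   `schedule`, `atlas`.
#' @export
generate_phantom <- function(atlas, regional_tacs, label_map = NULL,
                             noise_scale = 0, seed = NULL) {
  atlas <- as.array(atlas)
  stopifnot(length(dim(atlas)) == 3)
  if (!is.null(label_map)) {
    names(regional_tacs) <- as.character(label_map[names(regional_tacs)])
  }
  labels <- sort(setdiff(unique(as.integer(atlas)), 0L))
  missing <- setdiff(as.character(labels), names(regional_tacs))
  if (length(missing)) {
    stop("no TAC supplied for atlas label(s): ", paste(missing, collapse = ", "))
  }
  sched <- regional_tacs[[1]]$schedule
  ok <- vapply(regional_tacs, function(t) same_schedule(t$schedule, sched),
               logical(1))
  if (!all(ok)) stop("all phantom TACs must share one frame schedule")
  if (!is.null(seed)) set.seed(seed)

  nf <- n_frames(sched)
  img <- array(0, c(dim(atlas), nf))
  for (lab in labels) {
    vox <- which(atlas == lab)
    tc <- regional_tacs[[as.character(lab)]]
    sd <- if (noise_scale > 0) tac_noise_sd(tc, noise_scale) else rep(0, nf)
    for (f in seq_len(nf)) {
      vals <- tc$values[f]
      if (noise_scale > 0) {
        vals <- vals + stats::rnorm(length(vox), 0, sd[f])
      }
      frame <- img[, , , f, drop = FALSE]
      frame[vox] <- vals
      img[, , , f] <- frame
    }
  }
  structure(list(img = img, schedule = sched, atlas = atlas),
            class = "dynamic_phantom")
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  d <- dim(x$img)
  cat(sprintf("<dynamic_phantom> %dx%dx%d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
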