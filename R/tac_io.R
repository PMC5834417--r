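#' Extract regional TACs from a labelled dynamic image
#'
#' Each region's TAC is the unweighted mean over the voxels carrying its
#' label, frame by frame. The image and atlas must already be on the
#' same voxel grid (this package never registers). Labels present in
#' `region_names` but absent from the atlas are skipped with a warning.
#'
#' @param img 4D array (x, y, z, frame) or a [generate_phantom()] result.
#' @param schedule A [frame_schedule()] (taken from the phantom if one
#'   is passed).
#' @param atlas 3D integer label array on the image grid (0 = background).
#' @param region_names Optional named integer vector region name -> label;
#'   default names regions `"1"`, `"2"`, ... after their labels.
#' @param reference Name of the reference region among the extracted
#'   ones (required to build a [regional_tac_set()]).
#' @param subject,tracer Identifiers for the returned set.
#' @return A [regional_tac_set()].
#' @export
extract_tacs <- function(img, schedule = NULL, atlas = NULL,
                         region_names = NULL, reference = NULL,
                         subject = "s01", tracer = "tracer") {
  if (inherits(img, "dynamic_phantom")) {
    if (is.null(schedule)) schedule <- img$schedule
    if (is.null(atlas)) atlas <- img$atlas
    img <- img$img
  }
  img <- as.array(img)
  atlas <- as.array(atlas)
  stopifnot(length(dim(img)) == 4, length(dim(atlas)) == 3)
  if (!all(dim(img)[1:3] == dim(atlas))) {
    stop(sprintf(
      "image grid %s does not match atlas grid %s",
      paste(dim(img)[1:3], collapse = "x"), paste(dim(atlas), collapse = "x")
    ))
  }
  if (n_frames(schedule) != dim(img)[4]) {
    stop("schedule frame count does not match the image's 4th dimension")
  }
  labels <- sort(setdiff(unique(as.integer(atlas)), 0L))
  if (!length(labels)) stop("atlas contains no non-zero labels")
  if (is.null(region_names)) {
    region_names <- stats::setNames(labels, as.character(labels))
  }
  nf <- dim(img)[4]
  imat <- matrix(img, ncol = nf)  # voxels x frames
  tacs <- list()
  for (nm in names(region_names)) {
    vox <- which(as.integer(atlas) == region_names[[nm]])
    if (!length(vox)) {
      warning(sprintf("region '%s' (label %d) has no voxels; omitted",
                      nm, region_names[[nm]]))
      next
    }
    tacs[[nm]] <- tac(schedule, colMeans(imat[vox, , drop = FALSE]), nm)
  }
  if (is.null(reference)) reference <- names(tacs)[1]
  regional_tac_set(tacs, reference = reference, subject = subject,
                   tracer = tracer)
}

#' Write regional TAC sets as a tidy CSV table
#'
#' Long format, one row per (subject, tracer, region, frame):
#' `subject, tracer, region, reference, frame_start, frame_end, activity`.
#' The reference column repeats each set's reference-region name so the
#' file round-trips losslessly through [read_tac_table()].
#'
#' @param x A [regional_tac_set()], a list of them, or a
#'   [generate_cohort()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(x, path) {
  sets <- flatten_sets(x)
  rows <- lapply(sets, function(s) {
    do.call(rbind, lapply(s$tacs, function(tc) {
      data.frame(subject = s$subject, tracer = s$tracer, region = tc$region,
                 reference = s$reference, frame_start = tc$schedule$starts,
                 frame_end = tc$schedule$ends, activity = tc$values)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

flatten_sets <- function(x) {
  if (inherits(x, "regional_tac_set")) return(list(x))
  if (inherits(x, "cohort_dataset")) {
    return(unlist(x$sets, recursive = FALSE, use.names = FALSE))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "regional_tac_set")))
  x
}

#' Read regional TAC sets from a tidy CSV table
#'
#' Validates the schedule on read: frames must have end > start, be
#' strictly ordered and non-overlapping, all regions of one
#' subject/tracer must share one schedule, and the named reference
#' region must be present.
#'
#' @param path CSV written by [write_tac_table()].
#' @return Named list of [regional_tac_set()], one per subject x tracer,
#'   names `"<subject>.<tracer>"`.
#' @export
read_tac_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "tracer", "region", "reference",
            "frame_start", "frame_end", "activity")
  if (!all(need %in% names(d))) {
    stop("TAC table must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (key in unique(paste(d$subject, d$tracer, sep = "."))) {
    dd <- d[paste(d$subject, d$tracer, sep = ".") == key, ]
    regions <- unique(dd$region)
    sched <- NULL
    tacs <- list()
    for (rg in regions) {
      dr <- dd[dd$region == rg, ]
      dr <- dr[order(dr$frame_start), ]
      s <- frame_schedule(dr$frame_start, dr$frame_end)  # validates frames
      if (is.null(sched)) {
        sched <- s
      } else if (!same_schedule(s, sched)) {
        stop(sprintf("mixed frame schedules within %s (region '%s')", key, rg))
      }
      tacs[[rg]] <- tac(sched, dr$activity, rg)
    }
    ref <- unique(dd$reference)
    if (length(ref) != 1) stop("ambiguous reference region in ", key)
    out[[key]] <- regional_tac_set(tacs, reference = ref,
                                   subject = dd$subject[1],
                                   tracer = dd$tracer[1])
  }
  out
}

#' Write / read a dynamic image with its frame timing
#'
#' Volumes go to NIfTI-1 (via RNifti); timing goes to a sidecar CSV with
#' columns `frame_start`, `frame_end` in minutes.
#'
#' @param img 4D array or [generate_phantom()] result.
#' @param schedule A [frame_schedule()] (from the phantom if omitted).
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>_timing.csv` (plus `<prefix>_atlas.nii.gz` for phantoms).
#' @return `prefix`, invisibly.
#' @export
write_dynamic_image <- function(img, schedule = NULL, prefix) {
  atlas <- NULL
  if (inherits(img, "dynamic_phantom")) {
    if (is.null(schedule)) schedule <- img$schedule
    atlas <- img$atlas
    img <- img$img
  }
  RNifti::writeNifti(RNifti::asNifti(img), paste0(prefix, ".nii.gz"))
  utils::write.csv(
    data.frame(frame_start = schedule$starts, frame_end = schedule$ends),
    paste0(prefix, "_timing.csv"), row.names = FALSE
  )
  if (!is.null(atlas)) {
    RNifti::writeNifti(RNifti::asNifti(atlas + 0L),
                       paste0(prefix, "_atlas.nii.gz"))
  }
  invisible(prefix)
}

#' @rdname write_dynamic_image
#' @export
read_dynamic_image <- function(prefix) {
  nii <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  img <- array(as.numeric(nii), dim(nii))
  timing <- utils::read.csv(paste0(prefix, "_timing.csv"))
  sched <- frame_schedule(timing$frame_start, timing$frame_end)
  atlas_path <- paste0(prefix, "_atlas.nii.gz")
  atlas <- if (file.exists(atlas_path)) {
    a <- RNifti::readNifti(atlas_path)
    array(as.integer(round(a)), dim(a))
  }
  list(img = img, schedule = sched, atlas = atlas)
}
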