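test_that("extraction averages voxels within each label", {
  sched <- toy_sched()
  nf <- n_frames(sched)
  atlas <- block_atlas()
  img <- array(0, c(dim(atlas), nf))
  # constant value per label: 1 and 2 on disjoint supports
  for (f in seq_len(nf)) {
    frame <- array(0, dim(atlas))
    frame[atlas == 1] <- 1
    frame[atlas == 2] <- 2
    img[, , , f] <- frame
  }
  ex <- extract_tacs(img, sched, atlas,
                     region_names = c(one = 1, two = 2), reference = "one")
  expect_equal(ex$tacs$one$values, rep(1, nf))
  expect_equal(ex$tacs$two$values, rep(2, nf))
})

test_that("extraction is linear in the image and voxel-order invariant", {
  ref <- bolus_ref(toy_sched())
  tgt <- generate_target_tac(ref, truth_row())
  atlas <- block_atlas()
  ph <- generate_phantom(atlas, list(`1` = ref, `2` = tgt, `3` = tgt),
                        noise_scale = 0.2, seed = 5)
  ex1 <- extract_tacs(ph, reference = "1")
  ex2 <- extract_tacs(ph$img * 3, ph$schedule, atlas, reference = "1")
  expect_equal(ex2$tacs[["2"]]$values, 3 * ex1$tacs[["2"]]$values)
  # permute voxels within label 1's slab: the mean is unchanged
  img <- ph$img
  vox <- which(atlas == 1)
  set.seed(1)
  perm <- sample(vox)
  for (f in seq_len(dim(img)[4])) {
    frame <- img[, , , f]
    frame[vox] <- frame[perm]
    img[, , , f] <- frame
  }
  ex3 <- extract_tacs(img, ph$schedule, atlas, reference = "1")
  expect_equal(ex3$tacs[["1"]]$values, ex1$tacs[["1"]]$values)
})

test_that("grid mismatches and empty atlases are rejected", {
  img <- array(1, c(4, 4, 2, 3))
  expect_error(extract_tacs(img, frame_schedule(0:2, 1:3), array(1L, c(3, 4, 2))),
               "does not match")
  expect_error(extract_tacs(img, frame_schedule(0:2, 1:3), array(0L, c(4, 4, 2))),
               "no non-zero labels")
  expect_error(extract_tacs(img, frame_schedule(0:1, 1:2), array(1L, c(4, 4, 2))),
               "frame count")
})

test_that("TAC tables round-trip losslessly through CSV", {
  ch <- tiny_cohort(n = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac_table(ch, path)
  back <- read_tac_table(path)
  expect_length(back, 2)
  s <- back$s01.av45
  orig <- ch$sets$av45$s01
  expect_equal(sort(names(s$tacs)), sort(names(orig$tacs)))
  expect_equal(s$reference, orig$reference)
  expect_equal(s$tacs$frontal$values, orig$tacs$frontal$values)
  expect_true(same_schedule <- refkin:::same_schedule(
    s$tacs$frontal$schedule, orig$tacs$frontal$schedule))
})

test_that("malformed TAC tables produce descriptive errors", {
  ch <- tiny_cohort(n = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac_table(ch, path)
  d <- read.csv(path)

  bad <- d
  bad$frame_end[1] <- bad$frame_start[1] - 0.1  # end before start
  p1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p1, row.names = FALSE)
  expect_error(read_tac_table(p1), "exceed its start|overlap")

  bad <- d
  bad$frame_start[bad$region == "frontal" & bad$subject == "s01"][1] <- 0.01
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p2, row.names = FALSE)
  expect_error(read_tac_table(p2), "mixed frame schedules|overlap")

  bad <- d[d$region != "reference", ]  # reference region dropped
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, p3, row.names = FALSE)
  expect_error(read_tac_table(p3), "reference")
})

test_that("dynamic images and atlases round-trip through NIfTI", {
  ref <- bolus_ref(toy_sched())
  atlas <- block_atlas()
  ph <- generate_phantom(atlas, list(`1` = ref, `2` = ref, `3` = ref))
  prefix <- file.path(withr::local_tempdir(), "phantom")
  write_dynamic_image(ph, prefix = prefix)
  back <- read_dynamic_image(prefix)
  expect_equal(dim(back$img), dim(ph$img))
  expect_equal(as.vector(back$img), as.vector(ph$img), tolerance = 1e-6)
  expect_identical(back$atlas, atlas)
  expect_true(refkin:::same_schedule(back$schedule, ph$schedule))
})
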