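test_that("SRTM identity case: target equal to reference", {
  ref <- bolus_ref()
  f <- fit_srtm(ref, ref)
  expect_equal(f$R1, 1, tolerance = 1e-8)
  expect_equal(f$bpnd, 0, tolerance = 1e-8)
  expect_true(f$degenerate)  # k2 unidentifiable when the curves coincide
})

test_that("SRTM recovers noiseless forward-model parameters", {
  ref <- bolus_ref()
  draws <- list(truth_row(R1 = 0.7, k2 = 0.05, bpnd = 0.3),
                truth_row(R1 = 1.3, k2 = 0.25, bpnd = 2.8),
                truth_row(R1 = 1.0, k2 = 0.12, bpnd = 1.0))
  for (tt in draws) {
    f <- fit_srtm(generate_target_tac(ref, tt), ref)
    expect_equal(f$R1, tt$R1, tolerance = 1e-4)
    expect_equal(f$k2, tt$k2, tolerance = 1e-4)
    expect_equal(f$bpnd, tt$bpnd, tolerance = 1e-4)
    expect_false(f$boundary)
  }
})

test_that("a grid containing the true rate gives machine-precision WRSS", {
  ref <- bolus_ref()
  tt <- truth_row(R1 = 1.1, k2 = 0.15, bpnd = 1.4)
  theta_true <- tt$k2 / (1 + tt$bpnd)
  grid <- sort(c(default_theta_grid(25), theta_true))
  f <- fit_srtm(generate_target_tac(ref, tt), ref, theta_grid = grid,
                refine = FALSE)
  scale <- sum(generate_target_tac(ref, tt)$values^2)
  expect_lt(f$wrss / scale, 1e-20)
  expect_equal(f$theta, theta_true, tolerance = 1e-12)
})

test_that("SRTM estimates are invariant to joint rescaling of the TACs", {
  ref <- bolus_ref()
  tt <- truth_row(R1 = 0.9, k2 = 0.18, bpnd = 0.7)
  tgt <- generate_target_tac(ref, tt)
  scale <- function(x, c) tac(x$schedule, c * x$values, x$region,
                              fine_t = x$fine_t, fine_x = c * x$fine_x)
  f1 <- fit_srtm(tgt, ref)
  f2 <- fit_srtm(scale(tgt, 37), scale(ref, 37))
  expect_equal(f2$R1, f1$R1, tolerance = 1e-10)
  expect_equal(f2$k2, f1$k2, tolerance = 1e-10)
  expect_equal(f2$bpnd, f1$bpnd, tolerance = 1e-10)
})

test_that("SRTM works from frame data alone (interpolated reference)", {
  ref <- bolus_ref()
  tt <- truth_row(R1 = 1.0, k2 = 0.15, bpnd = 1.5)
  tgt <- generate_target_tac(ref, tt)
  strip <- function(x) tac(x$schedule, x$values, x$region)
  f <- fit_srtm(strip(tgt), strip(ref))
  expect_equal(f$bpnd, tt$bpnd, tolerance = 0.05)
  expect_equal(f$R1, tt$R1, tolerance = 0.05)
})

test_that("degenerate and invalid SRTM inputs error cleanly", {
  ref <- bolus_ref(toy_sched())
  zero <- tac(toy_sched(), rep(0, n_frames(toy_sched())))
  expect_error(fit_srtm(zero, ref), "identically zero")
  bad <- tac(toy_sched(), ref$values)
  bad$values[2] <- Inf
  expect_error(fit_srtm(bad, ref), "non-finite")
  other <- bolus_ref(fs_av45())
  expect_error(fit_srtm(other, ref), "share one frame schedule")
})

test_that("reference Logan on the identity line returns zero binding", {
  ref <- bolus_ref()
  f <- fit_reference_logan(ref, ref, t_star = 20)
  expect_equal(f$bpnd, 0, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("reference Logan approaches the true BP_ND as t* grows", {
  ref <- bolus_ref()
  tgt <- generate_target_tac(ref, truth_row(R1 = 1, k2 = 0.2, bpnd = 2))
  bps <- vapply(c(5, 10, 15, 20, 25, 30), function(ts) {
    fit_reference_logan(tgt, ref, ts)$bpnd
  }, numeric(1))
  expect_true(all(diff(bps) > 0))
  expect_lt(abs(bps[4] - 2) / 2, 0.02)  # t* = 20 min
})

test_that("Logan rejects insufficient late frames and zero-crossing targets", {
  ref <- bolus_ref()
  expect_error(fit_reference_logan(ref, ref, t_star = 58), "at least 3")
  flat <- tac(ref$schedule, c(rep(1, 10), rep(1e-12, 17)))
  expect_error(fit_reference_logan(flat, ref, t_star = 10), "near zero")
})

test_that("SUVR trivial ratios and window errors behave", {
  ref <- bolus_ref()
  dbl <- tac(ref$schedule, 2 * ref$values, "double")
  s <- regional_tac_set(list(reference = ref, double = dbl), "reference")
  for (win in list(c(0, 60), c(10, 30), c(40, 60))) {
    sv <- compute_suvr(s, win)
    expect_equal(sv$suvr[sv$region == "reference"], 1)
    expect_equal(sv$suvr[sv$region == "double"], 2, tolerance = 1e-12)
  }
  expect_error(compute_suvr(s, c(70, 90)), "does not overlap")
})

test_that("SUVR is additive over merged adjacent frames", {
  ref <- bolus_ref()
  tgt <- generate_target_tac(ref, truth_row())
  s <- compute_suvr(regional_tac_set(list(reference = ref, tgt = tgt),
                                     "reference"), c(30, 60))
  # merge the 300 s frames spanning [30, 60] into two 15-min frames
  sched <- ref$schedule
  keep <- sched$ends <= 30
  merge_frames <- function(x) {
    m1 <- sum(x$values[sched$starts >= 30 & sched$ends <= 45] *
                frame_durations(sched)[sched$starts >= 30 & sched$ends <= 45]) / 15
    m2 <- sum(x$values[sched$starts >= 45 & sched$ends <= 60] *
                frame_durations(sched)[sched$starts >= 45 & sched$ends <= 60]) / 15
    tac(frame_schedule(c(sched$starts[keep], 30, 45),
                       c(sched$ends[keep], 45, 60)),
        c(x$values[keep], m1, m2), x$region)
  }
  s2 <- compute_suvr(regional_tac_set(
    list(reference = merge_frames(ref), tgt = merge_frames(tgt)),
    "reference"), c(30, 60))
  expect_equal(s2$suvr, s$suvr, tolerance = 1e-12)
})

test_that("voxelwise maps honour masks and tolerate dead voxels", {
  ref <- bolus_ref(toy_sched())
  tgt <- generate_target_tac(ref, truth_row(R1 = 0.9, k2 = 0.14, bpnd = 0.8))
  atlas <- block_atlas()
  ph <- generate_phantom(atlas, list(`1` = ref, `2` = tgt, `3` = tgt))
  mask <- atlas > 0
  mask[1, 1, 1] <- FALSE
  img <- ph$img
  img[2, 1, 1, ] <- 0  # dead voxel inside the mask
  pm <- fit_parametric(img, ph$schedule, ref, "srtm", mask = mask)
  expect_true(is.na(pm$bpnd[1, 1, 1]))  # masked out
  expect_true(is.na(pm$bpnd[2, 1, 1]))  # failed, not thrown
  expect_equal(pm$n_failed, 1)
  expect_match(pm$failures[1], "all-zero")
  expect_equal(pm$bpnd[4, 2, 1], 0.8, tolerance = 1e-3)
})
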