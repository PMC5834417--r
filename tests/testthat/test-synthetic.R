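test_that("reference TAC matches the closed form for a boxcar input", {
  # unit-height boxcar on [0, 1] min, K1 = 1, k2 = 0.1: the one-tissue
  # solution is (1 - exp(-0.1 t)) / 0.1 during the boxcar, then decays
  # as C(1) exp(-0.1 (t - 1)). Frame averages computed by quadrature of
  # the closed form are the oracle.
  boxcar <- input_function("custom", fun = function(t) as.numeric(t <= 1))
  sched <- frame_schedule(seq(0, 9.5, 0.5), seq(0.5, 10, 0.5))
  # 0.001-min grid: the convolution treats the input as piecewise linear,
  # so the jump at t = 1 is resolved to within one step
  got <- generate_reference_tac(boxcar, 1, 0.1, sched, dt = 0.001)
  closed <- function(t) {
    ifelse(t <= 1, (1 - exp(-0.1 * t)) / 0.1,
           (1 - exp(-0.1)) / 0.1 * exp(-0.1 * (t - 1)))
  }
  want <- vapply(seq_len(n_frames(sched)), function(i) {
    stats::integrate(closed, sched$starts[i], sched$ends[i],
                     rel.tol = 1e-10)$value / frame_durations(sched)[i]
  }, numeric(1))
  expect_equal(got$values, want, tolerance = 1e-3)
})

test_that("reference TAC is zero for zero input and linear in K1", {
  zero <- input_function("custom", fun = function(t) 0 * t)
  sched <- toy_sched()
  expect_equal(generate_reference_tac(zero, 1, 0.1, sched)$values,
               rep(0, n_frames(sched)))
  r1 <- bolus_ref(sched, K1 = 0.3)
  r2 <- bolus_ref(sched, K1 = 0.6)
  expect_equal(r2$values, 2 * r1$values, tolerance = 1e-12)
})

test_that("schedules beyond the simulation horizon are rejected", {
  ref <- bolus_ref(toy_sched())
  long <- frame_schedule(c(0, 50), c(50, 100))
  expect_error(generate_target_tac(ref, truth_row(), long),
               "beyond the reference fine grid")
})

test_that("target TAC collapses to the reference when R1 = 1, BP_ND = 0", {
  ref <- bolus_ref()
  tgt <- generate_target_tac(ref, truth_row(R1 = 1, k2 = 0.23, bpnd = 0))
  expect_equal(tgt$values, ref$values, tolerance = 1e-10)
})

test_that("target TAC matches an independent FFT convolution oracle", {
  ref <- bolus_ref()
  tt <- truth_row(R1 = 0.8, k2 = 0.15, bpnd = 1.5)
  got <- generate_target_tac(ref, tt)
  fine_oracle <- oracle_srtm_curve(ref$fine_t, ref$fine_x,
                                   tt$R1, tt$k2, tt$bpnd)
  want <- oracle_frame_average(ref$fine_t, fine_oracle, ref$schedule)
  expect_equal(got$values, want, tolerance = 1e-3)
})

test_that("the infinite-binding limit gives C_R plus k2 times its integral", {
  ref <- bolus_ref()
  k2 <- 0.12
  tgt <- generate_target_tac(ref, truth_row(R1 = 1, k2 = k2, bpnd = 1e6))
  dt <- ref$fine_t[2] - ref$fine_t[1]
  int_cr <- c(0, cumsum((ref$fine_x[-length(ref$fine_x)] +
                           ref$fine_x[-1]) / 2 * dt))
  limit <- ref$fine_x + k2 * int_cr
  expect_equal(tgt$fine_x, limit, tolerance = 1e-4)
})

test_that("generated curves satisfy the reference-tissue ODE on the fine grid", {
  # dC_T/dt = R1 dC_R/dt + k2 C_R - theta C_T, theta = k2/(1+BP_ND);
  # substituting u = C_T - R1 C_R recovers the convolution form of the model
  ref <- bolus_ref()
  for (tt in list(truth_row(R1 = 0.7, k2 = 0.08, bpnd = 0.4),
                  truth_row(R1 = 1.2, k2 = 0.2, bpnd = 2.5))) {
    tgt <- generate_target_tac(ref, tt)
    t <- ref$fine_t
    dt <- t[2] - t[1]
    i <- seq(3, length(t) - 2)  # skip edges of the central difference
    d <- function(x) (x[i + 1] - x[i - 1]) / (2 * dt)
    theta <- tt$k2 / (1 + tt$bpnd)
    lhs <- d(tgt$fine_x)
    rhs <- tt$R1 * d(ref$fine_x) + tt$k2 * ref$fine_x[i] -
      theta * tgt$fine_x[i]
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 5e-3)
  }
})

test_that("invalid binding potential is rejected", {
  ref <- bolus_ref(toy_sched())
  expect_error(generate_target_tac(ref, truth_row(bpnd = -1)),
               "undefined")
})

test_that("noise model: identity at zero, deterministic under a seed", {
  ref <- bolus_ref(toy_sched())
  expect_identical(add_noise(ref, 0), ref)
  a <- add_noise(ref, 0.1, seed = 3)
  b <- add_noise(ref, 0.1, seed = 3)
  expect_identical(a$values, b$values)
  expect_false(identical(add_noise(ref, 0.1, seed = 4)$values, a$values))
})

test_that("empirical frame SD matches the count-based variance model", {
  ref <- bolus_ref(frame_schedule(c(0, 2, 10), c(2, 10, 40)))
  set.seed(123)
  reps <- replicate(10000, add_noise(ref, 0.05)$values)
  want <- refkin:::tac_noise_sd(ref, 0.05)
  expect_equal(apply(reps, 1, sd), want, tolerance = 0.03)
})

test_that("cohorts collapse to the mean parameterisation at zero spread", {
  ch <- tiny_cohort(n = 3)
  v1 <- ch$sets$av45$s01$tacs$frontal$values
  v2 <- ch$sets$av45$s03$tacs$frontal$values
  expect_identical(v1, v2)
  expect_equal(unique(round(ch$truth$bpnd[ch$truth$region == "frontal"], 12)),
               ts_av45()$regions$bpnd[1])
})

test_that("cohort generation is seed-deterministic", {
  spec <- cohort_spec(ts_av45(), n_subjects = 3, seed = 21)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  c <- generate_cohort(spec, seed = 22)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sets$av45$s02$tacs$frontal$values,
                   b$sets$av45$s02$tacs$frontal$values)
  expect_false(identical(a$truth$bpnd, c$truth$bpnd))
})

test_that("the copula induces the requested binding correlation", {
  regs <- rbind(region_truth("a", 1, 0.15, 0.8),
                region_truth("b", 1, 0.15, 1.2))
  tsp <- tracer_spec("t", toy_sched(), input_function(), 0.3, 0.15,
                     regs, noise_scale = 0)
  bc <- bp_cor_from_pairs(c("t:a", "t:b"),
                          list(list(a = "t:a", b = "t:b", rho = 0.9)))
  ch <- generate_cohort(cohort_spec(tsp, n_subjects = 500, bp_cor = bc,
                                    seed = 31))
  wide <- merge(ch$truth[ch$truth$region == "a", c("subject", "bpnd")],
                ch$truth[ch$truth$region == "b", c("subject", "bpnd")],
                by = "subject")
  expect_equal(cor(wide$bpnd.x, wide$bpnd.y), 0.9, tolerance = 0.03)
})

test_that("non-positive-semidefinite correlation matrices are rejected", {
  keys <- c("t:a", "t:b", "t:c")
  m <- diag(3)
  dimnames(m) <- list(keys, keys)
  m[1, 2] <- m[2, 1] <- 0.95
  m[1, 3] <- m[3, 1] <- 0.95
  m[2, 3] <- m[3, 2] <- -0.5
  regs <- rbind(region_truth("a", 1, 0.15, 1), region_truth("b", 1, 0.15, 1),
                region_truth("c", 1, 0.15, 1))
  tsp <- tracer_spec("t", toy_sched(), input_function(), 0.3, 0.15, regs)
  expect_error(cohort_spec(tsp, bp_cor = m), "eigenvalue")
})

test_that("phantoms replay their TACs voxelwise and respect labels", {
  ref <- bolus_ref(toy_sched())
  tgt <- generate_target_tac(ref, truth_row())
  atlas <- block_atlas()
  atlas[1, 1, 1] <- 0L  # leave some background
  ph <- generate_phantom(atlas, list(`1` = ref, `2` = tgt, `3` = tgt))
  expect_equal(dim(ph$img), c(dim(atlas), n_frames(toy_sched())))
  # single voxel check
  v <- which(atlas == 2)[1]
  ijk <- arrayInd(v, dim(atlas))
  expect_equal(ph$img[ijk[1], ijk[2], ijk[3], ], tgt$values)
  # background stays zero in every frame
  imat <- matrix(ph$img, ncol = n_frames(toy_sched()))
  expect_true(all(imat[which(atlas == 0), ] == 0))
  expect_error(generate_phantom(atlas, list(`1` = ref)), "label")
})

test_that("noisy phantom region means concentrate around the truth", {
  ref <- bolus_ref(toy_sched())
  atlas <- array(1L, c(10, 10, 10))  # 1000 voxels
  ph <- generate_phantom(atlas, list(`1` = ref), noise_scale = 0.1, seed = 8)
  ex <- extract_tacs(ph, reference = "1")
  se <- refkin:::tac_noise_sd(ref, 0.1) / sqrt(1000)
  expect_true(all(abs(ex$tacs[["1"]]$values - ref$values) < 3.5 * se))
})
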