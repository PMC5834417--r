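# Shared fixtures: small schedules, canned reference/target curves and
# mini cohorts, generated in code at test time.

fast_sched <- function() fs_av45()
slow_sched <- function() fs_av1451()

# a coarse 10-frame schedule for cheap structural tests
toy_sched <- function() frame_schedule(seq(0, 18, 2), seq(2, 20, 2))

bolus_ref <- function(schedule = fast_sched(), K1 = 0.3, k2 = 0.15) {
  generate_reference_tac(input_function(), K1, k2, schedule)
}

truth_row <- function(region = "tgt", R1 = 1.0, k2 = 0.15, bpnd = 1.5) {
  list(region = region, R1 = R1, k2 = k2, bpnd = bpnd)
}

# tiny noiseless cohort (one tracer), deterministic
tiny_cohort <- function(tspec = ts_av45(noise_scale = 0), n = 2,
                        cv = c(R1 = 0, k2 = 0, bpnd = 0), seed = 7) {
  generate_cohort(cohort_spec(tspec, n_subjects = n, cv = cv, seed = seed))
}

# 3-region block atlas used by phantom tests
block_atlas <- function(nx = 6, ny = 6, nz = 2) {
  a <- array(0L, c(nx, ny, nz))
  a[seq_len(nx / 2), , ] <- 1L
  a[(nx / 2 + 1):nx, seq_len(ny / 2), ] <- 2L
  a[(nx / 2 + 1):nx, (ny / 2 + 1):ny, ] <- 3L
  a
}
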