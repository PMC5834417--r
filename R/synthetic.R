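#' Ground-truth kinetic parameters for one region
#'
#' @param region Region label.
#' @param R1 Delivery ratio target/reference (unitless, > 0).
#' @param k2 Efflux rate constant from target tissue, 1/min (> 0).
#' @param bpnd Non-displaceable binding potential (unitless, > -1).
#' @return A one-row tibble with columns `region`, `R1`, `k2`, `bpnd`.
#' @export
region_truth <- function(region, R1, k2, bpnd) {
  stopifnot(R1 > 0, k2 > 0, bpnd > -1)
  tibble::tibble(region = as.character(region), R1 = R1, k2 = k2, bpnd = bpnd)
}

#' Decay constant of fluorine-18
#'
#' log(2) / 109.77 min, used by the frame-count noise model.
#' @return 1/min.
#' @export
lambda_f18 <- function() log(2) / 109.77

#' Simulate a reference-region TAC
#'
#' One-tissue compartment solution
#' `C_R(t) = K1_ref * (IF conv exp(-k2_ref t))(t)` evaluated on an
#' internal fine grid and averaged over each frame (scanners bin counts,
#' so frame values are time-averages, not midpoint samples).
#'
#' @param ifn An [input_function()].
#' @param K1_ref Delivery into the reference tissue, mL/min/mL (> 0).
#' @param k2_ref Efflux from the reference tissue, 1/min (> 0).
#' @param schedule A [frame_schedule()].
#' @param dt Fine-grid step, minutes (default 0.01).
#' @return A [tac()] carrying its fine-grid curve.
#' @export
generate_reference_tac <- function(ifn, K1_ref, k2_ref, schedule, dt = 0.01) {
  stopifnot(inherits(ifn, "input_function"), K1_ref > 0, k2_ref > 0)
  ft <- fine_grid(schedule, dt)
  cr <- K1_ref * exp_conv(if_values(ifn, ft), k2_ref, dt)
  tac(schedule, frame_average(ft, cr, schedule), region = "reference",
      fine_t = ft, fine_x = cr)
}

# SRTM forward model on the fine grid of a reference curve:
# C_T = R1 C_R + (k2 - R1 k2/(1+BP)) * (C_R conv exp(-k2/(1+BP) t))
srtm_forward_fine <- function(fine_t, fine_cr, R1, k2, bpnd) {
  theta <- k2 / (1 + bpnd)
  dt <- fine_t[2] - fine_t[1]
  R1 * fine_cr + (k2 - R1 * theta) * exp_conv(fine_cr, theta, dt)
}

#' Simulate a target-region TAC from the SRTM forward model
#'
#' Evaluates the simplified reference tissue model on the reference
#' TAC's fine grid and frame-averages onto `schedule`. The reference
#' TAC must carry a fine grid (as produced by
#' [generate_reference_tac()]) at least as long as the schedule.
#'
#' @param ref_tac Reference [tac()] with fine grid.
#' @param truth A [region_truth()] row (or any list with `R1`, `k2`,
#'   `bpnd`, `region`).
#' @param schedule Target [frame_schedule()]; defaults to the
#'   reference's.
#' @return A [tac()] carrying its fine-grid curve.
#' @export
generate_target_tac <- function(ref_tac, truth, schedule = ref_tac$schedule) {
  stopifnot(inherits(ref_tac, "tac"))
  if (is.null(ref_tac$fine_t)) {
    stop("ref_tac must carry a fine-grid curve (see generate_reference_tac)")
  }
  if (truth$bpnd <= -1) {
    stop("bpnd must exceed -1: apparent efflux rate k2/(1+BP_ND) undefined")
  }
  stopifnot(truth$R1 > 0, truth$k2 > 0)
  if (scan_end(schedule) > ref_tac$fine_t[length(ref_tac$fine_t)] + 1e-9) {
    stop("schedule extends beyond the reference fine grid")
  }
  ct <- srtm_forward_fine(ref_tac$fine_t, ref_tac$fine_x,
                          truth$R1, truth$k2, truth$bpnd)
  tac(schedule, frame_average(ref_tac$fine_t, ct, schedule),
      region = truth$region, fine_t = ref_tac$fine_t, fine_x = ct)
}

#' Add frame-count-based Gaussian noise to a TAC
#'
#' The per-frame standard deviation is the usual count-statistics
#' surrogate
#' `sd_i = noise_scale * sqrt(max(C_i, eps) * exp(lambda * t_mid,i) / dur_i)`:
#' variance grows with activity, shrinks with frame length, and is
#' inflated late in the scan where decay (lambda, 1/min; default
#' fluorine-18) has eaten into the counts. `noise_scale = 0` returns the
#' input unchanged. Noise is applied to the frame values only; the fine
#' grid, being unobservable, is dropped.
#'
#' @param x A [tac()].
#' @param noise_scale Unitless noise magnitude (>= 0).
#' @param decay_constant Isotope decay constant, 1/min.
#' @param seed Optional integer; fixed seed gives reproducible noise.
#' @return A [tac()] with noisy frame values.
#' @export
add_noise <- function(x, noise_scale, decay_constant = lambda_f18(),
                      seed = NULL) {
  stopifnot(inherits(x, "tac"), noise_scale >= 0)
  if (noise_scale == 0) return(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sd <- tac_noise_sd(x, noise_scale, decay_constant)
  tac(x$schedule, x$values + stats::rnorm(length(sd), 0, sd), x$region)
}

# The noise model's per-frame sd (exported logic kept in one place so
# tests can check the Monte-Carlo sd against the same formula).
tac_noise_sd <- function(x, noise_scale, decay_constant = lambda_f18(),
                         eps = 1e-3) {
  mid <- frame_midpoints(x$schedule)
  dur <- frame_durations(x$schedule)
  noise_scale * sqrt(pmax(x$values, eps) * exp(decay_constant * mid) / dur)
}

#' Per-tracer simulation settings
#'
#' @param name Tracer label, e.g. `"av45"`.
#' @param schedule A [frame_schedule()].
#' @param ifn An [input_function()].
#' @param K1_ref,k2_ref Reference-tissue one-tissue parameters
#'   (mL/min/mL and 1/min).
#' @param regions Tibble of mean ground truth with columns `region`,
#'   `R1`, `k2`, `bpnd` (rows from [region_truth()]).
#' @param noise_scale Frame-noise magnitude for this tracer.
#' @return An object of class `tracer_spec`.
#' @export
tracer_spec <- function(name, schedule, ifn = input_function(),
                        K1_ref = 0.3, k2_ref = 0.15,
                        regions, noise_scale = 0.05) {
  stopifnot(inherits(schedule, "frame_schedule"), K1_ref > 0, k2_ref > 0,
            noise_scale >= 0,
            all(c("region", "R1", "k2", "bpnd") %in% names(regions)))
  structure(
    list(name = name, schedule = schedule, ifn = ifn,
         K1_ref = K1_ref, k2_ref = k2_ref,
         regions = tibble::as_tibble(regions), noise_scale = noise_scale),
    class = "tracer_spec"
  )
}

#' Default fast-kinetics (amyloid-like) and slow-kinetics (tau-like)
#' tracer specifications
#'
#' The fast tracer is a 60-min acquisition with reference efflux
#' 0.15/min and target efflux around 0.14/min, so the apparent rate
#' k2/(1+BP_ND) puts equilibration on a ~15-25 min timescale; the slow
#' tracer is a 120-min acquisition with efflux around 0.045/min,
#' equilibrating roughly three times later. Regions span low to high
#' binding (BP_ND 0.3-1.8), mimicking the cortical/subcortical spread
#' seen in amyloid and tau imaging of early Alzheimer's disease.
#'
#' @param noise_scale Frame-noise magnitude (default 0.05).
#' @return A `tracer_spec`.
#' @export
ts_av45 <- function(noise_scale = 0.05) {
  regions <- rbind(
    region_truth("frontal",    R1 = 0.95, k2 = 0.14, bpnd = 1.2),
    region_truth("precuneus",  R1 = 1.00, k2 = 0.15, bpnd = 1.6),
    region_truth("thalamus",   R1 = 1.05, k2 = 0.16, bpnd = 0.8),
    region_truth("hippocampus", R1 = 0.85, k2 = 0.13, bpnd = 0.5),
    region_truth("amygdala",   R1 = 0.85, k2 = 0.13, bpnd = 0.6),
    region_truth("striatum",   R1 = 1.10, k2 = 0.17, bpnd = 1.4)
  )
  tracer_spec("av45", fs_av45(), input_function(), K1_ref = 0.3,
              k2_ref = 0.15, regions = regions, noise_scale = noise_scale)
}

#' @rdname ts_av45
#' @export
ts_av1451 <- function(noise_scale = 0.05) {
  regions <- rbind(
    region_truth("frontal",    R1 = 0.95, k2 = 0.045, bpnd = 0.4),
    region_truth("precuneus",  R1 = 1.00, k2 = 0.048, bpnd = 0.5),
    region_truth("thalamus",   R1 = 1.05, k2 = 0.050, bpnd = 0.9),
    region_truth("hippocampus", R1 = 0.85, k2 = 0.042, bpnd = 1.1),
    region_truth("amygdala",   R1 = 0.85, k2 = 0.042, bpnd = 1.0),
    region_truth("striatum",   R1 = 1.10, k2 = 0.052, bpnd = 1.3)
  )
  tracer_spec("av1451", fs_av1451(), input_function(), K1_ref = 0.28,
              k2_ref = 0.05, regions = regions, noise_scale = noise_scale)
}

#' Cohort simulation specification
#'
#' Defines a multi-subject, possibly multi-tracer simulated study.
#' Subject-level parameters are drawn log-normally around the tracer
#' means with coefficient of variation `cv` (BP_ND as `1 + BP_ND`
#' log-normal, preserving `bpnd > -1`); a Gaussian copula over the
#' latent normals of `1 + BP_ND` induces the requested between-subject
#' correlation of binding across regions and tracers.
#'
#' @param tracers List of [tracer_spec()] objects.
#' @param n_subjects Number of subjects (>= 2; default 12, the size of
#'   a typical pilot cohort).
#' @param cv Named numeric: between-subject coefficient of variation for
#'   `R1`, `k2`, `bpnd` (and the reference parameters, which reuse `R1`
#'   and `k2` entries).
#' @param bp_cor Optional correlation matrix for `1 + BP_ND` latents
#'   across all tracer:region combinations, with dimnames
#'   `"<tracer>:<region>"`; defaults to identity. Must be symmetric with
#'   unit diagonal and positive semidefinite.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(tracers, n_subjects = 12,
                        cv = c(R1 = 0.08, k2 = 0.10, bpnd = 0.20),
                        bp_cor = NULL, seed = 1L) {
  if (inherits(tracers, "tracer_spec")) tracers <- list(tracers)
  stopifnot(length(tracers) >= 1, n_subjects >= 2,
            all(c("R1", "k2", "bpnd") %in% names(cv)), all(cv >= 0))
  names(tracers) <- vapply(tracers, function(t) t$name, character(1))
  keys <- unlist(lapply(tracers, function(tr) {
    paste(tr$name, tr$regions$region, sep = ":")
  }), use.names = FALSE)
  if (is.null(bp_cor)) {
    bp_cor <- diag(length(keys))
    dimnames(bp_cor) <- list(keys, keys)
  } else {
    bp_cor <- validate_bp_cor(bp_cor, keys)
  }
  structure(
    list(tracers = tracers, n_subjects = as.integer(n_subjects), cv = cv,
         bp_cor = bp_cor, keys = keys, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

validate_bp_cor <- function(m, keys) {
  m <- as.matrix(m)
  if (is.null(dimnames(m)[[1]])) {
    if (nrow(m) != length(keys)) stop("bp_cor dimension does not match regions")
    dimnames(m) <- list(keys, keys)
  }
  if (!setequal(rownames(m), keys)) {
    stop("bp_cor dimnames must be the tracer:region keys: ",
         paste(keys, collapse = ", "))
  }
  m <- m[keys, keys]
  if (max(abs(m - t(m))) > 1e-8) stop("bp_cor must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("bp_cor must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("bp_cor is not positive semidefinite (smallest eigenvalue %.3g)",
                 min(ev)))
  }
  m
}

#' Convenience correlation matrix from a list of region pairs
#'
#' @param keys Character vector of `"tracer:region"` keys, in order.
#' @param pairs List of `list(a =, b =, rho =)` entries.
#' @return Correlation matrix with the requested off-diagonals.
#' @export
bp_cor_from_pairs <- function(keys, pairs) {
  m <- diag(length(keys))
  dimnames(m) <- list(keys, keys)
  for (p in pairs) {
    m[p$a, p$b] <- m[p$b, p$a] <- p$rho
  }
  validate_bp_cor(m, keys)
}

# log-normal with mean `mu` and coefficient of variation `cv`, driven by
# standard-normal draws z (so copula correlation can be injected).
lnorm_from_z <- function(z, mu, cv) {
  if (cv == 0) return(rep(mu, length(z)))
  s2 <- log(1 + cv^2)
  mu * exp(sqrt(s2) * z - s2 / 2)
}

#' Simulate a multi-subject dual-tracer cohort
#'
#' Draws per-subject kinetic parameters around the tracer means,
#' generates reference and target TACs for every subject, tracer and
#' region from the SRTM forward model, adds frame-count noise, and
#' records the realized ground truth.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return An object of class `cohort_dataset`: list with `sets` (nested
#'   list `sets[[tracer]][[subject]]` of [regional_tac_set()]), `truth`
#'   (tibble subject x tracer x region with realized `R1`, `k2`,
#'   `bpnd`), and the generating `spec`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(if (is.null(seed)) spec$seed else as.integer(seed))
  n <- spec$n_subjects
  subjects <- sprintf("s%02d", seq_len(n))
  keys <- spec$keys

  # correlated standard normals for the 1+BP_ND copula
  cf <- chol(spec$bp_cor + diag(1e-10, length(keys)))
  zbp <- matrix(stats::rnorm(n * length(keys)), n) %*% cf
  colnames(zbp) <- keys

  truth <- list()
  sets <- list()
  for (tr in spec$tracers) {
    per_subj <- vector("list", n)
    for (i in seq_len(n)) {
      K1r <- lnorm_from_z(stats::rnorm(1), tr$K1_ref, spec$cv[["R1"]])
      k2r <- lnorm_from_z(stats::rnorm(1), tr$k2_ref, spec$cv[["k2"]])
      ref <- generate_reference_tac(tr$ifn, K1r, k2r, tr$schedule)
      # noisy references are measurements: add_noise drops the fine grid,
      # so downstream fits interpolate them like real data
      tacs <- list(reference = add_noise(ref, tr$noise_scale))
      for (j in seq_len(nrow(tr$regions))) {
        row <- tr$regions[j, ]
        key <- paste(tr$name, row$region, sep = ":")
        R1 <- lnorm_from_z(stats::rnorm(1), row$R1, spec$cv[["R1"]])
        k2 <- lnorm_from_z(stats::rnorm(1), row$k2, spec$cv[["k2"]])
        bp <- lnorm_from_z(zbp[i, key], 1 + row$bpnd, spec$cv[["bpnd"]]) - 1
        tt <- list(region = row$region, R1 = R1, k2 = k2, bpnd = bp)
        tacs[[row$region]] <- add_noise(
          generate_target_tac(ref, tt, tr$schedule), tr$noise_scale
        )
        truth[[length(truth) + 1L]] <- tibble::tibble(
          subject = subjects[i], tracer = tr$name, region = row$region,
          R1 = R1, k2 = k2, bpnd = bp
        )
      }
      per_subj[[i]] <- regional_tac_set(tacs, reference = "reference",
                                        subject = subjects[i],
                                        tracer = tr$name)
    }
    names(per_subj) <- subjects
    sets[[tr$name]] <- per_subj
  }
  structure(
    list(sets = sets, truth = do.call(rbind, truth), spec = spec),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects, tracers: %s\n",
              x$spec$n_subjects, paste(names(x$sets), collapse = ", ")))
  invisible(x)
}
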