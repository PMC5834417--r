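#' Fit every subject and region of a cohort
#'
#' Runs SRTM, reference Logan and/or SUVR over all regional TACs of a
#' simulated (or read-in) cohort and returns one tidy table of
#' estimates, the shape the sweep and correlation stages consume.
#'
#' @param cohort A [generate_cohort()] result.
#' @param methods Subset of `c("srtm", "logan", "suvr")`.
#' @param t_star Named list/vector of Logan equilibrium times per tracer
#'   (minutes), or a single number used for all tracers.
#' @param window Named list of SUVR windows `c(start, end)` per tracer,
#'   or a single window used for all.
#' @param ... SRTM basis settings (`theta_grid`, `dt`).
#' @return Tibble `subject`, `tracer`, `region`, `method`, `parameter`,
#'   `value` (parameters: `bpnd`, `R1`, `k2`, `int`, `r2`, `suvr`).
#' @export
fit_cohort <- function(cohort, methods = c("srtm", "logan", "suvr"),
                       t_star = NULL, window = NULL, ...) {
  stopifnot(all(methods %in% c("srtm", "logan", "suvr")))
  sets <- if (inherits(cohort, "cohort_dataset")) cohort$sets else cohort
  rows <- list()
  emit <- function(s, region, method, params) {
    for (p in names(params)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = s$subject, tracer = s$tracer, region = region,
        method = method, parameter = p, value = unname(params[[p]])
      )
    }
  }
  pick <- function(x, tracer, what) {
    if (is.null(x)) stop(sprintf("%s required for tracer '%s'", what, tracer))
    if (is.list(x) || (!is.null(names(x)) && tracer %in% names(x))) {
      if (tracer %in% names(x)) return(x[[tracer]])
      stop(sprintf("no %s given for tracer '%s'", what, tracer))
    }
    x
  }
  for (tr in names(sets)) {
    for (s in sets[[tr]]) {
      ref <- s$tacs[[s$reference]]
      if ("suvr" %in% methods) {
        sv <- compute_suvr(s, pick(window, tr, "window"))
        for (i in seq_len(nrow(sv))) {
          if (sv$region[i] == s$reference) next
          emit(s, sv$region[i], "suvr", list(suvr = sv$suvr[i]))
        }
      }
      basis <- if ("srtm" %in% methods) srtm_basis(ref, ...)
      for (nm in setdiff(names(s$tacs), s$reference)) {
        if ("srtm" %in% methods) {
          f <- srtm_fit_core(basis, s$tacs[[nm]]$values)
          emit(s, nm, "srtm", list(bpnd = f$bpnd, R1 = f$R1, k2 = f$k2))
        }
        if ("logan" %in% methods) {
          f <- fit_reference_logan(s$tacs[[nm]], ref, pick(t_star, tr, "t_star"))
          emit(s, nm, "logan", list(bpnd = f$bpnd, int = f$int, r2 = f$r2))
        }
      }
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Pull one parameter of one method as a tidy subject/region table
#'
#' @param fits A [fit_cohort()] table.
#' @param method,parameter Which estimate to extract.
#' @param tracer Optional tracer filter.
#' @return Tibble `subject`, `region`, `value` (regions prefixed
#'   `tracer:` when several tracers remain).
#' @export
fits_values <- function(fits, method, parameter, tracer = NULL) {
  d <- fits[fits$method == method & fits$parameter == parameter, ]
  if (!is.null(tracer)) d <- d[d$tracer == tracer, ]
  region <- if (length(unique(d$tracer)) > 1) {
    paste(d$tracer, d$region, sep = ":")
  } else {
    d$region
  }
  tibble::tibble(subject = d$subject, region = region, value = d$value)
}
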