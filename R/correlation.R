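#' Signed-R2 cross-regional correlation matrix
#'
#' For every pair of one region's values under measure A (e.g. amyloid
#' BP_ND) and one region's values under measure B (e.g. tau BP_ND),
#' computed across subjects, the cell holds `sign(r) * r^2` — the
#' signed coefficient of determination. Cells with `|signed R2|` below
#' `mask_threshold` are masked to `NA` in the display matrix for easier
#' interpretation; the raw values and per-cell correlation-test
#' p-values are kept alongside, so masking never destroys data.
#'
#' @param measure_a,measure_b Subject x region matrices (columns are
#'   regions, rows subjects) or tidy tibbles with columns `subject`,
#'   `region`, `value`.
#' @param mask_threshold Absolute signed-R2 mask level (default 0.3).
#' @param method `"pearson"` (default, matching the linear-regression
#'   framing) or `"spearman"`.
#' @param p_adjust Multiple-testing adjustment for the p-value matrix
#'   (default `"none"`, per-cell reporting; `"BH"` available).
#' @return An object of class `signed_r2_matrix`: `signed_r2` (raw),
#'   `masked` (below-threshold cells set `NA`), `p`, `n` (complete pairs
#'   per cell), `threshold`. Rows index measure-A regions, columns
#'   measure-B regions.
#' @export
signed_r2_matrix <- function(measure_a, measure_b, mask_threshold = 0.3,
                             method = c("pearson", "spearman"),
                             p_adjust = "none") {
  method <- match.arg(method)
  a <- values_matrix(measure_a)
  b <- values_matrix(measure_b)
  ra <- colnames(a)
  rb <- colnames(b)
  r2 <- p <- n <- matrix(NA_real_, length(ra), length(rb),
                         dimnames = list(ra, rb))
  for (i in seq_along(ra)) {
    for (j in seq_along(rb)) {
      va <- a[, i]
      vb <- b[, j]
      ok <- is.finite(va) & is.finite(vb)
      n[i, j] <- sum(ok)
      if (sum(ok) < 3) {
        warning(sprintf("fewer than 3 complete pairs for %s x %s; cell missing",
                        ra[i], rb[j]))
        next
      }
      if (stats::var(va[ok]) == 0 || stats::var(vb[ok]) == 0) {
        warning(sprintf("zero variance across subjects for %s x %s; cell missing",
                        ra[i], rb[j]))
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(va[ok], vb[ok], method = method)
      )
      r2[i, j] <- sign(ct$estimate) * ct$estimate^2
      p[i, j] <- ct$p.value
    }
  }
  if (p_adjust != "none") {
    p[] <- stats::p.adjust(p, method = p_adjust)
  }
  masked <- r2
  masked[!is.na(masked) & abs(masked) < mask_threshold] <- NA_real_
  structure(
    list(signed_r2 = r2, masked = masked, p = p, n = n,
         threshold = mask_threshold, method = method),
    class = "signed_r2_matrix"
  )
}

# subject x region value matrix from tidy or matrix input
values_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("region", seq_len(ncol(x)))
    return(x)
  }
  x <- as.data.frame(x)
  stopifnot(all(c("subject", "region", "value") %in% names(x)))
  subjects <- unique(x$subject)
  regions <- unique(x$region)
  m <- matrix(NA_real_, length(subjects), length(regions),
              dimnames = list(subjects, regions))
  m[cbind(match(x$subject, subjects), match(x$region, regions))] <- x$value
  m
}

#' @export
print.signed_r2_matrix <- function(x, ...) {
  cat(sprintf("<signed_r2_matrix> %dx%d cells, mask +/-%g (%s)\n",
              nrow(x$signed_r2), ncol(x$signed_r2), x$threshold, x$method))
  print(round(x$masked, 3))
  invisible(x)
}

#' Squared correlation between a regional measure and a covariate
#'
#' @param values Numeric vector of the regional outcome per subject.
#' @param covariate Numeric covariate per subject (e.g. a cognitive
#'   score).
#' @return Squared Pearson correlation (scalar in `[0, 1]`).
#' @export
covariate_r2 <- function(values, covariate) {
  stopifnot(length(values) == length(covariate))
  ok <- is.finite(values) & is.finite(covariate)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::var(covariate[ok]) == 0 || stats::var(values[ok]) == 0) {
    stop("zero variance: R2 undefined")
  }
  unname(stats::cor(values[ok], covariate[ok])^2)
}
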