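# Statistical layer for condition comparisons.
#
# Thin, contract-fixing wrappers around the standard R tests, so that
# every choice the analysis depends on (exact vs approximate Wilcoxon
# path, Yates correction, tie handling, bandwidth rule) is explicit
# and testable: Mann-Whitney-Wilcoxon rank-sum for pairwise feature
# comparisons, Yates-corrected 2x2 chi-square on positive-cell
# counts, one-way ANOVA of single-cell values across replicates, and
# dual-marker 2D Gaussian kernel density estimation. All p-values are
# two-sided; code keeps exact values, display uses a 2.2e-16 floor.

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' U statistic from midranks. The exact two-sided p-value (full
#' permutation null) is used when `n1 * n2 <= exact_cutoff` and there
#' are no ties; otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_cutoff Largest `n1 * n2` for the exact path.
#' @return List of class `two_sample_test`: `method`, `statistic` (U
#'   for `x`), `p_value`, `n1`, `n2`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_cutoff = 400) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= exact_cutoff
  res <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, conf.int = FALSE))
  structure(list(method = "Mann-Whitney-Wilcoxon rank-sum",
                 statistic = unname(res$statistic),
                 p_value = res$p.value,
                 n1 = length(x), n2 = length(y), exact = exact),
            class = "two_sample_test")
}

#' Yates-corrected 2x2 chi-square test on counts
#'
#' Pearson chi-square on the table `[[a, b], [c, d]]` (rows =
#' conditions, columns = positive/negative) with the continuity
#' correction `(|O - E| - min(0.5, |O - E|))^2 / E` when
#' `yates = TRUE`; df = 1.
#'
#' @param a,b,c,d Non-negative counts: treated positive/negative,
#'   control positive/negative.
#' @param yates Apply the Yates continuity correction (default TRUE)?
#' @return List of class `contingency_result`: `table`, `statistic`,
#'   `df`, `p_value`, `yates`.
#' @export
chi2_2x2 <- function(a, b, c, d, yates = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined: a table margin is zero",
         call. = FALSE)
  res <- suppressWarnings(chisq.test(tab, correct = yates))
  structure(list(table = tab, statistic = unname(res$statistic),
                 df = 1L, p_value = res$p.value, yates = yates),
            class = "contingency_result")
}

#' One-way ANOVA across groups
#'
#' Standard fixed-effects one-way ANOVA,
#' `F = (SSB / df_b) / (SSW / df_w)`, used here to test variability of
#' single-cell feature values between replicates within a treatment
#' group.
#'
#' @param groups List of >= 2 numeric samples, each with >= 2 values.
#' @return List of class `anova_result`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `group_n`, `degenerate` (TRUE when all
#'   values are identical so F is undefined).
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L))
    stop("every group needs >= 2 values", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  degenerate <- stats::var(values) == 0
  if (degenerate) {
    return(structure(list(f_statistic = NaN, df_between = length(groups) - 1L,
                          df_within = sum(sizes) - length(groups),
                          p_value = NA_real_, group_n = sizes,
                          degenerate = TRUE),
                     class = "anova_result"))
  }
  res <- oneway.test(values ~ g, var.equal = TRUE)
  structure(list(f_statistic = unname(res$statistic),
                 df_between = unname(res$parameter[1]),
                 df_within = unname(res$parameter[2]),
                 p_value = res$p.value, group_n = sizes,
                 degenerate = FALSE),
            class = "anova_result")
}

#' Dual-marker 2D kernel density estimate
#'
#' Product-Gaussian kernel density on a regular grid. Default
#' bandwidth: Scott's rule per axis, `sigma_hat * n^(-1/6)`. The grid
#' spans the data range plus `pad_bw` bandwidths on each side, so the
#' density integrates to ~1 over the grid.
#'
#' @param x,y Samples (same length, n >= 2, finite).
#' @param n_grid Grid points per axis.
#' @param bandwidth Optional `c(bx, by)` kernel SDs; required when an
#'   axis has zero variance.
#' @param lims Optional `c(xmin, xmax, ymin, ymax)`.
#' @param pad_bw Padding beyond the data range, in bandwidths.
#' @return List of class `kde2d_grid`: `x`, `y` (grid vectors), `z`
#'   (density matrix, x by y), `bandwidth`.
#' @export
kde2d_grid <- function(x, y, n_grid = 128L, bandwidth = NULL,
                       lims = NULL, pad_bw = 4) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need >= 2 finite (x, y) pairs", call. = FALSE)
  if (is.null(bandwidth)) {
    sx <- sd(x); sy <- sd(y)
    if (sx == 0 || sy == 0)
      stop("zero variance on one axis; supply `bandwidth` manually",
           call. = FALSE)
    n <- length(x)
    bandwidth <- c(sx, sy) * n^(-1 / 6)   # Scott's rule, 2D
  }
  if (any(bandwidth <= 0))
    stop("bandwidths must be > 0", call. = FALSE)
  if (is.null(lims))
    lims <- c(min(x) - pad_bw * bandwidth[1], max(x) + pad_bw * bandwidth[1],
              min(y) - pad_bw * bandwidth[2], max(y) + pad_bw * bandwidth[2])
  # MASS::kde2d's h is 4x the kernel SD
  k <- MASS::kde2d(x, y, h = 4 * bandwidth, n = n_grid, lims = lims)
  structure(list(x = k$x, y = k$y, z = k$z, bandwidth = bandwidth),
            class = "kde2d_grid")
}

#' Trapezoidal integral of a 2D density grid
#' @param grid A [kde2d_grid()] result.
#' @return Scalar integral (should be ~1 for a well-sized grid).
#' @export
kde2d_integral <- function(grid) {
  wx <- diff(grid$x); wy <- diff(grid$y)
  zx <- (grid$z[-1, , drop = FALSE] + grid$z[-nrow(grid$z), , drop = FALSE]) / 2
  z1 <- wx %*% zx
  sum((z1[, -1] + z1[, -length(z1)]) / 2 * wy)
}

#' Compare a treated condition against its control
#'
#' The composite per-marker analysis used for treatment-vs-control
#' reporting: Wilcoxon rank-sum on the marker feature, positivity
#' calling against the control-derived mean + 1 SD threshold,
#' Yates-corrected chi-square on the positive/negative counts, and
#' the dual-marker "diagonal shift" (signed difference of treated and
#' control medians for both marker features).
#'
#' @param control_records,treated_records Cell data frames with the
#'   marker feature columns.
#' @param thresholds Optional named list per marker of
#'   [compute_threshold()] results; computed from the control records
#'   when missing.
#' @return List of class `condition_comparison`: per marker
#'   `wilcoxon`, `threshold`, `positive_fraction_control`,
#'   `positive_fraction_treated`, `chi2`, `delta_median`; plus
#'   `n_control`, `n_treated`.
#' @export
compare_conditions <- function(control_records, treated_records,
                               thresholds = list()) {
  if (!nrow(control_records) || !nrow(treated_records))
    stop("both conditions must be non-empty", call. = FALSE)
  out <- list(n_control = nrow(control_records),
              n_treated = nrow(treated_records), markers = list())
  for (marker in MARKERS) {
    feat <- marker_feature(marker)
    vc <- control_records[[feat]]; vt <- treated_records[[feat]]
    if (is.null(vc) || is.null(vt)) next
    thr <- thresholds[[marker]]
    if (is.null(thr)) thr <- compute_threshold(vc, marker)
    pc <- classify_positive(control_records, thr, marker)$positive_fraction
    pt <- classify_positive(treated_records, thr, marker)$positive_fraction
    a <- round(pt * length(vt)); b <- length(vt) - a
    cc <- round(pc * length(vc)); d <- length(vc) - cc
    chi <- tryCatch(chi2_2x2(a, b, cc, d, yates = TRUE),
                    error = function(e) NULL)
    out$markers[[marker]] <- list(
      feature = feat,
      wilcoxon = wilcoxon_rank_sum(vt, vc),
      threshold = thr,
      positive_fraction_control = pc,
      positive_fraction_treated = pt,
      chi2 = chi,
      delta_median = median(vt) - median(vc))
  }
  structure(out, class = "condition_comparison")
}

# Display convention: exact values in code, 2.2e-16 floor in text.
format_p <- function(p) {
  if (is.na(p)) "NA"
  else if (p < 2.2e-16) "< 2.2e-16"
  else sprintf("%.3g", p)
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> control n = %d, treated n = %d\n",
              x$n_control, x$n_treated))
  for (marker in names(x$markers)) {
    m <- x$markers[[marker]]
    cat(sprintf(
      "  %s [%s]: Wilcoxon U = %.4g, p %s | positive %0.1f%% -> %0.1f%%",
      marker, m$feature, m$wilcoxon$statistic, format_p(m$wilcoxon$p_value),
      100 * m$positive_fraction_control, 100 * m$positive_fraction_treated))
    if (!is.null(m$chi2))
      cat(sprintf(" (X2 = %.4g, p %s)", m$chi2$statistic,
                  format_p(m$chi2$p_value)))
    cat(sprintf(" | delta median = %+.4g\n", m$delta_median))
  }
  invisible(x)
}
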