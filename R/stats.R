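# Paired nonparametric statistics: exact Wilcoxon signed-rank by full
# enumeration of sign assignments, Bonferroni adjustment, paired Cohen's d,
# and population DVH summaries.

#' Paired sample of per-patient measurements
#'
#' @param values_a,values_b Numeric vectors of equal length (>= 2), paired
#'   by patient.
#' @param labels Character vector of length 2 naming the two arms.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(values_a, values_b, labels = c("a", "b")) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2,
            is.numeric(values_a), is.numeric(values_b))
  structure(list(values_a = as.numeric(values_a),
                 values_b = as.numeric(values_b),
                 labels = labels),
            class = "paired_sample")
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's original exclusion rule) and
#' tied absolute differences are mid-ranked. For `mode = "exact"` (used
#' whenever n <= 15 under `"auto"`) the null distribution of the positive
#' rank sum is enumerated over all 2^n sign assignments, which remains
#' exact under ties; otherwise a normal approximation with continuity
#' correction and tie-corrected variance is used. The two-sided p value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param sample A `paired_sample`, or a numeric vector of differences.
#' @param mode `"auto"`, `"exact"` or `"normal-approx"`.
#' @return List with `p`, `statistic` (positive rank sum), `n_used`
#'   (pairs after dropping zeros) and `mode`.
#' @export
wilcoxon_signed_rank <- function(sample, mode = c("auto", "exact",
                                                  "normal-approx")) {
  mode <- match.arg(mode)
  d <- if (inherits(sample, "paired_sample"))
    sample$values_a - sample$values_b else as.numeric(sample)
  if (length(d) < 2) stop("need at least 2 pairs")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(p = 1.0, statistic = 0, n_used = 0L, mode = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 15) "exact" else "normal-approx"
  if (mode == "exact") {
    # distribution of W+ over all 2^n sign assignments
    signs <- matrix(FALSE, 2^n, n)
    for (j in seq_len(n))
      signs[, j] <- rep(c(FALSE, TRUE), each = 2^(j - 1),
                        length.out = 2^n)
    wall <- as.vector(signs %*% r)
    p_le <- mean(wall <= w + 1e-9)
    p_ge <- mean(wall >= w - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p = p, statistic = w, n_used = n, mode = mode)
}

#' Bonferroni adjustment
#'
#' @param p_raw Raw p value in (0, 1].
#' @param k Number of comparisons (default 3, the three treatment-approach
#'   pairs).
#' @return `min(1, k * p_raw)`.
#' @export
bonferroni <- function(p_raw, k = 3) {
  stopifnot(k >= 1, all(p_raw > 0), all(p_raw <= 1))
  pmin(1, k * p_raw)
}

#' Paired Cohen's d (d_z)
#'
#' `d_z = mean(differences) / sd(differences)` with the n-1 denominator in
#' the standard deviation. Undefined (NA, with a warning) when all
#' differences are equal.
#'
#' @param sample A `paired_sample`, or a numeric vector of differences.
#' @return Numeric scalar (possibly NA).
#' @export
cohens_d <- function(sample) {
  d <- if (inherits(sample, "paired_sample"))
    sample$values_a - sample$values_b else as.numeric(sample)
  if (length(d) < 2) stop("need at least 2 pairs")
  s <- stats::sd(d)
  if (s == 0) {
    warning("zero standard deviation of differences; Cohen's d undefined")
    return(NA_real_)
  }
  mean(d) / s
}

#' Population mean and SD DVH curves
#'
#' Rebins all DVHs onto the union bin range (same bin width) and returns
#' the pointwise mean and standard deviation of the cumulative volume
#' across patients.
#'
#' @param dvhs Nonempty list of `dvh` objects with a common bin width.
#' @return List with `bin_edges`, `mean`, `sd` (sd is 0 for a single
#'   patient).
#' @export
population_dvh <- function(dvhs) {
  if (length(dvhs) == 0) stop("empty DVH list")
  bw <- vapply(dvhs, function(d) d$bin_edges[2] - d$bin_edges[1], 0)
  if (max(abs(bw - bw[1])) > 1e-12) stop("DVHs have different bin widths")
  top <- max(vapply(dvhs, function(d) max(d$bin_edges), 0))
  edges <- seq(0, top, by = bw[1])
  curves <- vapply(dvhs, function(d) {
    v <- rep(0, length(edges))
    v[seq_along(d$cumulative_volume)] <- d$cumulative_volume
    v
  }, numeric(length(edges)))
  curves <- matrix(curves, nrow = length(edges))
  m <- rowMeans(curves)
  s <- if (ncol(curves) == 1) rep(0, length(edges))
  else apply(curves, 1, stats::sd)
  list(bin_edges = edges, mean = m, sd = s)
}
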