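#' Pearson correlation coefficient of two expression profiles
#'
#' The standard sample correlation
#' \deqn{r_{X,Y} = \frac{\sum_i (X_i - \bar X)(Y_i - \bar Y)}
#'   {\sqrt{\sum_i (X_i - \bar X)^2}\sqrt{\sum_i (Y_i - \bar Y)^2}}}
#' over the n samples. Measures only the linear component of coexpression;
#' contrast with [mi_adaptive()].
#'
#' @param x,y numeric vectors of equal length n >= 2, finite, each with
#'   nonzero variance.
#' @return r in \[-1, 1\].
#' @examples
#' pearson_r(c(0.1, 0.3, 0.5, 0.7, 0.9), c(0.3, 0.1, 0.5, 0.9, 0.7)) # 0.8
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    coexmi_error("coexmi_shape_mismatch_error", "x and y must have equal length")
  }
  if (length(x) < 2L) coexmi_error("coexmi_domain_error", "need n >= 2 samples")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    coexmi_error("coexmi_domain_error", "non-finite values in input")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    coexmi_error("coexmi_zero_variance_error",
                 "correlation undefined for a zero-variance profile")
  }
  stats::cor(x, y)
}

#' Discretize a profile into fixed-width intervals
#'
#' Divides `[range_low, range_high]` into `m` equal-width intervals
#' `A_1..A_m`; intervals are half-open `[lo, hi)` except the last, which is
#' closed on the right so the range is fully covered. Every value receives
#' exactly one interval label.
#'
#' @param values numeric vector, all within `[range_low, range_high]`.
#' @param m number of intervals, at least 2.
#' @param range_low,range_high interval range; defaults to the observed
#'   `range(values)`.
#' @return a `binning_scheme`: list with `m`, `boundaries` (m+1 increasing
#'   reals), `labels` (integer interval index in 1..m per value), `counts`
#'   (per-interval occupancy `k_i`), `n`, and `mode = "fixed"`.
#' @examples
#' b <- fixed_interval_bins(c(0.1, 0.3, 0.5, 0.7, 0.9), 5, 0, 1)
#' b$labels  # 1 2 3 4 5
#' @export
fixed_interval_bins <- function(values, m, range_low = min(values),
                                range_high = max(values)) {
  m <- as.integer(m)
  if (is.na(m) || m < 2L) coexmi_error("coexmi_domain_error", "need m >= 2 intervals")
  if (!(range_low < range_high)) {
    coexmi_error("coexmi_domain_error", "range_low must be < range_high")
  }
  if (any(values < range_low) || any(values > range_high)) {
    coexmi_error("coexmi_domain_error", "values outside the binning range")
  }
  width <- (range_high - range_low) / m
  labels <- pmin(as.integer(floor((values - range_low) / width)) + 1L, m)
  new_binning_scheme(m = m,
                     boundaries = range_low + width * (0:m),
                     labels = labels, n = length(values), mode = "fixed")
}

#' Discretize a profile into adaptive equal-frequency intervals
#'
#' Equal-frequency (quantile) partition: the value range is cut into `m`
#' non-overlapping intervals each holding approximately N/m data points, so
#' densely occupied regions get narrower intervals. This is the
#' discretization under which the plug-in MI estimator is far less biased
#' than fixed-width binning on skewed expression data.
#'
#' Interval boundaries sit at positions `ceil(i*N/m)` of the sorted values;
#' when a boundary would split a run of tied values the lower interval
#' absorbs the whole run, so equal values always share one interval and the
#' intervals remain genuine subintervals of the value range. Under heavy
#' ties some intervals may end up empty (they contribute nothing to the
#' entropy).
#'
#' @param values numeric vector with `length(values) >= m` and at least `m`
#'   distinct values.
#' @param m number of intervals (default 11, the configuration under which
#'   pairwise MI is capped by log2(11) ~ 3.46 bits).
#' @return a `binning_scheme` with `mode = "adaptive"`; see
#'   [fixed_interval_bins()].
#' @export
adaptive_bins <- function(values, m = 11L) {
  m <- as.integer(m)
  n <- length(values)
  if (is.na(m) || m < 2L) coexmi_error("coexmi_domain_error", "need m >= 2 intervals")
  if (n < m) {
    coexmi_error("coexmi_insufficient_samples_error",
                 sprintf("adaptive binning needs at least m = %d samples, got %d", m, n))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    coexmi_error("coexmi_domain_error", "non-finite values")
  }
  s <- sort(values)
  if (length(unique(s)) < m) {
    coexmi_error("coexmi_degenerate_input_error", sprintf(
      "fewer than m = %d distinct values; lower m or use fixed-width binning", m))
  }
  # cut positions in the sorted order, pushed right past any tie run
  pos <- ceiling(seq_len(m - 1L) * n / m)
  for (i in seq_along(pos)) {
    while (pos[i] < n && s[pos[i]] == s[pos[i] + 1L]) pos[i] <- pos[i] + 1L
  }
  # boundary values: midpoints between the last value of a bin and the next
  inner <- ifelse(pos < n, (s[pos] + s[pmin(pos + 1L, n)]) / 2, s[n])
  boundaries <- c(s[1L], inner, s[n])
  # label = 1 + number of cut positions at or below the value's sorted slot
  ord <- order(values)
  lab_sorted <- rep.int(seq_len(m), times = diff(c(0L, pos, n)))
  labels <- integer(n)
  labels[ord] <- lab_sorted
  new_binning_scheme(m = m, boundaries = boundaries, labels = labels,
                     n = n, mode = "adaptive")
}

#' @noRd
new_binning_scheme <- function(m, boundaries, labels, n, mode) {
  structure(list(m = m, boundaries = boundaries, labels = labels,
                 counts = tabulate(labels, nbins = m), n = n, mode = mode),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("binning_scheme (%s): %d intervals over [%g, %g], N = %d\n",
              x$mode, x$m, x$boundaries[1], x$boundaries[x$m + 1], x$n))
  cat("counts:", x$counts, "\n")
  invisible(x)
}

#' Shannon entropy of a discretized profile
#'
#' \deqn{H(X) = -\sum_i p(A_i) \log_2 p(A_i), \quad p(A_i) = k_i / N}
#' in bits, with the 0 log 0 = 0 convention (empty intervals contribute
#' nothing). H is 0 when one interval holds all points and reaches its
#' maximum log2(M) when all intervals are equally occupied.
#'
#' @param scheme a `binning_scheme` from [fixed_interval_bins()] or
#'   [adaptive_bins()].
#' @return entropy in bits, >= 0.
#' @export
entropy <- function(scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  -sum(xlog2x(scheme$counts / scheme$n))
}

#' Joint occupancy counts of two discretized profiles
#'
#' Counts `k_ij`: the number of samples whose X-value lies in interval i and
#' Y-value in interval j. Row sums recover X's per-interval counts and
#' column sums Y's; the grand total is N.
#'
#' @param scheme_x,scheme_y `binning_scheme`s built over the same samples in
#'   the same order.
#' @return a `joint_counts` object: integer matrix `m_x` x `m_y` with
#'   attribute `n`.
#' @export
joint_counts <- function(scheme_x, scheme_y) {
  stopifnot(inherits(scheme_x, "binning_scheme"), inherits(scheme_y, "binning_scheme"))
  if (scheme_x$n != scheme_y$n) {
    coexmi_error("coexmi_shape_mismatch_error",
                 "schemes were built over different numbers of samples")
  }
  k <- matrix(tabulate(scheme_x$labels + scheme_x$m * (scheme_y$labels - 1L),
                       nbins = scheme_x$m * scheme_y$m),
              nrow = scheme_x$m, ncol = scheme_y$m)
  structure(k, n = scheme_x$n, class = c("joint_counts", "matrix", "array"))
}

#' Mutual information of a joint count table
#'
#' Plug-in estimator, in bits:
#' \deqn{I(X,Y) = \log_2 N + \frac{1}{N}\sum_{ij} k_{ij}
#'   \log_2\frac{k_{ij}}{k_i k_j}}
#' which equals `H(X) + H(Y) - H(X,Y)` with relative-frequency
#' probabilities. Zero iff the table factorizes (discretized independence);
#' symmetric; bounded above by `min(log2 M_X, log2 M_Y)`. Values within
#' 1e-12 below zero (floating-point cancellation) are clamped to 0.
#'
#' @param table a `joint_counts` object (or an integer matrix of counts).
#' @return mutual information in bits, >= 0.
#' @examples
#' # a 5x5 permutation table of single counts: maximal MI log2(5)
#' b <- fixed_interval_bins(c(0.1, 0.3, 0.5, 0.7, 0.9), 5, 0, 1)
#' mutual_information(joint_counts(b, b))
#' @export
mutual_information <- function(table) {
  k <- unclass(table)
  n <- attr(table, "n") %||% sum(k)
  if (n < 1) coexmi_error("coexmi_domain_error", "empty joint table")
  ki <- rowSums(k)
  kj <- colSums(k)
  nz <- which(k > 0)
  i <- row(k)[nz]; j <- col(k)[nz]
  mi <- log2(n) + sum(k[nz] * log2(k[nz] / (ki[i] * kj[j]))) / n
  if (mi < 0 && mi > -1e-12) mi <- 0
  mi
}

#' Mutual information of two profiles under adaptive binning
#'
#' The package's production MI estimate for a probe pair: each profile is
#' discretized by [adaptive_bins()] with `m` intervals, the joint count
#' table is formed, and the plug-in MI computed. Result lies in
#' `[0, log2(m)]`.
#'
#' @param x,y numeric vectors of equal length N >= m.
#' @param m adaptive interval count (default 11).
#' @return mutual information in bits.
#' @export
mi_adaptive <- function(x, y, m = 11L) {
  if (length(x) != length(y)) {
    coexmi_error("coexmi_shape_mismatch_error", "x and y must have equal length")
  }
  mutual_information(joint_counts(adaptive_bins(x, m), adaptive_bins(y, m)))
}
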