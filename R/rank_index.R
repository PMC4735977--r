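#' Lookup table for (k/N) log2(k/N)
#'
#' Precomputes the N+1 values `(k/N) log2(k/N)` for `k = 0..N` (the k = 0 and
#' k = N entries are 0). Since every term of the plug-in MI sum is such a
#' value with integer k, all-pairs MI computation can look the terms up
#' instead of re-evaluating log2 — the time-saving device used for
#' database-scale all-pairs scans.
#'
#' @param n sample count N >= 1.
#' @return a `log_table`: list with `n` and `entries` (numeric length N+1;
#'   `entries[k + 1]` is the value for k).
#' @export
build_log_table <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) coexmi_error("coexmi_domain_error", "need N >= 1")
  k <- 0:n
  structure(list(n = n, entries = xlog2x(k / n)), class = "log_table")
}

#' Mutual information via the log lookup table
#'
#' Computes `H(X) + H(Y) - H(X,Y)` with every `(k/N) log2(k/N)` term taken
#' from a [build_log_table()] table. Matches [mutual_information()] to
#' 1e-12; exists so the equivalence is testable and so all-pairs scans can
#' share one table.
#'
#' @param table a `joint_counts` object.
#' @param log_table a `log_table` with `n` equal to the table's sample count.
#' @return mutual information in bits.
#' @export
mi_via_log_table <- function(table, log_table) {
  stopifnot(inherits(log_table, "log_table"))
  k <- unclass(table)
  n <- attr(table, "n") %||% sum(k)
  if (n != log_table$n) {
    coexmi_error("coexmi_shape_mismatch_error", "log table built for a different N")
  }
  e <- log_table$entries
  hx <- -sum(e[rowSums(k) + 1L])
  hy <- -sum(e[colSums(k) + 1L])
  hxy <- -sum(e[k + 1L])
  mi <- hx + hy - hxy
  if (mi < 0 && mi > -1e-12) mi <- 0
  mi
}

#' Create an empty compressed value histogram
#'
#' The memory-compression device behind percentile ranks: instead of storing
#' every pairwise value (order 10^8 for a 4x10^4-probe array), values are
#' counted into fixed-width bins. The MI histogram uses 35,000 bins of width
#' 1/10,000 over \[0, 3.5\] (the attainable MI range under 11 adaptive
#' intervals, capped by log2(11) ~ 3.46); the |r| histogram uses 10,000 bins
#' of the same width over \[0, 1\]. Bin j counts values in
#' `[(j-1)/10000, j/10000)`.
#'
#' @param measure `"mi"` or `"r"`; sets range and bin count.
#' @return a `value_histogram`: list with `measure`, `lo`, `hi`, `bin_width`,
#'   `counts` (all zero), `total`.
#' @seealso [hist_add()], [percentiles_from_histogram()]
#' @export
value_histogram <- function(measure = c("mi", "r")) {
  measure <- match.arg(measure)
  hi <- if (measure == "mi") 3.5 else 1.0
  nbins <- as.integer(round(hi * 10000))
  structure(list(measure = measure, lo = 0, hi = hi, bin_width = 1e-4,
                 counts = numeric(nbins), total = 0),
            class = "value_histogram")
}

#' Add a batch of values to a compressed histogram
#'
#' Single-pass accumulator: histograms are built by streaming batches of
#' pairwise values through `hist_add`, with memory proportional to the bin
#' count only. For the `"r"` histogram, correlations are ranked by
#' magnitude, so signed values are folded to `|r|` first. Values at or above
#' the top of the range are clamped into the last bin with a warning
#' (cannot occur for MI under 11 adaptive intervals).
#'
#' @param hist a [value_histogram()].
#' @param values numeric batch (MI values >= 0, or correlations in \[-1,1\]).
#' @return the updated histogram.
#' @export
hist_add <- function(hist, values) {
  stopifnot(inherits(hist, "value_histogram"))
  if (length(values) == 0) return(hist)
  if (anyNA(values)) coexmi_error("coexmi_domain_error", "NA values in stream")
  if (hist$measure == "r") {
    if (any(abs(values) > 1)) {
      coexmi_error("coexmi_domain_error", "|r| cannot exceed 1")
    }
    values <- abs(values)
  } else if (any(values < 0)) {
    coexmi_error("coexmi_domain_error", "negative MI values in stream")
  }
  nbins <- length(hist$counts)
  j <- floor(values / hist$bin_width) + 1
  if (any(j > nbins)) {
    warning(sprintf("%d value(s) at or above %g clamped to the last histogram bin",
                    sum(j > nbins), hist$hi))
    j <- pmin(j, nbins)
  }
  hist$counts <- hist$counts + tabulate(j, nbins = nbins)
  hist$total <- hist$total + length(values)
  hist
}

#' Percentile thresholds from a compressed histogram
#'
#' Produces the 101-entry vector `v_0..v_100`: `v_0` is the lower edge of
#' the first occupied bin (the minimum observed value at bin resolution) and
#' `v_i` for i >= 1 is the upper edge of the first bin at which the
#' cumulative count reaches `ceil(i * total / 100)` — so approximately 1% of
#' all values lies between consecutive thresholds, and locating a value
#' among the 101 thresholds replaces searching the full sorted list of all
#' pairwise values.
#'
#' @param hist a [value_histogram()] with at least 100 values.
#' @return a `percentile_vector`: numeric length 101 (names `v0..v100`) with
#'   attributes `measure` and `total`.
#' @export
percentiles_from_histogram <- function(hist) {
  stopifnot(inherits(hist, "value_histogram"))
  if (hist$total < 100) {
    coexmi_error("coexmi_insufficient_samples_error",
                 "need at least 100 values to build percentile thresholds")
  }
  percentile_thresholds(hist)
}

# Threshold construction without the >= 100 validation: tiny indexes (few
# probes) still get well-defined, if coarse, thresholds.
#' @noRd
percentile_thresholds <- function(hist) {
  if (hist$total < 1) {
    coexmi_error("coexmi_insufficient_samples_error", "empty histogram")
  }
  cum <- cumsum(hist$counts)
  upper <- hist$lo + seq_along(hist$counts) * hist$bin_width
  first_occ <- which(hist$counts > 0)[1]
  targets <- ceiling((1:100) * hist$total / 100)
  idx <- findInterval(targets - 1, cum) + 1  # first bin with cum >= target
  v <- c(hist$lo + (first_occ - 1) * hist$bin_width, upper[idx])
  structure(stats::setNames(v, paste0("v", 0:100)),
            measure = hist$measure, total = hist$total,
            class = "percentile_vector")
}

#' Percentile rank of a value among all pairwise values
#'
#' Returns the largest i with `v_i <= value`, clamped into \[1, 99\]: "i
#' percent of all values are smaller than this one", at 1-percent
#' resolution. Values below `v_0` report 1 and values at or above `v_100`
#' report 99 — extremes are never displayed as 0% or 100%.
#'
#' @param value the MI (or correlation; folded to `|r|` for an r-based
#'   vector) to rank.
#' @param pv a [percentiles_from_histogram()] result.
#' @return integer percent in 1..99.
#' @export
rank_percent <- function(value, pv) {
  stopifnot(inherits(pv, "percentile_vector"))
  if (identical(attr(pv, "measure"), "r")) value <- abs(value)
  i <- findInterval(value, unname(pv)) - 1L  # largest i with v_i <= value
  max(1L, min(99L, i))
}

#' Build a compressed MI histogram from a stream of pair values
#'
#' Convenience wrapper: an empty MI [value_histogram()] with one or more
#' batches streamed through [hist_add()].
#'
#' @param values numeric vector (or list of numeric batches) of pairwise MI
#'   values, each >= 0.
#' @return a `value_histogram`.
#' @export
build_mi_histogram <- function(values) {
  h <- value_histogram("mi")
  for (batch in if (is.list(values)) values else list(values)) h <- hist_add(h, batch)
  h
}

#' Build a compressed |r| histogram from a stream of pair correlations
#'
#' As [build_mi_histogram()] but over correlation magnitudes: ranks for r
#' are taken on `|r|` (a strongly negative and a strongly positive
#' correlation are equally extreme), with 10,000 bins of width 1/10,000 over
#' \[0, 1\].
#'
#' @param values numeric vector (or list of batches) of correlations in
#'   \[-1, 1\]; folded to magnitude internally.
#' @return a `value_histogram`.
#' @export
build_r_histogram <- function(values) {
  h <- value_histogram("r")
  for (batch in if (is.list(values)) values else list(values)) h <- hist_add(h, batch)
  h
}

#' Build the pairwise rank index of an expression matrix
#'
#' Scans all unordered probe pairs of a matrix once, computing each pair's
#' adaptive-binning MI and Pearson correlation, and accumulates both into
#' compressed histograms ([value_histogram()]) from which the percentile
#' vectors are derived. Probe labels are discretized once (each profile's
#' interval assignment is precomputed), and all MI terms are looked up in
#' the shared [build_log_table()] table; the scan keeps only O(bins) state
#' per measure, never the 0.5*P*(P-1) raw values.
#'
#' Probes whose profiles are degenerate (zero variance, or fewer distinct
#' values than intervals) are excluded from pairing with a message; their
#' pairs contribute nothing to the index.
#'
#' @param mat an [expression_matrix()].
#' @param m adaptive interval count (default 11).
#' @param chunk number of probes whose pair batch is accumulated per
#'   histogram update.
#' @return a `rank_index`: list with `mi_hist`, `r_hist`, `mi_pct`, `r_pct`
#'   (percentile vectors), `m`, `n_samples`, `n_probes`, `n_pairs`,
#'   `probe_ids` of the indexed probes, and `fingerprint` of the matrix.
#' @export
build_rank_index <- function(mat, m = 11L, chunk = 64L) {
  stopifnot(inherits(mat, "expression_matrix"))
  m <- as.integer(m)
  p_all <- nrow(mat)
  labels <- matrix(NA_integer_, p_all, ncol(mat))
  usable <- logical(p_all)
  for (i in seq_len(p_all)) {
    sc <- tryCatch(adaptive_bins(mat[i, ], m), coexmi_error = function(e) NULL)
    if (!is.null(sc) && stats::var(mat[i, ]) > 0) {
      labels[i, ] <- sc$labels
      usable[i] <- TRUE
    }
  }
  if (sum(usable) < 2L) {
    coexmi_error("coexmi_degenerate_input_error",
                 "fewer than two probes usable for pairwise indexing")
  }
  if (any(!usable)) {
    message(sprintf("excluding %d degenerate probe(s) from the index", sum(!usable)))
  }
  keep <- which(usable)
  lab <- labels[keep, , drop = FALSE]
  vals <- unclass(mat)[keep, , drop = FALSE]
  p <- length(keep)
  n <- ncol(vals)
  lt <- build_log_table(n)
  e <- lt$entries
  marg_h <- -apply(lab, 1L, function(l) sum(e[tabulate(l, m) + 1L]))
  mi_hist <- value_histogram("mi")
  r_hist <- value_histogram("r")
  xc <- t(scale(t(vals)))  # row-standardized for fast pairwise r
  buf_mi <- numeric(0); buf_r <- numeric(0)
  for (i in seq_len(p - 1L)) {
    js <- seq.int(i + 1L, p)
    code_i <- (lab[i, ] - 1L) * m
    mi_i <- vapply(js, function(j) {
      joint <- tabulate(code_i + lab[j, ], nbins = m * m)
      marg_h[i] + marg_h[j] + sum(e[joint + 1L])
    }, numeric(1))
    mi_i[mi_i < 0 & mi_i > -1e-12] <- 0
    r_i <- as.vector(xc[js, , drop = FALSE] %*% xc[i, ]) / (n - 1)
    buf_mi <- c(buf_mi, mi_i)
    buf_r <- c(buf_r, pmin(pmax(r_i, -1), 1))
    if (length(buf_mi) >= chunk * p || i == p - 1L) {
      mi_hist <- hist_add(mi_hist, buf_mi)
      r_hist <- hist_add(r_hist, buf_r)
      buf_mi <- numeric(0); buf_r <- numeric(0)
    }
  }
  structure(list(
    mi_hist = mi_hist, r_hist = r_hist,
    mi_pct = percentile_thresholds(mi_hist),
    r_pct = percentile_thresholds(r_hist),
    m = m, n_samples = n, n_probes = p, n_pairs = mi_hist$total,
    probe_ids = rownames(mat)[keep],
    fingerprint = matrix_fingerprint(mat)
  ), class = "rank_index")
}

# Cheap arithmetic fingerprint tying an index to the matrix it was built on.
#' @noRd
matrix_fingerprint <- function(mat) {
  v <- unclass(mat)
  sprintf("%dx%d:%.10e:%.10e", nrow(v), ncol(v), sum(v), sum(v * v))
}

#' @export
print.rank_index <- function(x, ...) {
  cat(sprintf("rank_index: %d probes x %d samples, %s pairs, M = %d adaptive intervals\n",
              x$n_probes, x$n_samples, format(x$n_pairs, big.mark = ","), x$m))
  invisible(x)
}

#' Number of unordered probe pairs
#'
#' `P(P-1)/2`, computed in closed form (no enumeration): the total count the
#' all-pairs histograms must conserve. For the 41,477 probe sets of a
#' full human expression array this is 860,150,026.
#'
#' @param p probe count.
#' @return pair count as a double (exact for p below ~9.4e7).
#' @export
n_probe_pairs <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) coexmi_error("coexmi_domain_error", "negative probe count")
  p * (p - 1) / 2
}

#' Histogram of rank differences RoMI - Ror
#'
#' For each probe pair, the difference between its MI percentile rank (RoMI)
#' and its correlation-magnitude percentile rank (Ror) summarizes whether
#' nonlinear dependency outruns linear correlation (positive), the reverse
#' (negative), or the two agree (zero). With ranks clamped to \[1, 99\] the
#' difference lies in \[-98, 98\]. The sum of all counts equals the number
#' of pairs scanned.
#'
#' @param mat an [expression_matrix()].
#' @param index a [build_rank_index()] result built on `mat`.
#' @return integer vector of counts named by difference -98..98.
#' @export
rank_difference_histogram <- function(mat, index) {
  stopifnot(inherits(index, "rank_index"))
  check_index_matrix(mat, index)
  ids <- index$probe_ids
  p <- length(ids)
  counts <- stats::setNames(integer(197), as.character(-98:98))
  for (i in seq_len(p - 1L)) {
    x <- mat[ids[i], ]
    for (j in seq.int(i + 1L, p)) {
      y <- mat[ids[j], ]
      d <- rank_percent(mi_adaptive(x, y, index$m), index$mi_pct) -
        rank_percent(pearson_r(x, y), index$r_pct)
      counts[as.character(d)] <- counts[as.character(d)] + 1L
    }
  }
  counts
}

#' @noRd
check_index_matrix <- function(mat, index) {
  if (!identical(index$fingerprint, matrix_fingerprint(mat))) {
    coexmi_error("coexmi_index_mismatch_error",
                 "index was built on a different matrix (fingerprint mismatch)")
  }
}

#' Write a rank index to a directory
#'
#' Serializes the histograms, percentile vectors and metadata as versioned
#' JSON (`index.json`) so an all-pairs scan need only run once per matrix.
#'
#' @param index a `rank_index`.
#' @param dir output directory (created if needed).
#' @return the path to `index.json`, invisibly.
#' @export
write_rank_index <- function(index, dir) {
  stopifnot(inherits(index, "rank_index"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "index.json")
  payload <- list(
    format = "coexmi-rank-index", version = 1L,
    m = index$m, n_samples = index$n_samples, n_probes = index$n_probes,
    n_pairs = index$n_pairs, probe_ids = index$probe_ids,
    fingerprint = index$fingerprint,
    mi_hist = index$mi_hist[c("measure", "lo", "hi", "bin_width", "counts", "total")],
    r_hist = index$r_hist[c("measure", "lo", "hi", "bin_width", "counts", "total")],
    mi_pct = as.numeric(index$mi_pct), r_pct = as.numeric(index$r_pct)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rank index written by [write_rank_index()]
#'
#' @param dir directory containing `index.json`.
#' @return a `rank_index`.
#' @export
read_rank_index <- function(dir) {
  path <- file.path(dir, "index.json")
  if (!file.exists(path)) coexmi_error("coexmi_io_error", sprintf("no index at %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "coexmi-rank-index")) {
    coexmi_error("coexmi_parse_error", "not a coexmi rank index")
  }
  rebuild_hist <- function(h) {
    structure(list(measure = h$measure, lo = h$lo, hi = h$hi,
                   bin_width = h$bin_width, counts = as.numeric(h$counts),
                   total = h$total), class = "value_histogram")
  }
  mk_pct <- function(v, measure, total) {
    if (is.null(v) || !length(v)) return(NULL)
    structure(stats::setNames(as.numeric(v), paste0("v", 0:100)),
              measure = measure, total = total, class = "percentile_vector")
  }
  structure(list(
    mi_hist = rebuild_hist(p$mi_hist), r_hist = rebuild_hist(p$r_hist),
    mi_pct = mk_pct(p$mi_pct, "mi", p$n_pairs),
    r_pct = mk_pct(p$r_pct, "r", p$n_pairs),
    m = as.integer(p$m), n_samples = as.integer(p$n_samples),
    n_probes = as.integer(p$n_probes), n_pairs = as.numeric(p$n_pairs),
    probe_ids = as.character(p$probe_ids), fingerprint = p$fingerprint
  ), class = "rank_index")
}
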