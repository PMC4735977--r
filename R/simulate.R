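#' Simulate a pair of expression profiles with controlled dependency
#'
#' Generates two length-`n` nonnegative expression vectors whose dependency
#' structure is one of four kinds:
#'
#' * `"linear"` — `y = a*x + epsilon`: the textbook case Pearson r detects.
#' * `"monotone_nonlinear"` — `y = x^2 + epsilon`: monotone but curved, so
#'   r underestimates the (perfect, noiseless) dependency.
#' * `"permuted_dependency"` — y is a deterministic bijection of x's rank
#'   arranged so the linear trend vanishes: ranks are split into
#'   `blocks` contiguous blocks, the blocks are rearranged by a permutation
#'   whose rank correlation is driven to ~0, and order is preserved within
#'   blocks. The map is bijective, so mutual information stays near its
#'   discretization cap while r collapses to ~0 — the regime where MI
#'   detects what r misses. With `n <= blocks` every block is a single
#'   point and the pair is a pure permutation scatter.
#' * `"independent"` — x and y drawn independently (null pair).
#'
#' For `linear`, `monotone_nonlinear` and `independent`, x is uniform on
#' \[0, 1\]; for `permuted_dependency` x is the evenly spaced grid
#' `(i - 0.5)/n` in shuffled order, so that the value correlation equals the
#' rank correlation of the constructed permutation. Both MI (rank-based
#' binning) and |r| are invariant to this choice of marginal scale. Noise is
#' Gaussian with standard deviation `noise_sd`, and outputs are clamped at 0
#' to respect nonnegative signal intensities.
#'
#' @param kind one of `"linear"`, `"monotone_nonlinear"`,
#'   `"permuted_dependency"`, `"independent"`.
#' @param n number of samples, at least 5.
#' @param noise_sd Gaussian noise standard deviation on y (default 0.1,
#'   i.e. 10% of the unit signal range).
#' @param seed integer seed; equal seeds give identical pairs.
#' @param blocks block count for `"permuted_dependency"` (default 11,
#'   matching the default adaptive bin count so each block lands in about
#'   one bin).
#' @return list with numeric vectors `x` and `y` of length `n`.
#' @examples
#' p <- simulate_pair("permuted_dependency", n = 5, noise_sd = 0, seed = 1)
#' round(stats::cor(p$x, p$y), 10)   # ~0 despite y being a bijection of x
#' @export
simulate_pair <- function(kind = c("linear", "monotone_nonlinear",
                                   "permuted_dependency", "independent"),
                          n, noise_sd = 0.1, seed = 1L, blocks = 11L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 5L) {
    coexmi_error("coexmi_domain_error", "simulate_pair requires n >= 5")
  }
  if (noise_sd < 0) coexmi_error("coexmi_domain_error", "noise_sd must be >= 0")
  with_seed(seed, {
    if (kind == "permuted_dependency") {
      grid <- (seq_len(n) - 0.5) / n
      x <- sample(grid)
      perm <- zero_cor_block_permutation(n, min(as.integer(blocks), n))
      y <- grid[perm[rank(x, ties.method = "first")]]
    } else {
      x <- stats::runif(n)
      y <- switch(kind,
        linear = x,
        monotone_nonlinear = x^2,
        independent = stats::runif(n))
    }
    if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
    list(x = x, y = pmax(y, 0))
  })
}

# Permutation q of 1..n with near-zero rank correlation, built blockwise:
# ranks are cut into `blocks` contiguous runs; run j is moved, order
# preserved, into slot p[j] where the block-level permutation p has its
# sum(i * p_i) pushed to the zero-correlation target by swap search.
# Bijective by construction; the residual correlation is the O(1/blocks^2)
# within-run trend.
#' @noRd
zero_cor_block_permutation <- function(n, blocks) {
  b <- max(2L, min(blocks, n))
  p <- swap_to_zero_cor(sample(b))       # block j occupies slot p[j]
  edges <- floor(seq(0, n, length.out = b + 1))
  sizes <- diff(edges)
  blk_in_slot <- order(p)                # block sitting in slot s
  slot_starts <- cumsum(c(0L, sizes[blk_in_slot][-b]))
  q <- integer(n)
  for (j in seq_len(b)) {
    rs <- seq.int(edges[j] + 1L, edges[j + 1L])
    q[rs] <- slot_starts[p[j]] + seq_along(rs)
  }
  refine_within_blocks(q, edges)
}

# Cancel the residual within-block linear trend by swapping positions that
# share a block: such swaps leave every block's membership (hence the
# coarse joint structure and MI) untouched while steering sum(i * q_i) to
# the zero-correlation target.
#' @noRd
refine_within_blocks <- function(q, edges, iters = 600L, cand = 400L) {
  n <- length(q)
  b <- length(edges) - 1L
  sizes <- diff(edges)
  if (all(sizes <= 1L)) return(q)
  target <- n * (n + 1)^2 / 4
  s <- sum(seq_len(n) * q)
  for (it in seq_len(iters)) {
    d <- target - s
    if (abs(d) < 1) break
    blk <- sample.int(b, cand, replace = TRUE)
    i <- edges[blk] + 1L + floor(stats::runif(cand) * sizes[blk])
    j <- edges[blk] + 1L + floor(stats::runif(cand) * sizes[blk])
    delta <- (i - j) * (q[j] - q[i])
    best <- which.min(abs(s + delta - target))
    if (abs(s + delta[best] - target) >= abs(d)) next
    ii <- i[best]; jj <- j[best]
    tmp <- q[ii]; q[ii] <- q[jj]; q[jj] <- tmp
    s <- s + delta[best]
  }
  q
}

# sum(i*p) == n(n+1)^2/4 gives exactly zero Pearson correlation of ranks;
# greedy swap descent with random restarts (the greedy can stall one unit
# short from some starting permutations).
#' @noRd
swap_to_zero_cor <- function(p) {
  n <- length(p)
  target <- n * (n + 1)^2 / 4
  best <- p
  best_d <- abs(sum(seq_len(n) * p) - target)
  for (restart in seq_len(25L)) {
    q <- greedy_swaps(if (restart == 1L) p else sample(n), target)
    d <- abs(sum(seq_len(n) * q) - target)
    if (d < best_d) {
      best <- q
      best_d <- d
    }
    if (best_d < 1) break
  }
  best
}

#' @noRd
greedy_swaps <- function(p, target) {
  n <- length(p)
  s <- sum(seq_len(n) * p)
  for (iter in seq_len(200L)) {
    d <- target - s
    if (abs(d) < 1) break
    idx <- if (n <= 60L) {
      as.matrix(expand.grid(i = seq_len(n), j = seq_len(n)))
    } else {
      cbind(i = sample(n, 2000L, replace = TRUE), j = sample(n, 2000L, replace = TRUE))
    }
    delta <- (idx[, 1] - idx[, 2]) * (p[idx[, 2]] - p[idx[, 1]])
    best <- which.min(abs(s + delta - target))
    if (abs(s + delta[best] - target) >= abs(d)) next
    i <- idx[best, 1]; j <- idx[best, 2]
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    s <- s + delta[best]
  }
  p
}

#' Simulate a full expression matrix
#'
#' Builds a P x n [expression_matrix()] of independent null probes, then
#' overwrites pairs of probes with planted dependent pairs from
#' [simulate_pair()]. This emulates the structure of a cell-type-specific
#' expression compendium: a large background of unrelated profiles in which
#' a few pairs carry genuine linear or nonlinear coexpression.
#'
#' @param probes number of probe sets P (>= 2).
#' @param n number of samples.
#' @param seed integer seed.
#' @param planted character vector of dependency kinds (see
#'   [simulate_pair()]); each plants one probe pair at the front of the
#'   matrix, in order (probes 1-2, 3-4, ...).
#' @param noise_sd noise level passed to [simulate_pair()].
#' @param cell_type label attached to the matrix.
#' @return an [expression_matrix()] with probe IDs `probe_0001_at`, ... and an
#'   attribute `planted_pairs`: a data.frame of (probe_a, probe_b, kind).
#' @export
simulate_matrix <- function(probes, n, seed = 1L, planted = character(),
                            noise_sd = 0.1, cell_type = "synthetic") {
  probes <- as.integer(probes)
  if (probes < 2L) coexmi_error("coexmi_domain_error", "need at least 2 probes")
  if (2L * length(planted) > probes) {
    coexmi_error("coexmi_domain_error", "too many planted pairs for the probe count")
  }
  vals <- with_seed(seed, matrix(stats::runif(probes * n), probes, n))
  planted_df <- NULL
  if (length(planted)) {
    rows <- list()
    for (i in seq_along(planted)) {
      pr <- simulate_pair(planted[i], n = n, noise_sd = noise_sd,
                          seed = seed + 1000L * i)
      a <- 2L * i - 1L; b <- 2L * i
      vals[a, ] <- pr$x
      vals[b, ] <- pr$y
      rows[[i]] <- data.frame(probe_a = sprintf("probe_%04d_at", a),
                              probe_b = sprintf("probe_%04d_at", b),
                              kind = planted[i], stringsAsFactors = FALSE)
    }
    planted_df <- do.call(rbind, rows)
  }
  m <- expression_matrix(vals,
                         probe_ids = sprintf("probe_%04d_at", seq_len(probes)),
                         sample_ids = sprintf("sample_%04d", seq_len(n)),
                         cell_type = cell_type)
  attr(m, "planted_pairs") <- planted_df
  m
}

# Run code under a private RNG stream, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
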