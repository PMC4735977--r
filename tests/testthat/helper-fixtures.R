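# Five-point worked datasets: identical point sets, rearranged pairing.
# fig_linearish has a strong linear trend; fig_permuted pairs the same x
# and y values through a different bijection that kills the linear trend.
fig_x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
fig_y_linearish <- c(0.3, 0.1, 0.5, 0.9, 0.7)
fig_y_permuted <- c(0.3, 0.9, 0.5, 0.1, 0.7)

five_point_matrix <- function(y) {
  expression_matrix(rbind(fig_x, y),
                    probe_ids = c("probe_x_at", "probe_y_at"),
                    sample_ids = paste0("s", 1:5))
}

# Independent plug-in MI oracle: direct -sum(p log2 p) over occupied cells
# of plain contingency tables, no package code in the computation.
oracle_mi <- function(labels_x, labels_y) {
  n <- length(labels_x)
  h <- function(tab) {
    p <- as.numeric(tab[tab > 0]) / n
    -sum(p * log2(p))
  }
  h(table(labels_x)) + h(table(labels_y)) - h(table(labels_x, labels_y))
}

# Exact percentile oracle from a full sort: percent of values smaller.
oracle_rank_percent <- function(value, values) {
  max(1L, min(99L, as.integer(floor(100 * sum(values < value) / length(values)))))
}

with_seed_values <- function(n, seed) {
  set.seed(seed)
  runif(n)
}

# joint entropy straight from the count table, independent of entropy()
joint_entropy_direct <- function(tab) {
  n <- attr(tab, "n")
  p <- as.numeric(tab[tab > 0]) / n
  -sum(p * log2(p))
}

tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
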