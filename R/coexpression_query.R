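#' Hybrid linear/nonlinear coexpression score
#'
#' For a query probe i and candidate j,
#' \deqn{MIr = \beta \frac{r_{ij}}{\max_{k \ne i} r_{ik}} +
#'   (1-\beta) \frac{MI_{ij}}{\max_{k \ne i} MI_{ik}}}
#' blends the linear (Pearson) and general-dependency (MI) views, each
#' normalized by its maximum over the query's candidates so the two
#' otherwise incomparable scales can be mixed. `beta = 1` reduces to the
#' normalized correlation, `beta = 0` to the normalized MI; the default 0.5
#' weighs them equally. By default the literal signed r enters the ratio;
#' `abs_r = TRUE` switches both numerator and maximum to magnitudes for
#' consistency with |r|-based ranking.
#'
#' @param r_aj candidate's Pearson correlation with the query.
#' @param mi_aj candidate's mutual information with the query (bits).
#' @param max_r,max_mi maxima of the respective measure over all candidates
#'   k != i of the query probe; both must be positive.
#' @param beta mixing weight in \[0, 1\] (default 0.5).
#' @param abs_r use `|r|` instead of signed r.
#' @return the hybrid score (1 when the candidate attains both maxima).
#' @export
mir_score <- function(r_aj, mi_aj, max_r, max_mi, beta = 0.5, abs_r = FALSE) {
  if (beta < 0 || beta > 1) coexmi_error("coexmi_domain_error", "beta must be in [0, 1]")
  if (abs_r) {
    r_aj <- abs(r_aj); max_r <- abs(max_r)
  }
  if (max_r <= 0 || max_mi <= 0) {
    coexmi_error("coexmi_undefined_score_error",
                 "hybrid score undefined: candidate maxima must be positive")
  }
  beta * r_aj / max_r + (1 - beta) * mi_aj / max_mi
}

#' Detection-call co-occurrence rates of two probes
#'
#' Fractions of samples, out of all samples, in which the two probes'
#' detection calls fall in each present/absent combination: `pp` (both
#' present), `aa` (both absent), `pa` (first present, second absent), `ap`
#' (the reverse). Samples where either call is marginal (`M`) are counted in
#' none of the four. A high `aa` with `pp` near zero flags pairs whose large
#' Pearson r is an artifact of shared non-expression rather than genuine
#' linear coexpression.
#'
#' @param calls_a,calls_b character vectors of equal length with entries
#'   `P`/`A`/`M`.
#' @return named list `pp`, `aa`, `pa`, `ap`, `marginal` (fraction excluded)
#'   and `total_coexpression` (`pp + aa`, the composite rate reported
#'   alongside its parts).
#' @export
cooccurrence_rates <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    coexmi_error("coexmi_shape_mismatch_error", "call vectors differ in length")
  }
  if (!all(c(calls_a, calls_b) %in% c("P", "A", "M"))) {
    coexmi_error("coexmi_parse_error", "calls must be P, A or M")
  }
  n <- length(calls_a)
  pp <- sum(calls_a == "P" & calls_b == "P") / n
  aa <- sum(calls_a == "A" & calls_b == "A") / n
  pa <- sum(calls_a == "P" & calls_b == "A") / n
  ap <- sum(calls_a == "A" & calls_b == "P") / n
  list(pp = pp, aa = aa, pa = pa, ap = ap,
       marginal = sum(calls_a == "M" | calls_b == "M") / n,
       total_coexpression = pp + aa)
}

#' Full coexpression report for one probe pair
#'
#' Computes everything a pairwise query displays: Pearson r, adaptive MI,
#' their percentile ranks RoMI and Ror against a prebuilt all-pairs index,
#' the hybrid MIr score (normalized over probe_a's candidates), and — when a
#' detection-call matrix is supplied — the P/A co-occurrence rates. The rank
#' comparison encodes the four diagnostic regimes: both ranks high (strong
#' linear and nonlinear coexpression), RoMI high / Ror low (dependency that
#' r misses), both low (unrelated), RoMI low / Ror high (r inflated, e.g.
#' by shared absence).
#'
#' @param mat an [expression_matrix()].
#' @param probe_a,probe_b probe IDs present in `mat`.
#' @param index a [build_rank_index()] result built on `mat` (fingerprint
#'   checked).
#' @param calls optional `detection_calls` matrix matching `mat`.
#' @param beta hybrid-score weight (default 0.5).
#' @return a `pair_correlation`: list with `probe_a`, `probe_b`, `r`, `mi`,
#'   `ro_mi`, `ro_r`, `rank_difference`, `mir`, `rates` (or NULL).
#' @export
pair_report <- function(mat, probe_a, probe_b, index, calls = NULL, beta = 0.5) {
  stopifnot(inherits(mat, "expression_matrix"), inherits(index, "rank_index"))
  check_index_matrix(mat, index)
  for (pr in c(probe_a, probe_b)) {
    if (!pr %in% rownames(mat)) {
      coexmi_error("coexmi_unknown_probe_error", sprintf("unknown probe ID: %s", pr))
    }
  }
  if (probe_a == probe_b) {
    coexmi_error("coexmi_domain_error", "self-pairs are undefined (candidates exclude the query)")
  }
  x <- mat[probe_a, ]; y <- mat[probe_b, ]
  r <- pearson_r(x, y)
  mi <- mi_adaptive(x, y, index$m)
  scores <- candidate_scores(mat, probe_a, index$m)
  mir <- mir_score(r, mi, max(scores$r), max(scores$mi), beta = beta)
  rates <- if (!is.null(calls)) cooccurrence_rates(calls[probe_a, ], calls[probe_b, ])
  ro_mi <- rank_percent(mi, index$mi_pct)
  ro_r <- rank_percent(r, index$r_pct)
  structure(list(probe_a = probe_a, probe_b = probe_b, r = r, mi = mi,
                 ro_mi = ro_mi, ro_r = ro_r,
                 rank_difference = ro_mi - ro_r, mir = mir,
                 beta = beta, rates = rates),
            class = "pair_correlation")
}

#' @export
print.pair_correlation <- function(x, ...) {
  cat(sprintf("pair %s ~ %s\n", x$probe_a, x$probe_b))
  cat(sprintf("  r   = %.5f  (Ror  = %d%%)\n", x$r, x$ro_r))
  cat(sprintf("  MI  = %.5f  (RoMI = %d%%)\n", x$mi, x$ro_mi))
  cat(sprintf("  MIr = %.5f  (beta = %.2f)   RoMI - Ror = %+d\n",
              x$mir, x$beta, x$rank_difference))
  if (!is.null(x$rates)) {
    cat(sprintf("  calls: PP = %.2f%%  AA = %.2f%%  PA = %.2f%%  AP = %.2f%%  (PP+AA = %.2f%%)\n",
                100 * x$rates$pp, 100 * x$rates$aa, 100 * x$rates$pa,
                100 * x$rates$ap, 100 * x$rates$total_coexpression))
  }
  invisible(x)
}

# r and adaptive MI of every candidate k != query; shared by pair_report
# and top_related.
#' @noRd
candidate_scores <- function(mat, probe, m) {
  ids <- setdiff(rownames(mat), probe)
  x <- mat[probe, ]
  bx <- adaptive_bins(x, m)
  r <- vapply(ids, function(id) pearson_r(x, mat[id, ]), numeric(1))
  mi <- vapply(ids, function(id) {
    mutual_information(joint_counts(bx, adaptive_bins(mat[id, ], m)))
  }, numeric(1))
  list(ids = ids, r = r, mi = mi)
}

#' Top-k related probes by MI, r, and the hybrid score
#'
#' Scores every candidate probe against the query and returns the k
#' strongest under each of the three perspectives: mutual information
#' (general dependency), Pearson r (linear), and the MIr hybrid. Lists are
#' sorted by descending score with deterministic lexicographic probe-ID
#' tie-breaks; the query itself is never a candidate.
#'
#' @param mat an [expression_matrix()].
#' @param probe query probe ID.
#' @param k list length (default 10; truncated to P-1).
#' @param beta hybrid weight (default 0.5).
#' @param m adaptive interval count (default 11).
#' @param annotation optional named character vector mapping probe IDs to
#'   gene symbols (see [read_probe_annotation()]).
#' @return a `related_gene_list`: list of three data.frames `by_mi`, `by_r`,
#'   `by_mir`, each with columns `probe_id`, `gene_symbol`, `score`.
#' @export
top_related <- function(mat, probe, k = 10L, beta = 0.5, m = 11L,
                        annotation = NULL) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!probe %in% rownames(mat)) {
    coexmi_error("coexmi_unknown_probe_error", sprintf("unknown probe ID: %s", probe))
  }
  sc <- candidate_scores(mat, probe, m)
  mir <- mir_score(sc$r, sc$mi, max(sc$r), max(sc$mi), beta = beta)
  k <- min(as.integer(k), length(sc$ids))
  pick <- function(score) {
    ord <- order(-score, sc$ids)[seq_len(k)]
    data.frame(probe_id = sc$ids[ord],
               gene_symbol = if (is.null(annotation)) NA_character_
                             else unname(annotation[sc$ids[ord]]),
               score = unname(score[ord]), stringsAsFactors = FALSE)
  }
  structure(list(query = probe, k = k, beta = beta,
                 by_mi = pick(sc$mi), by_r = pick(sc$r), by_mir = pick(mir)),
            class = "related_gene_list")
}

#' @export
print.related_gene_list <- function(x, ...) {
  cat(sprintf("top %d probes related to %s (beta = %.2f)\n", x$k, x$query, x$beta))
  for (nm in c("by_mi", "by_r", "by_mir")) {
    cat(sprintf("-- %s --\n", sub("by_", "", nm)))
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Export the scatter data of a probe pair
#'
#' Writes the two profiles side by side as TSV (`sample_id`, then one column
#' per probe, query first) — the data behind the two-dimensional scatter
#' plot a pairwise query displays.
#'
#' @param mat an [expression_matrix()].
#' @param probe_a,probe_b probe IDs.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
scatter_export <- function(mat, probe_a, probe_b, path) {
  stopifnot(inherits(mat, "expression_matrix"))
  for (pr in c(probe_a, probe_b)) {
    if (!pr %in% rownames(mat)) {
      coexmi_error("coexmi_unknown_probe_error", sprintf("unknown probe ID: %s", pr))
    }
  }
  dt <- data.table::data.table(sample_id = colnames(mat))
  dt[[probe_a]] <- unname(mat[probe_a, ])
  dt[[probe_b]] <- unname(mat[probe_b, ])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
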