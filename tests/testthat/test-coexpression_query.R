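test_that("the hybrid score blends normalized r and MI as specified", {
  expect_equal(mir_score(0.4, 1.2, 0.8, 2.4, beta = 1), 0.5)     # pure r view
  expect_equal(mir_score(0.4, 1.2, 0.8, 2.4, beta = 0), 0.5)     # pure MI view
  expect_equal(mir_score(0.8, 2.4, 0.8, 2.4, beta = 0.37), 1.0)  # attains both maxima
  # monotone in both arguments for interior beta
  base <- mir_score(0.3, 1.0, 0.9, 3.0, beta = 0.5)
  expect_gt(mir_score(0.4, 1.0, 0.9, 3.0, beta = 0.5), base)
  expect_gt(mir_score(0.3, 1.5, 0.9, 3.0, beta = 0.5), base)
  # |r| option folds the sign
  expect_equal(mir_score(-0.5, 1, 0.5, 2, beta = 0.5, abs_r = TRUE),
               mir_score(0.5, 1, 0.5, 2, beta = 0.5))
  expect_error(mir_score(0.1, 1, 0, 2), class = "coexmi_undefined_score_error")
  expect_error(mir_score(0.1, 1, 0.5, 2, beta = 1.4), class = "coexmi_domain_error")
})

test_that("detection-call co-occurrence rates count P/A combinations only", {
  r <- cooccurrence_rates(c("P", "P", "A", "A"), c("P", "A", "P", "A"))
  expect_equal(unlist(r[c("pp", "pa", "ap", "aa")]), c(pp = .25, pa = .25, ap = .25, aa = .25))
  expect_equal(r$total_coexpression, 0.5)

  all_p <- cooccurrence_rates(rep("P", 6), rep("P", 6))
  expect_equal(all_p$pp, 1.0)
  expect_equal(all_p$aa + all_p$pa + all_p$ap, 0)

  marg <- cooccurrence_rates(rep("M", 5), c("P", "A", "P", "A", "M"))
  expect_equal(marg$pp + marg$aa + marg$pa + marg$ap, 0)
  expect_equal(marg$marginal, 1.0)

  # rates partition the samples; probe swap exchanges pa and ap
  set.seed(79)
  a <- sample(c("P", "A", "M"), 60, replace = TRUE, prob = c(.3, .6, .1))
  b <- sample(c("P", "A", "M"), 60, replace = TRUE, prob = c(.2, .7, .1))
  ab <- cooccurrence_rates(a, b); ba <- cooccurrence_rates(b, a)
  expect_equal(ab$pp + ab$aa + ab$pa + ab$ap + ab$marginal, 1.0)
  expect_equal(ab$pa, ba$ap)
  expect_equal(ab$pp, ba$pp)
  expect_error(cooccurrence_rates(a, b[-1]), class = "coexmi_shape_mismatch_error")
})

test_that("pair_report assembles r, MI, ranks, hybrid score and rates", {
  m <- simulate_matrix(30, 150, seed = 83, planted = c("linear", "permuted_dependency"))
  idx <- build_rank_index(m)
  rep1 <- pair_report(m, "probe_0001_at", "probe_0002_at", idx)
  expect_equal(rep1$r, pearson_r(m["probe_0001_at", ], m["probe_0002_at", ]))
  expect_equal(rep1$mi, mi_adaptive(m["probe_0001_at", ], m["probe_0002_at", ]))
  expect_gte(rep1$ro_mi, 95); expect_gte(rep1$ro_r, 95)
  expect_equal(rep1$rank_difference, rep1$ro_mi - rep1$ro_r)
  expect_gt(rep1$mir, 0.9)  # the planted linear partner dominates both views

  calls <- matrix("P", 30, 150, dimnames = dimnames(unclass(m)))
  calls[2, 1:30] <- "A"
  rep2 <- pair_report(m, "probe_0001_at", "probe_0002_at", idx, calls = calls)
  expect_equal(rep2$rates$pp, 120 / 150)
  expect_equal(rep2$rates$pa, 30 / 150)

  expect_error(pair_report(m, "probe_0001_at", "nope_at", idx),
               class = "coexmi_unknown_probe_error")
  expect_error(pair_report(m, "probe_0001_at", "probe_0001_at", idx),
               class = "coexmi_domain_error")
})

test_that("planted dependency kinds reproduce the four rank-comparison regimes", {
  m <- simulate_matrix(50, 300, seed = 89,
                       planted = c("linear", "permuted_dependency", "independent"))
  idx <- build_rank_index(m)
  planted <- attr(m, "planted_pairs")
  reports <- lapply(seq_len(nrow(planted)), function(i) {
    pair_report(m, planted$probe_a[i], planted$probe_b[i], idx)
  })
  names(reports) <- planted$kind
  # case 1: strong linear coexpression -> both ranks high
  expect_gte(reports$linear$ro_mi, 95)
  expect_gte(reports$linear$ro_r, 95)
  # case 2: dependency without linear trend -> MI rank high, r rank behind
  expect_gte(reports$permuted_dependency$ro_mi, 95)
  expect_lte(reports$permuted_dependency$ro_r, 50)
  expect_gte(reports$permuted_dependency$rank_difference, 50)
  # case 3: unrelated probes carry no coexpression signal. A single null
  # pair's percentile is uniform by construction, so the check is
  # statistical over 20 background pairs: the vast majority are not
  # flagged as strong by either measure, and ranks center mid-scale.
  null_reports <- lapply(seq(7, 45, by = 2), function(i) {
    pair_report(m, sprintf("probe_%04d_at", i), sprintf("probe_%04d_at", i + 1), idx)
  })
  ro_mi <- vapply(null_reports, `[[`, integer(1), "ro_mi")
  ro_r <- vapply(null_reports, `[[`, integer(1), "ro_r")
  expect_gte(mean(ro_mi < 95), 0.8)
  expect_gte(mean(ro_r < 95), 0.8)
  expect_true(abs(median(ro_mi) - 50) <= 40)
  expect_true(abs(median(ro_r) - 50) <= 40)
})

test_that("top_related matches brute-force scoring of every candidate", {
  m <- simulate_matrix(30, 120, seed = 97, planted = c("permuted_dependency"))
  probe <- "probe_0005_at"
  res <- top_related(m, probe, k = 10)
  ids <- setdiff(rownames(m), probe)
  r <- vapply(ids, function(id) pearson_r(m[probe, ], m[id, ]), numeric(1))
  mi <- vapply(ids, function(id) mi_adaptive(m[probe, ], m[id, ]), numeric(1))
  mir <- 0.5 * r / max(r) + 0.5 * mi / max(mi)
  expect_identical(res$by_r$probe_id, ids[order(-r, ids)][1:10])
  expect_identical(res$by_mi$probe_id, ids[order(-mi, ids)][1:10])
  expect_identical(res$by_mir$probe_id, ids[order(-mir, ids)][1:10])
  expect_equal(res$by_mi$score, unname(sort(mi, decreasing = TRUE))[1:10])

  # an affine copy tops all three lists for its partner
  vals <- unclass(simulate_matrix(3, 80, seed = 101))
  vals[2, ] <- 2 * vals[1, ] + 0.1
  m3 <- expression_matrix(vals)
  res3 <- top_related(m3, "probe_0001_at", k = 5)
  expect_identical(res3$by_r$probe_id[1], "probe_0002_at")
  expect_identical(res3$by_mi$probe_id[1], "probe_0002_at")
  expect_identical(res3$by_mir$probe_id[1], "probe_0002_at")
  expect_identical(nrow(res3$by_mi), 2L)  # k capped at P - 1

  # MI and r perspectives disagree when a rank-permuted partner is planted
  mq <- simulate_matrix(30, 200, seed = 103, planted = c("permuted_dependency"))
  resq <- top_related(mq, "probe_0001_at", k = 5)
  expect_identical(resq$by_mi$probe_id[1], "probe_0002_at")
  expect_false(identical(resq$by_r$probe_id[1], "probe_0002_at"))

  expect_error(top_related(m, "nope_at"), class = "coexmi_unknown_probe_error")
})

test_that("annotation symbols flow into related-gene lists", {
  m <- simulate_matrix(6, 60, seed = 107, planted = "linear")
  ann <- setNames(paste0("GENE", 1:6), rownames(m))
  res <- top_related(m, "probe_0001_at", k = 3, annotation = ann)
  expect_identical(res$by_mi$gene_symbol, unname(ann[res$by_mi$probe_id]))
})

test_that("scatter export writes the pair's profiles and round-trips", {
  m <- five_point_matrix(fig_y_linearish)
  path <- withr::local_tempfile(fileext = ".tsv")
  scatter_export(m, "probe_x_at", "probe_y_at", path)
  tab <- read.delim(path)
  expect_identical(names(tab), c("sample_id", "probe_x_at", "probe_y_at"))
  expect_equal(tab$probe_x_at, fig_x)
  expect_equal(tab$probe_y_at, fig_y_linearish)
  expect_error(scatter_export(m, "probe_x_at", "nope_at", path),
               class = "coexmi_unknown_probe_error")
})
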