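test_that("unweighted walk on a front-loaded set is the classic KS statistic", {
  rk <- ranked_genes(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1), metric = "log2fc")
  sc <- enrichment_score(rk, c("g1", "g2"), weight_p = 0)
  expect_equal(sc$running_sum, c(0.5, 1, 0.5, 0))
  expect_equal(sc$es, 1)
  expect_equal(sc$peak_index, 2L)

  expect_error(enrichment_score(rk, paste0("g", 1:4)),
               class = "lncpath_degenerate_error")
  expect_error(enrichment_score(rk, "absent"),
               class = "lncpath_empty_set_error")
})

test_that("all-zero hit scores fall back to uniform increments", {
  rk <- ranked_genes(c(a = 2, b = 1, c = 0, d = 0, e = -1), metric = "log2fc")
  sc <- enrichment_score(rk, c("c", "d"), weight_p = 1)
  # hits at positions 3 and 4 increment by 1/2 each; misses drop by 1/3
  expect_equal(sc$running_sum,
               c(-1 / 3, -2 / 3, -2 / 3 + 1 / 2, -2 / 3 + 1, 0),
               tolerance = 1e-12)
})

test_that("enrichment score matches the literal walk oracle on random instances", {
  set.seed(2024)
  for (i in 1:80) {
    n <- sample(5:50, 1)
    scores <- round(rnorm(n), 3) # rounding creates occasional ties
    genes <- sprintf("g%03d", seq_len(n))
    rk <- ranked_genes(setNames(scores, genes))
    m <- sample(n - 1, 1)
    members <- sample(genes, m)
    p <- sample(c(0, 0.5, 1, 2), 1)
    got <- enrichment_score(rk, members, weight_p = p)
    ora <- oracle_es_walk(rk$score, rk$gene_id %in% members, p)
    expect_identical(got$peak_index, ora$peak_index)
    expect_equal(got$es, ora$es, tolerance = 1e-12)
    expect_identical(leading_edge(rk, members, got$es, got$peak_index),
                     rk$gene_id[ora$leading_idx])
  }
})

test_that("enrichment score agrees with an established implementation", {
  skip_if_not_installed("fgsea")
  set.seed(77)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    rk <- ranked_genes(setNames(scores, sprintf("g%03d", 1:n)))
    pos <- sort(sample(n, sample(3:10, 1)))
    ref <- fgsea::calcGseaStat(scores, selectedStats = pos, gseaParam = 1)
    got <- enrichment_score(rk, rk$gene_id[pos], weight_p = 1)
    expect_equal(got$es, ref, tolerance = 1e-10)
  }
})

test_that("permutation null is seed-reproducible and reuses the full walk's statistic", {
  rk <- toy_ranking(n = 40, seed = 3)
  null1 <- permutation_null(rk, set_size = 6, n_perm = 50, seed = 9)
  null2 <- permutation_null(rk, set_size = 6, n_perm = 50, seed = 9)
  expect_identical(null1, null2)

  # replay the same subset draws through the O(N) walk
  replay <- local({
    set.seed(9)
    vapply(1:50, function(i) {
      pos <- sort(sample.int(40, 6))
      enrichment_score(rk, rk$gene_id[pos], weight_p = 1)$es
    }, numeric(1))
  })
  expect_equal(null1, replay, tolerance = 1e-12)

  expect_error(permutation_null(rk, set_size = 6, n_perm = 0),
               class = "lncpath_parameter_error")
  expect_error(permutation_null(rk, set_size = 40, n_perm = 10),
               class = "lncpath_parameter_error")
})

test_that("size-1 null on a 2-gene list enumerates both subsets equally", {
  rk <- ranked_genes(c(a = 1, b = 0.5))
  null <- permutation_null(rk, set_size = 1, n_perm = 2000, seed = 4)
  expect_setequal(unique(null), c(1, -1))
  # binomial(2000, 1/2): observed frequency within 3 SD of 1/2
  expect_lt(abs(mean(null == 1) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("leading edge follows the peak on both signs", {
  rk <- toy_ranking(n = 10, seed = 6)
  top2 <- rk$gene_id[1:2]
  sc <- enrichment_score(rk, top2, weight_p = 0)
  expect_identical(leading_edge(rk, top2, sc$es, sc$peak_index), top2)

  bottom <- rk$gene_id[8:10]
  sc2 <- enrichment_score(rk, bottom, weight_p = 0)
  expect_lt(sc2$es, 0)
  ora <- oracle_es_walk(rk$score, rk$gene_id %in% bottom, 0)
  expect_identical(leading_edge(rk, bottom, sc2$es, sc2$peak_index),
                   rk$gene_id[ora$leading_idx])

  # a member strictly after a positive peak is excluded
  mixed <- rk$gene_id[c(1, 2, 9)]
  sc3 <- enrichment_score(rk, mixed, weight_p = 0)
  expect_gt(sc3$es, 0)
  expect_identical(leading_edge(rk, mixed, sc3$es, sc3$peak_index), top2)
  expect_error(leading_edge(rk, top2, 0.5, 99),
               class = "lncpath_parameter_error")
})

test_that("antisymmetry: reversing the list and negating scores negates the unweighted ES", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    genes <- sprintf("g%03d", 1:n)
    rk <- ranked_genes(setNames(scores, genes))
    rk_rev <- ranked_genes(setNames(rev(-scores), rev(genes)))
    members <- sample(genes, sample(2:(n - 2), 1))
    sc_f <- enrichment_score(rk, members, weight_p = 0)
    es_r <- enrichment_score(rk_rev, members, weight_p = 0)$es
    expect_equal(abs(es_r), abs(sc_f$es), tolerance = 1e-12)
    # an exact |max| == |min| tie leaves the sign to the first-occurrence
    # rule, which reversal does not preserve; skip the sign check there
    rs <- sc_f$running_sum
    if (abs(max(rs) + min(rs)) > 1e-9) {
      expect_equal(es_r, -sc_f$es, tolerance = 1e-12)
    }
    expect_lte(abs(sc_f$es), 1)
  }
})

test_that("ES reaches 1 exactly when members fill the top of the list", {
  rk <- toy_ranking(n = 20, seed = 8)
  sc <- enrichment_score(rk, rk$gene_id[1:5], weight_p = 0)
  expect_equal(sc$es, 1)
  sc2 <- enrichment_score(rk, rk$gene_id[c(1:4, 6)], weight_p = 0)
  expect_lt(sc2$es, 1)
})

test_that("preranked run recovers a planted set and obeys table invariants", {
  co <- small_cohort(seed = 12)
  res <- suppressMessages(infer_lnc_pathways(co$lnc, co$coding, co$sets,
                                       co$target_id, metric = "gba",
                                       n_perm = 1000, seed = 2))
  expect_s3_class(res, "lnc_enrichment")
  expect_equal(res$pathway[which.max(abs(res$nes))], "PLANTED")
  expect_lt(res$q_fdr[res$pathway == "PLANTED"], 0.05)

  # structural invariants
  expect_true(all(sign(res$nes[res$es != 0]) == sign(res$es[res$es != 0]),
                  na.rm = TRUE))
  expect_true(all(res$p_nominal >= 1 / (res$n_perm_effective + 1)))
  ord <- order(res$p_nominal)
  expect_true(!is.unsorted(res$q_fdr[ord]))
  expect_equal(res$q_fdr, stats::p.adjust(res$p_nominal, "BH"))
  rk <- attr(res, "ranking")
  for (i in seq_len(nrow(res))) {
    le <- res$leading_edge[[i]]
    members <- gene_set_list(co$sets)[[res$pathway[i]]]
    expect_true(all(le %in% intersect(rk$gene_id, members)))
    expect_false(is.unsorted(match(le, rk$gene_id)))
  }
})

test_that("size filter skips sets and an empty filter result errors", {
  rk <- toy_ranking(n = 30, seed = 5)
  gs <- gene_sets(list(BIG = rk$gene_id[1:20], TINY = rk$gene_id[1:2],
                       OK = rk$gene_id[c(3, 7, 11, 15, 19, 23)]))
  res <- run_preranked(rk, gs, min_size = 5, max_size = 10, n_perm = 100,
                       seed = 1)
  expect_equal(res$pathway, "OK")
  expect_setequal(attr(res, "skipped")$set, c("BIG", "TINY"))
  expect_error(run_preranked(rk, gs, min_size = 25, n_perm = 100),
               class = "lncpath_empty_result_error")
})

test_that("identical input and seed reproduce the result table exactly", {
  co <- small_cohort(seed = 3)
  r1 <- suppressMessages(infer_lnc_pathways(co$lnc, co$coding, co$sets,
                                      co$target_id, metric = "dge",
                                      n_perm = 300, seed = 11))
  r2 <- suppressMessages(infer_lnc_pathways(co$lnc, co$coding, co$sets,
                                      co$target_id, metric = "dge",
                                      n_perm = 300, seed = 11))
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
})

test_that("result tables round-trip through TSV ordered by NES", {
  co <- small_cohort(seed = 21)
  res <- suppressMessages(infer_lnc_pathways(co$lnc, co$coding, co$sets,
                                       co$target_id, n_perm = 200, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  back <- read_enrichment(path)
  expect_equal(back$pathway, res$pathway)
  expect_equal(back$nes, res$nes, tolerance = 1e-12)
  expect_identical(back$leading_edge, res$leading_edge)
  expect_false(is.unsorted(rev(back$nes), na.rm = TRUE))
})
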