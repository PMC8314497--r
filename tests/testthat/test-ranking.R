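test_that("quantile split takes order-statistic groups with deterministic ties", {
  v <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8), paste0("S", 1:8))
  sp <- split_by_quantile(v, q = 0.25)
  expect_setequal(sp$high, c("S7", "S8"))
  expect_setequal(sp$low, c("S1", "S2"))
  expect_equal(sp$group_size, 2L)

  # all-tied abundances fall back to sample-id order (hand-applied rule:
  # sort by (value, sample_id), take k from each end -> low = first two ids,
  # high = last two ids, disjoint)
  fx <- degenerate_fixtures()$all_tied_lnc
  sp2 <- split_by_quantile(fx$target, q = 0.25)
  expect_equal(sort(sp2$low), c("S01", "S02"))
  expect_equal(sort(sp2$high), c("S07", "S08"))
  expect_length(intersect(sp2$high, sp2$low), 0L)
})

test_that("quantile split rejects tiny cohorts and overlapping groups", {
  expect_error(split_by_quantile(setNames(1:3, paste0("S", 1:3))),
               class = "lncpath_size_error")
  expect_error(split_by_quantile(setNames(1:8, paste0("S", 1:8)), q = 0.6),
               class = "lncpath_parameter_error")
})

test_that("fold-change ranking equals hand-computed group mean differences", {
  set.seed(42)
  n_genes <- 50
  v <- matrix(rnorm(n_genes * 8, mean = 5), n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes), paste0("S", 1:8)))
  coding <- as_expr_mat(v)
  attr(coding, "log_transformed") <- TRUE
  high <- paste0("S", 1:3)
  low <- paste0("S", 6:8)
  rk <- rank_by_dge(coding, high, low, target_id = "LNC")

  # brute-force oracle: per-gene difference of arithmetic means
  expected <- sapply(rownames(v), function(g) {
    sum(v[g, high]) / 3 - sum(v[g, low]) / 3
  })
  expect_equal(rk$score[match(names(expected), rk$gene_id)],
               unname(expected), tolerance = 1e-12)
  expect_false(is.unsorted(rev(rk$score)))
  expect_equal(attr(rk, "group_sizes"), c(n_high = 3L, n_low = 3L))

  # identical values in both groups -> score 0; +2 shift in high -> +2
  const <- as_expr_mat(matrix(3, 2, 8, dimnames = list(c("a", "b"),
                                                       paste0("S", 1:8))))
  attr(const, "log_transformed") <- TRUE
  rk0 <- rank_by_dge(const, high, low)
  expect_equal(rk0$score, c(0, 0))
  shifted <- const
  for (s in high) shifted[[s]] <- shifted[[s]] + 2
  expect_equal(rank_by_dge(shifted, high, low)$score, c(2, 2))

  expect_error(rank_by_dge(coding, high, c(high[1], low)),
               class = "lncpath_validation_error")
  raw <- as_expr_mat(v - min(v))
  expect_error(rank_by_dge(raw, high, low),
               class = "lncpath_validation_error")
})

test_that("correlation ranking matches the textbook sum formula", {
  set.seed(99)
  n_g <- 20; n_s <- 30
  v <- matrix(rnorm(n_g * n_s), n_g,
              dimnames = list(sprintf("g%02d", 1:n_g), paste0("S", 1:n_s)))
  # inject ties so midranks are exercised
  v[3, 1:5] <- v[3, 6:10]
  coding <- as_expr_mat(v + 10)
  attr(coding, "log_transformed") <- TRUE
  target <- setNames(rnorm(n_s), paste0("S", 1:n_s))

  rp <- rank_by_gba(coding, target, method = "pearson")
  for (g in rownames(v)) {
    expect_equal(rp$score[rp$gene_id == g], oracle_pearson(v[g, ], target),
                 tolerance = 1e-10)
  }
  rs <- rank_by_gba(coding, target, method = "spearman")
  for (g in rownames(v)) {
    expect_equal(rs$score[rs$gene_id == g],
                 oracle_pearson(oracle_midrank(v[g, ]),
                                oracle_midrank(target)),
                 tolerance = 1e-10)
  }
})

test_that("correlation ranking hits exact values on constructed genes", {
  n_s <- 12
  target <- setNames(seq_len(n_s) + 0.5, paste0("S", 1:n_s))
  v <- rbind(self = target, anti = -target + 100, flat = rep(7, n_s),
             noise = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8))
  colnames(v) <- names(target)
  coding <- as_expr_mat(v)
  attr(coding, "log_transformed") <- TRUE
  rk <- suppressMessages(rank_by_gba(coding, target))
  expect_equal(rk$score[rk$gene_id == "self"], 1)
  expect_equal(rk$score[rk$gene_id == "anti"], -1)
  expect_false("flat" %in% rk$gene_id)
  expect_message(rank_by_gba(coding, target), "1 zero-variance")

  expect_error(rank_by_gba(coding, setNames(rep(1, n_s), names(target))),
               class = "lncpath_degenerate_error")
  expect_error(rank_by_gba(coding, target[1:5]),
               class = "lncpath_validation_error")
})

test_that("pearson ranking is affine-invariant and sign-flips under negation", {
  set.seed(5)
  n_s <- 25
  v <- matrix(rnorm(3 * n_s), 3, dimnames = list(c("a", "b", "c"),
                                                 paste0("S", 1:n_s)))
  coding <- as_expr_mat(v + 10)
  attr(coding, "log_transformed") <- TRUE
  target <- setNames(rnorm(n_s), paste0("S", 1:n_s))
  base <- rank_by_gba(coding, target)
  up <- rank_by_gba(coding, 3 * target + 7)
  expect_equal(up$score[match(base$gene_id, up$gene_id)], base$score,
               tolerance = 1e-12)
  neg <- rank_by_gba(coding, -target)
  expect_equal(neg$score[match(base$gene_id, neg$gene_id)], -base$score,
               tolerance = 1e-12)
})

test_that("rankings sort descending with lexicographic tie-break and round-trip as .rnk", {
  rk <- ranked_genes(c(b = 1, a = 1, c = 2, d = -1), metric = "log2fc")
  expect_equal(rk$gene_id, c("c", "a", "b", "d"))
  path <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(rk, path)
  rk2 <- read_rnk(path, metric = "log2fc")
  expect_equal(tibble::as_tibble(rk2), tibble::as_tibble(rk))
  expect_error(ranked_genes(c(a = 1, a = 2)),
               class = "lncpath_validation_error")
  expect_error(ranked_genes(c(a = 1, b = NaN)),
               class = "lncpath_validation_error")
})
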