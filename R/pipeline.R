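#' Infer pathways associated with a target lncRNA
#'
#' The full workflow: harmonize the lncRNA and coding matrices on shared
#' (barcode-truncated) samples, put both on log2(x + 1) scale unless already
#' logged, rank the coding genes for the target lncRNA by the chosen metric,
#' and score the ranking against the gene-set collection with pre-ranked
#' enrichment analysis.
#'
#' Two ranking metrics are available. `"dge"` splits patients at the top and
#' bottom quantile of target-lncRNA expression and ranks genes by the log2
#' fold change between the groups, mimicking knockdown-versus-control
#' profiling; it is the recommended choice when the lncRNA is expressed in
#' only part of the cohort. `"gba"` (guilt by association) ranks genes by
#' their Pearson or Spearman correlation with the lncRNA across all samples.
#'
#' @param lnc,coding Expression matrices ([as_expr_mat()] /
#'   [read_expression_matrix()]) on raw or log2 scale.
#' @param sets A [gene_sets()] collection.
#' @param target_id One or more lncRNA identifiers present in `lnc`.
#' @param metric `"gba"` or `"dge"`.
#' @param cor_method Correlation for the GBA metric.
#' @param quantile_frac Quantile fraction for the DGE split (default 0.25).
#' @param barcode_fields Dash-fields used to match samples (default 4).
#' @param weight_p,n_perm,min_size,max_size,seed Passed to
#'   [run_preranked()].
#' @param out_dir Optional directory; when given, the result table, rank
#'   file and a key=value run-metadata file are written per target.
#' @return For one target, a `lnc_enrichment` tibble with the ranking in
#'   `attr(, "ranking")`; for several targets, a named list of them.
#' @export
infer_lnc_pathways <- function(lnc, coding, sets, target_id,
                         metric = c("gba", "dge"),
                         cor_method = c("pearson", "spearman"),
                         quantile_frac = 0.25, barcode_fields = 4,
                         weight_p = 1, n_perm = 1000, min_size = 5,
                         max_size = 500, seed = 1, out_dir = NULL) {
  metric <- match.arg(metric)
  cor_method <- match.arg(cor_method)
  h <- harmonize_samples(lnc, coding, barcode_fields = barcode_fields)
  lnc_l <- if (is_logged(h$lnc)) h$lnc else log2_transform(h$lnc)
  coding_l <- if (is_logged(h$coding)) h$coding else log2_transform(h$coding)

  one <- function(tid) {
    target <- extract_target_vector(lnc_l, tid)
    ranking <- if (metric == "dge") {
      grp <- split_by_quantile(target, q = quantile_frac)
      rank_by_dge(coding_l, grp$high, grp$low, target_id = tid)
    } else {
      rank_by_gba(coding_l, target, method = cor_method, target_id = tid)
    }
    res <- run_preranked(ranking, sets, min_size = min_size,
                         max_size = max_size, weight_p = weight_p,
                         n_perm = n_perm, seed = seed)
    attr(res, "ranking") <- ranking
    if (!is.null(out_dir)) {
      write_run_outputs(res, ranking, out_dir, tid, metric, seed)
    }
    res
  }
  if (length(target_id) == 1L) {
    one(target_id)
  } else {
    stats::setNames(lapply(target_id, one), target_id)
  }
}

write_run_outputs <- function(res, ranking, out_dir, tid, metric, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", tid),
                                    "_", metric))
  write_enrichment(res, paste0(stem, "_enrichment.tsv"))
  write_rnk(ranking, paste0(stem, ".rnk"))
  info <- attr(res, "run_info")
  meta <- c(sprintf("target_id=%s", tid),
            sprintf("metric=%s", metric),
            sprintf("n_genes_ranked=%d", nrow(ranking)),
            sprintf("n_samples_used=%d", attr(ranking, "n_samples_used")),
            sprintf("weight_p=%g", info$weight_p),
            sprintf("n_perm=%d", info$n_perm),
            sprintf("min_size=%d", info$min_size),
            sprintf("max_size=%d", info$max_size),
            sprintf("seed=%d", seed),
            sprintf("lncpath_version=%s",
                    as.character(utils::packageVersion("lncpath"))))
  readr::write_lines(meta, paste0(stem, "_run_info.txt"))
  invisible(stem)
}

#' Compare two gene rankings for concordance
#'
#' Convenience wrapper over [similarity_pvalue()] for `lnc_ranking` tibbles
#' (e.g. the DGE and GBA rankings of the same lncRNA). Batch mode combines
#' the per-pair permutation p-values with [fisher_meta()].
#'
#' @param rank_a,rank_b `lnc_ranking` tibbles, or lists of them (paired by
#'   position) for batch mode.
#' @inheritParams similarity_pvalue
#' @return One `lnc_similarity` row per pair; in batch mode a list with
#'   `pairs` (one row each) and `meta` ([fisher_meta()] row).
#' @export
compare_rankings <- function(rank_a, rank_b, alpha = NULL, n_top = 100,
                             n_perm = 999, seed = 1) {
  if (is.data.frame(rank_a)) {
    return(similarity_pvalue(rank_a$gene_id, rank_b$gene_id, alpha = alpha,
                             n_top = n_top, n_perm = n_perm, seed = seed))
  }
  stopifnot(length(rank_a) == length(rank_b))
  pairs <- purrr::imap(rank_a, function(a, i) {
    b <- rank_b[[i]]
    similarity_pvalue(a$gene_id, b$gene_id, alpha = alpha, n_top = n_top,
                      n_perm = n_perm,
                      seed = derive_seed(seed, if (is.character(i)) match(i, names(rank_a)) else i))
  })
  pairs <- dplyr::bind_rows(pairs, .id = "pair")
  list(pairs = pairs, meta = fisher_meta(pairs$p_perm))
}
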