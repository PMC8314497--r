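#' Ranked gene lists
#'
#' The input to pre-ranked enrichment: a tibble of coding genes with a signed
#' ranking score, sorted by score descending (ties broken by gene id so the
#' order is deterministic). Metadata attributes record the metric
#' (`"log2fc"`, `"pearson"` or `"spearman"`), the target lncRNA, the number
#' of samples used and, for the fold-change metric, the group sizes.
#'
#' @param scores Named numeric vector (names = gene ids) or a data frame with
#'   `gene_id` and `score` columns.
#' @param metric,target_id,n_samples_used,group_sizes Metadata.
#' @return A tibble of class `lnc_ranking` with columns `gene_id`, `score`.
#' @export
ranked_genes <- function(scores, metric = "log2fc", target_id = "",
                         n_samples_used = NA_integer_, group_sizes = NULL) {
  if (is.data.frame(scores)) {
    df <- tibble(gene_id = as.character(scores$gene_id),
                 score = as.numeric(scores$score))
  } else {
    df <- tibble(gene_id = names(scores), score = as.numeric(scores))
  }
  if (is.null(df$gene_id) || anyDuplicated(df$gene_id)) {
    abort("gene ids must be present and unique in a ranking.",
          class = "lncpath_validation_error")
  }
  if (!all(is.finite(df$score))) {
    abort("ranking scores must all be finite.",
          class = "lncpath_validation_error")
  }
  df <- df[order(-df$score, df$gene_id), ]
  structure(df,
            metric = metric, target_id = target_id,
            n_samples_used = as.integer(n_samples_used),
            group_sizes = group_sizes,
            class = c("lnc_ranking", class(tibble())))
}

#' Split samples into high/low lncRNA-expression groups
#'
#' Patients are split at the top and bottom quantile of target-lncRNA
#' abundance. Groups are order-statistic based with exactly `ceiling(q * n)`
#' samples each; ties in abundance are resolved by sample id (ascending), so
#' the split is deterministic even when many samples share a value (e.g.
#' lncRNA dropout zeros).
#'
#' @param target Named abundance vector (names = sample ids).
#' @param q Quantile fraction in (0, 0.5]; default 0.25.
#' @return A list with character vectors `high` and `low` and the quantile
#'   used.
#' @export
split_by_quantile <- function(target, q = 0.25) {
  check_number(q, "q", lower = 0, upper = 0.5, strict_lower = TRUE)
  n <- length(target)
  if (n < 4L) {
    abort(sprintf("need >= 4 samples to split; got %d.", n),
          class = "lncpath_size_error")
  }
  if (is.null(names(target))) {
    abort("`target` must be named by sample id.",
          class = "lncpath_validation_error")
  }
  k <- as.integer(ceiling(q * n))
  if (k < 2L) {
    abort(sprintf("group size %d < 2 at q = %g, n = %d.", k, q, n),
          class = "lncpath_size_error")
  }
  if (2L * k > n) {
    abort(sprintf("groups of size %d overlap on %d samples; lower q.", k, n),
          class = "lncpath_size_error")
  }
  ord <- names(target)[order(target, names(target))]
  low <- ord[seq_len(k)]
  high <- ord[seq.int(n - k + 1L, n)]
  list(high = high, low = low, q = q, group_size = k)
}

#' Rank genes by log2 fold change between high and low groups
#'
#' The differential-expression (DGE) ranking metric: for each coding gene,
#' the difference of its mean log2 abundance between the high- and
#' low-lncRNA sample groups — a log2 fold change, mimicking a
#' knockdown-versus-control contrast.
#'
#' @param coding An `expr_mat` on log2 scale ([log2_transform()]).
#' @param high_ids,low_ids Disjoint sample-id sets from
#'   [split_by_quantile()].
#' @param target_id Recorded on the result.
#' @return An [ranked_genes()] tibble with metric `"log2fc"`.
#' @export
rank_by_dge <- function(coding, high_ids, low_ids, target_id = "") {
  if (!is_logged(coding)) {
    abort("`coding` must be log2-transformed before fold-change ranking.",
          class = "lncpath_validation_error")
  }
  sam <- sample_ids(coding)
  if (!all(high_ids %in% sam) || !all(low_ids %in% sam)) {
    abort("group sample ids must all be columns of `coding`.",
          class = "lncpath_validation_error")
  }
  if (length(intersect(high_ids, low_ids)) > 0L) {
    abort("high and low groups overlap.", class = "lncpath_validation_error")
  }
  v <- expr_values(coding)
  lfc <- rowMeans(v[, high_ids, drop = FALSE]) -
    rowMeans(v[, low_ids, drop = FALSE])
  keep <- is.finite(lfc)
  if (any(!keep)) {
    inform(sprintf("excluded %d gene(s) with non-finite fold change.",
                   sum(!keep)))
  }
  ranked_genes(lfc[keep], metric = "log2fc", target_id = target_id,
               n_samples_used = length(high_ids) + length(low_ids),
               group_sizes = c(n_high = length(high_ids),
                               n_low = length(low_ids)))
}

#' Rank genes by correlation with the target lncRNA
#'
#' The guilt-by-association (GBA) ranking metric: every coding gene's
#' Pearson or Spearman correlation with the target lncRNA across all
#' samples. Spearman is Pearson on midranks (average ranks on ties).
#' Zero-variance genes, whose correlation is undefined, are excluded with a
#' message rather than being interleaved at score 0.
#'
#' @param coding An `expr_mat` on log2 scale.
#' @param target Named abundance vector over the same samples (same order).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param target_id Recorded on the result.
#' @return A [ranked_genes()] tibble with the correlation metric.
#' @export
rank_by_gba <- function(coding, target, method = c("pearson", "spearman"),
                        target_id = "") {
  method <- match.arg(method)
  sam <- sample_ids(coding)
  if (length(target) != length(sam) ||
      (!is.null(names(target)) && !identical(names(target), sam))) {
    abort("`target` must be indexed by the same samples as `coding` columns.",
          class = "lncpath_validation_error")
  }
  if (length(sam) < 3L) {
    abort("need >= 3 samples for correlation ranking.",
          class = "lncpath_size_error")
  }
  if (stats::sd(target) == 0) {
    abort("target lncRNA has zero variance across samples.",
          class = "lncpath_degenerate_error")
  }
  v <- expr_values(coding)
  y <- as.numeric(target)
  if (method == "spearman") {
    v <- t(apply(v, 1L, rank, ties.method = "average"))
    y <- rank(y, ties.method = "average")
  }
  sds <- apply(v, 1L, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    inform(sprintf("excluded %d zero-variance gene(s) from correlation ranking.",
                   sum(!keep)))
  }
  if (!any(keep)) {
    abort("no gene with non-zero variance to rank.",
          class = "lncpath_degenerate_error")
  }
  r <- as.numeric(stats::cor(t(v[keep, , drop = FALSE]), y))
  names(r) <- rownames(v)[keep]
  ranked_genes(r, metric = method, target_id = target_id,
               n_samples_used = length(sam))
}

#' Read / write a two-column rank file (".rnk" dialect)
#'
#' @param path File path.
#' @param ... Metadata passed to [ranked_genes()].
#' @return [read_rnk()] a `lnc_ranking`; [write_rnk()] `path`, invisibly.
#' @export
read_rnk <- function(path, ...) {
  if (!file.exists(path)) {
    abort(sprintf("rank file not found: %s", path), class = "lncpath_io_error")
  }
  df <- readr::read_tsv(path, col_names = c("gene_id", "score"),
                        col_types = "cd", progress = FALSE)
  if (nrow(df) == 0L || anyNA(df$score)) {
    abort(sprintf("malformed rank file: %s", path),
          class = "lncpath_parse_error")
  }
  ranked_genes(df, ...)
}

#' @rdname read_rnk
#' @param ranking A `lnc_ranking` tibble.
#' @export
write_rnk <- function(ranking, path) {
  readr::write_tsv(as_tibble(ranking)[c("gene_id", "score")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
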