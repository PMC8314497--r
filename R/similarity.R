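#' Exponentially weighted top/bottom overlap of two ranked lists
#'
#' Concordance statistic for two orderings of the same genes: at each depth
#' `n = 1..n_top` the sizes of the overlaps between the two lists' first `n`
#' genes and between their last `n` genes are summed with weight
#' `exp(-alpha * n)`, so agreement at the extremes of the rankings counts
#' most. The lists are first restricted to their common gene universe,
#' preserving relative order.
#'
#' @param list_a,list_b Character vectors of gene ids, most to least
#'   associated.
#' @param alpha Positive decay rate; default `log(100) / n_top`, i.e. the
#'   weight has fallen to 0.01 at depth `n_top`.
#' @param n_top Depth limit (default 100; at most the common universe size).
#' @return The non-negative overlap score.
#' @examples
#' g <- paste0("g", 1:50)
#' weighted_overlap(g, g, n_top = 10) # maximal for identical lists
#' @export
weighted_overlap <- function(list_a, list_b, alpha = NULL, n_top = 100) {
  p <- overlap_prep(list_a, list_b, alpha, n_top)
  wo_score(p$pos_a, p$pos_b, p$n, p$wts)
}

overlap_prep <- function(list_a, list_b, alpha, n_top) {
  common <- intersect(list_a, list_b)
  n <- length(common)
  if (n == 0L) {
    abort("ranked lists share no genes.", class = "lncpath_validation_error")
  }
  check_number(n_top, "n_top", lower = 1, upper = n, integer = TRUE)
  alpha <- alpha %||% (log(100) / n_top)
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  a <- list_a[list_a %in% common]
  b <- list_b[list_b %in% common]
  list(pos_a = match(common, a), pos_b = match(common, b), n = n,
       wts = exp(-alpha * seq_len(n_top)), alpha = alpha, n_top = n_top)
}

# Score from per-gene positions in the two restricted lists: a gene is in
# both depth-n tops iff max of its two positions <= n, so the depth profile
# is a cumulative tabulation of pairwise position maxima.
wo_score <- function(pos_a, pos_b, n, wts) {
  k <- length(wts)
  top <- cumsum(tabulate(pmax(pos_a, pos_b), nbins = n))[seq_len(k)]
  bot <- cumsum(tabulate(pmax(n + 1L - pos_a, n + 1L - pos_b),
                         nbins = n))[seq_len(k)]
  sum(wts * (top + bot))
}

#' Orientation-resolved overlap score
#'
#' Two rankings can agree while running in opposite directions (e.g. one
#' tool scores association, the other dissociation). The overlap score is
#' computed for `list_b` as given and reversed; the larger wins and fixes
#' the reported direction (`"same"` on ties).
#'
#' @inheritParams weighted_overlap
#' @return A list with `direction` (`"same"` or `"reversed"`) and `score`.
#' @export
direction_and_score <- function(list_a, list_b, alpha = NULL, n_top = 100) {
  p <- overlap_prep(list_a, list_b, alpha, n_top)
  s_same <- wo_score(p$pos_a, p$pos_b, p$n, p$wts)
  s_rev <- wo_score(p$pos_a, p$n + 1L - p$pos_b, p$n, p$wts)
  if (s_same >= s_rev) {
    list(direction = "same", score = s_same)
  } else {
    list(direction = "reversed", score = s_rev)
  }
}

#' Permutation significance of ranked-list similarity
#'
#' Compares the observed orientation-resolved overlap score against scores
#' of `list_a` versus `n_perm` uniform random orderings of `list_b`. The
#' null statistic also takes the max over both orientations, mirroring the
#' observed one, so orientation selection introduces no bias.
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams weighted_overlap
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed.
#' @return One-row tibble of class `lnc_similarity`: `score`, `direction`,
#'   `p_perm`, `alpha`, `n_top`, `n_perm`, `seed`.
#' @export
similarity_pvalue <- function(list_a, list_b, alpha = NULL, n_top = 100,
                              n_perm = 999, seed = 1) {
  check_number(n_perm, "n_perm", lower = 1, integer = TRUE)
  p <- overlap_prep(list_a, list_b, alpha, n_top)
  s_same <- wo_score(p$pos_a, p$pos_b, p$n, p$wts)
  s_rev <- wo_score(p$pos_a, p$n + 1L - p$pos_b, p$n, p$wts)
  obs <- max(s_same, s_rev)
  null <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pb <- sample.int(p$n)
      max(wo_score(p$pos_a, pb, p$n, p$wts),
          wo_score(p$pos_a, p$n + 1L - pb, p$n, p$wts))
    }, numeric(1))
  })
  structure(
    tibble(score = obs,
           direction = if (s_same >= s_rev) "same" else "reversed",
           p_perm = (1 + sum(null >= obs)) / (1 + n_perm),
           alpha = p$alpha, n_top = p$n_top,
           n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = c("lnc_similarity", class(tibble())))
}

#' Fisher's method for combining independent p-values
#'
#' Meta-analytic combination across comparisons (e.g. one similarity test
#' per lncRNA): `X = -2 * sum(log(p_i))` is chi-square with `2k` degrees of
#' freedom under the joint null.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return One-row tibble: `meta_p`, `statistic`, `df`, `k`, `method`.
#' @examples
#' fisher_meta(c(0.05, 0.05)) # more significant than either alone
#' @export
fisher_meta <- function(p_values) {
  if (length(p_values) < 1L || !is.numeric(p_values) ||
      any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort("`p_values` must be >= 1 values in (0, 1].",
          class = "lncpath_parameter_error")
  }
  k <- length(p_values)
  x <- -2 * sum(log(p_values))
  tibble(meta_p = stats::pchisq(x, df = 2 * k, lower.tail = FALSE),
         statistic = x, df = 2L * k, k = k, method = "fisher")
}

#' Concordance of two NES-ordered enrichment tables
#'
#' Orders the gene sets shared by two enrichment results by normalized
#' enrichment score and measures agreement of the two orderings: the
#' orientation-resolved weighted overlap of the set-name lists, plus the
#' Spearman rank correlation of the two NES vectors.
#'
#' @param res_a,res_b `lnc_enrichment` tibbles (>= 3 shared set names with
#'   defined NES).
#' @param alpha,n_top Overlap parameters; `n_top` defaults to the number of
#'   shared sets.
#' @return One-row tibble: `score`, `direction`, `spearman_rho`, `n_shared`.
#' @export
geneset_table_concordance <- function(res_a, res_b, alpha = NULL,
                                      n_top = NULL) {
  a <- as_tibble(res_a)[!is.na(res_a$nes), c("pathway", "nes")]
  b <- as_tibble(res_b)[!is.na(res_b$nes), c("pathway", "nes")]
  shared <- intersect(a$pathway, b$pathway)
  if (length(shared) < 3L) {
    abort(sprintf("only %d shared gene set(s); need >= 3.", length(shared)),
          class = "lncpath_validation_error")
  }
  a <- a[a$pathway %in% shared, ]
  b <- b[b$pathway %in% shared, ]
  ord_a <- a$pathway[order(-a$nes, a$pathway)]
  ord_b <- b$pathway[order(-b$nes, b$pathway)]
  n_top <- n_top %||% length(shared)
  ds <- direction_and_score(ord_a, ord_b, alpha = alpha, n_top = n_top)
  rho <- stats::cor(a$nes[match(shared, a$pathway)],
                    b$nes[match(shared, b$pathway)], method = "spearman")
  tibble(score = ds$score, direction = ds$direction, spearman_rho = rho,
         n_shared = length(shared))
}
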