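#' Weighted running-sum enrichment score
#'
#' Walks the ranked gene list: at each gene-set member ("hit") the running
#' sum increments by `|score|^weight_p / N_R` (where `N_R` sums the weighted
#' scores over hits), at each non-member ("miss") it decrements by
#' `1 / (N - N_hit)`. The enrichment score (ES) is the running-sum value of
#' maximal absolute deviation from zero; on ties the first position wins.
#' With `weight_p = 0` this is the classic unweighted two-sample
#' Kolmogorov-Smirnov walk. If every hit score is zero the hits increment
#' uniformly by `1 / N_hit`.
#'
#' @param ranked A [ranked_genes()] tibble.
#' @param members Character vector of gene-set member ids.
#' @param weight_p Non-negative weight exponent (default 1).
#' @return A list with `es`, `peak_index` and the full `running_sum` vector.
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  check_number(weight_p, "weight_p", lower = 0)
  genes <- ranked$gene_id
  n <- length(genes)
  hit <- genes %in% members
  n_hit <- sum(hit)
  if (n_hit == 0L) {
    abort("gene set has no members in the ranked list.",
          class = "lncpath_empty_set_error")
  }
  if (n_hit == n) {
    abort("gene set covers the whole ranked list; misses are undefined.",
          class = "lncpath_degenerate_error")
  }
  w <- abs(ranked$score[hit])^weight_p
  n_r <- sum(w)
  step <- rep(-1 / (n - n_hit), n)
  step[hit] <- if (n_r > 0) w / n_r else 1 / n_hit
  running <- cumsum(step)
  peak <- which.max(abs(running))
  list(es = running[peak], peak_index = peak, running_sum = running)
}

# O(m) enrichment score from sorted hit positions, used for permutation
# nulls. `aw` = |score|^weight_p over the whole ranked list. Reproduces the
# full walk's value and first-occurrence tie rule: the running sum attains
# its maximum just after a hit and its minimum just before one.
fast_es <- function(aw, n, pos) {
  m <- length(pos)
  w <- aw[pos]
  n_r <- sum(w)
  inc <- if (n_r > 0) w / n_r else rep(1 / m, m)
  miss <- 1 / (n - m)
  ch <- cumsum(inc)
  base <- (pos - seq_len(m)) * miss
  v_after <- ch - base
  v_before <- c(0, ch[-m]) - base
  i_hi <- which.max(v_after)
  i_lo <- which.min(v_before)
  hi <- v_after[i_hi]
  lo <- v_before[i_lo]
  if (abs(hi) > abs(lo)) {
    hi
  } else if (abs(lo) > abs(hi)) {
    lo
  } else if (pos[i_hi] <= pos[i_lo] - 1L) {
    hi
  } else {
    lo
  }
}

#' Gene-label permutation null for the enrichment score
#'
#' Draws `n_perm` uniform random gene subsets of a given size from the
#' ranked list and records each subset's enrichment score. This is the
#' pre-ranked null: sample labels are unavailable, so significance is
#' assessed against random same-size gene sets.
#'
#' @param ranked A [ranked_genes()] tibble.
#' @param set_size Subset size, `1 <= set_size < N`.
#' @param weight_p Weight exponent (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the null is reproducible given the seed.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, weight_p = 1, n_perm = 1000,
                             seed = 1) {
  n <- nrow(ranked)
  check_number(set_size, "set_size", lower = 1, upper = n - 1, integer = TRUE)
  check_number(n_perm, "n_perm", lower = 1, integer = TRUE)
  aw <- abs(ranked$score)^weight_p
  local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      fast_es(aw, n, sort.int(sample.int(n, set_size)))
    }, numeric(1))
  })
}

#' Leading-edge genes of an enrichment
#'
#' The gene-set members that drive the enrichment score: for a positive ES,
#' members at or before the running-sum peak; for a negative ES, members at
#' or after it. Returned in ranking order.
#'
#' @param ranked The [ranked_genes()] tibble scored by [enrichment_score()].
#' @param members The gene set.
#' @param es,peak_index Results of the prior [enrichment_score()] call.
#' @return Character vector of leading-edge gene ids.
#' @export
leading_edge <- function(ranked, members, es, peak_index) {
  n <- nrow(ranked)
  check_number(peak_index, "peak_index", lower = 1, upper = n, integer = TRUE)
  pos <- which(ranked$gene_id %in% members)
  keep <- if (es >= 0) pos <= peak_index else pos >= peak_index
  ranked$gene_id[pos[keep]]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Scores a ranked gene list against every set in a collection. Sets are
#' restricted to those with `min_size <= |set intersect ranked| <= max_size`.
#' Per set: the enrichment score; a normalized enrichment score
#' `NES = ES / mean(|null ES| of the same sign)` over a gene-label
#' permutation null shared across sets of equal size; a nominal Monte-Carlo
#' p-value with the +1 correction, `p = (1 + #{same-sign null at least as
#' extreme}) / (1 + #same-sign null)` (floor `1/(n_perm + 1)`); a
#' Benjamini-Hochberg FDR q-value across all tested sets; and the
#' leading-edge genes. Pathways with `q_fdr < 0.05` are conventionally
#' called associated with the target lncRNA.
#'
#' @param ranked A [ranked_genes()] tibble.
#' @param collection A [gene_sets()] collection.
#' @param min_size,max_size Size filter on `|set intersect ranked|`
#'   (defaults 5 and 500).
#' @param weight_p Weight exponent (default 1).
#' @param n_perm Permutations per null pool (default 1000).
#' @param seed Master seed; each set size gets a deterministic sub-seed, so
#'   results do not depend on collection order.
#' @return A tibble of class `lnc_enrichment` ordered by `nes` descending,
#'   with columns `pathway`, `size`, `es`, `nes`, `p_nominal`, `q_fdr` and a
#'   `leading_edge` list-column. Sets skipped by the size filter are in
#'   `attr(, "skipped")`; run metadata in `attr(, "run_info")`.
#' @examples
#' rk <- ranked_genes(stats::setNames(10:1 / 10, paste0("g", 1:10)),
#'                    metric = "pearson")
#' gs <- gene_sets(list(TOP = paste0("g", 1:5), MIX = paste0("g", c(2, 9, 4, 7, 6))))
#' run_preranked(rk, gs, min_size = 3, n_perm = 100, seed = 7)
#' @export
run_preranked <- function(ranked, collection, min_size = 5, max_size = 500,
                          weight_p = 1, n_perm = 1000, seed = 1) {
  check_number(min_size, "min_size", lower = 1, integer = TRUE)
  check_number(max_size, "max_size", lower = min_size, integer = TRUE)
  check_number(n_perm, "n_perm", lower = 1, integer = TRUE)
  if (nrow(collection) == 0L) {
    abort("empty gene-set collection.", class = "lncpath_validation_error")
  }
  universe <- ranked$gene_id
  n <- length(universe)
  # intersect(universe, set) keeps the members in ranking order
  used <- lapply(collection$genes, function(g) intersect(universe, g))
  sizes <- lengths(used)
  ok <- sizes >= min_size & sizes <= max_size & sizes < n
  skipped <- tibble(set = collection$set[!ok], size_used = sizes[!ok])
  if (!any(ok)) {
    abort(sprintf("no gene set within the size filter [%d, %d].",
                  min_size, max_size),
          class = "lncpath_empty_result_error")
  }
  sets <- collection$set[ok]
  used <- used[ok]
  sizes <- sizes[ok]

  nulls <- new.env(parent = emptyenv())
  null_for <- function(size) {
    key <- as.character(size)
    if (is.null(nulls[[key]])) {
      nulls[[key]] <- permutation_null(ranked, size, weight_p = weight_p,
                                       n_perm = n_perm,
                                       seed = derive_seed(seed, size))
    }
    nulls[[key]]
  }

  rows <- purrr::map2(used, sizes, function(members, size) {
    sc <- enrichment_score(ranked, members, weight_p = weight_p)
    null <- null_for(size)
    pool <- if (sc$es >= 0) null[null >= 0] else null[null < 0]
    if (length(pool) == 0L) {
      inform(sprintf("no same-sign null score for a set of size %d; NES undefined.",
                     size))
      nes <- NA_real_
      p <- 1
    } else {
      nes <- sc$es / mean(abs(pool))
      p <- (1 + sum(abs(pool) >= abs(sc$es))) / (1 + length(pool))
    }
    tibble(size = size, es = sc$es, nes = nes, p_nominal = p,
           n_perm_effective = length(pool),
           leading_edge = list(leading_edge(ranked, members, sc$es,
                                            sc$peak_index)))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, pathway = sets, .before = 1)
  out$q_fdr <- stats::p.adjust(out$p_nominal, method = "BH")
  out <- out[order(-replace(out$nes, is.na(out$nes), -Inf),
                   out$pathway), ]
  out <- out[c("pathway", "size", "es", "nes", "p_nominal", "q_fdr",
               "n_perm_effective", "leading_edge")]
  structure(out,
            skipped = skipped,
            run_info = list(metric = attr(ranked, "metric"),
                            target_id = attr(ranked, "target_id"),
                            weight_p = weight_p, n_perm = n_perm,
                            min_size = min_size, max_size = max_size,
                            seed = seed),
            class = c("lnc_enrichment", class(tibble())))
}

#' Read / write an enrichment result table
#'
#' TSV with columns pathway, size, es, nes, p_nominal, q_fdr and
#' comma-joined leading-edge gene ids, ordered by NES descending.
#'
#' @param res A `lnc_enrichment` tibble.
#' @param path Output path.
#' @return `path` ([write_enrichment()]) or a tibble ([read_enrichment()]).
#' @export
write_enrichment <- function(res, path) {
  flat <- as_tibble(res)
  flat$leading_edge <- vapply(res$leading_edge, paste, character(1),
                              collapse = ",")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("result file not found: %s", path),
          class = "lncpath_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  df$leading_edge <- strsplit(df$leading_edge, ",", fixed = TRUE)
  structure(df, class = c("lnc_enrichment", class(tibble())))
}
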