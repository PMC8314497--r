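#' Configuration for a synthetic TCGA-like cohort
#'
#' The generator plants a linear lncRNA-pathway association in log2
#' expression space: the target lncRNA's log2 abundance is Gaussian, and
#' each "responsive" coding gene follows
#' `baseline + effect_beta * lnc_log2 + Normal(0, noise_sd)`, while null
#' genes are baseline plus noise. The linear-Gaussian model makes the
#' expected guilt-by-association correlation analytic,
#' `beta * sd_lnc / sqrt(beta^2 * sd_lnc^2 + noise_sd^2)`, so recovery
#' expectations are derivable rather than guessed. A `dropout_fraction` of
#' samples can be zeroed on the raw scale to emulate lncRNAs expressed in
#' only part of a cancer cohort.
#'
#' Defaults describe the validation cohort used throughout the package:
#' 200 samples, 2000 coding genes, one planted 30-gene set with unit effect
#' and noise SD 0.5, and 49 null gene sets.
#'
#' @param n_samples Number of tumor samples (>= 8).
#' @param n_genes Number of coding genes.
#' @param planted_sets List of lists with fields `name`, `size`,
#'   `effect_beta` and `fraction_responsive` (fraction of members that
#'   carry the effect).
#' @param n_null_sets Number of gene sets drawn from non-responsive genes.
#' @param null_set_size_range Length-2 integer range of null set sizes.
#' @param noise_sd Residual SD of coding-gene log2 abundance.
#' @param lnc_mean,lnc_sd Mean and SD of the target lncRNA's log2 abundance.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 abundance
#'   distribution.
#' @param dropout_fraction Fraction of samples with zero lncRNA abundance on
#'   the raw scale.
#' @param seed Integer seed driving all randomness.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 200, n_genes = 2000,
                             planted_sets = list(list(
                               name = "PLANTED_UP", size = 30,
                               effect_beta = 1, fraction_responsive = 1)),
                             n_null_sets = 49,
                             null_set_size_range = c(10, 50),
                             noise_sd = 0.5, lnc_mean = 3, lnc_sd = 1,
                             baseline_mean = 5, baseline_sd = 1,
                             dropout_fraction = 0, seed = 1) {
  check_number(n_samples, "n_samples", lower = 8, integer = TRUE)
  check_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_number(n_null_sets, "n_null_sets", lower = 0, integer = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  check_number(dropout_fraction, "dropout_fraction", lower = 0, upper = 1)
  check_number(lnc_sd, "lnc_sd", lower = 0, strict_lower = TRUE)
  for (ps in planted_sets) {
    stopifnot(is.character(ps$name), ps$size >= 1,
              ps$fraction_responsive >= 0, ps$fraction_responsive <= 1)
    if (ps$size > n_genes) {
      abort("planted set larger than the gene pool.",
            class = "lncpath_config_error")
    }
  }
  if (sum(vapply(planted_sets, `[[`, numeric(1), "size")) > n_genes) {
    abort("planted sets exceed the gene pool.",
          class = "lncpath_config_error")
  }
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 planted_sets = planted_sets, n_null_sets = n_null_sets,
                 null_set_size_range = null_set_size_range,
                 noise_sd = noise_sd, lnc_mean = lnc_mean, lnc_sd = lnc_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 dropout_fraction = dropout_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic lncRNA/coding-gene cohort with planted signal
#'
#' Emits paired lncRNA and coding expression matrices on the raw abundance
#' scale (`2^x - 1`, floored at 0, `log_transformed = FALSE`), a gene-set
#' collection containing the planted and null sets, and the ground truth.
#' Sample ids are TCGA-style barcodes; the lncRNA matrix carries longer
#' aliquot barcodes than the coding matrix, as real annotation sources do,
#' so [harmonize_samples()] is exercised end to end. Four decoy lncRNAs
#' with no planted signal accompany the target.
#'
#' @param config A [synthetic_config()].
#' @return A list with `lnc` and `coding` expression matrices, `sets` (a
#'   [gene_sets()] collection), `truth` (tibbles `sets` and `genes`) and
#'   `target_id` (`"LNC_TARGET"`).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_samples = 30, n_genes = 100,
#'   planted_sets = list(list(name = "P", size = 10, effect_beta = 1,
#'                            fraction_responsive = 1)),
#'   n_null_sets = 3, null_set_size_range = c(5, 10), seed = 42))
#' cohort$truth$sets
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  local_seed(cf$seed, {
    n <- cf$n_samples
    g <- cf$n_genes
    base_ids <- sprintf("TCGA-SY-%04d-01A", seq_len(n))
    lnc_sample_ids <- paste0(base_ids, "-11R-A001-07")
    gene_ids <- sprintf("G%05d", seq_len(g))

    lnc_log2 <- stats::rnorm(n, cf$lnc_mean, cf$lnc_sd)
    n_drop <- round(cf$dropout_fraction * n)
    if (n_drop > 0) {
      lnc_log2[sample.int(n, n_drop)] <- 0
    }

    # assign planted members from the front of the gene pool
    sets_truth <- list()
    responsive <- logical(g)
    beta_vec <- numeric(g)
    cursor <- 0L
    member_ids <- list()
    for (ps in cf$planted_sets) {
      idx <- cursor + seq_len(ps$size)
      cursor <- cursor + ps$size
      n_resp <- round(ps$fraction_responsive * ps$size)
      resp_idx <- idx[seq_len(n_resp)]
      responsive[resp_idx] <- TRUE
      beta_vec[resp_idx] <- ps$effect_beta
      member_ids[[ps$name]] <- gene_ids[idx]
      sets_truth[[ps$name]] <- tibble(
        set = ps$name, gene_id = gene_ids[idx],
        effect_beta = ps$effect_beta,
        responsive = idx %in% resp_idx)
    }

    baseline <- stats::rnorm(g, cf$baseline_mean, cf$baseline_sd)
    noise <- matrix(stats::rnorm(g * n, 0, cf$noise_sd), nrow = g)
    coding_log2 <- baseline + outer(beta_vec, lnc_log2) + noise
    coding_raw <- pmax(2^coding_log2 - 1, 0)
    dimnames(coding_raw) <- list(gene_ids, base_ids)

    null_pool <- which(!responsive & !(seq_len(g) <= cursor))
    if (cf$n_null_sets > 0) {
      if (length(null_pool) < max(cf$null_set_size_range)) {
        abort("not enough null genes for the requested null sets.",
              class = "lncpath_config_error")
      }
      for (i in seq_len(cf$n_null_sets)) {
        sz <- sample(seq(cf$null_set_size_range[1],
                         cf$null_set_size_range[2]), 1)
        member_ids[[sprintf("NULL_SET_%02d", i)]] <-
          gene_ids[sample(null_pool, sz)]
      }
    }

    # target lncRNA plus decoys with independent expression
    n_decoy <- 4L
    decoy_log2 <- matrix(stats::rnorm(n_decoy * n, cf$lnc_mean, cf$lnc_sd),
                         nrow = n_decoy)
    lnc_raw <- rbind(pmax(2^lnc_log2 - 1, 0), pmax(2^decoy_log2 - 1, 0))
    dimnames(lnc_raw) <- list(c("LNC_TARGET", sprintf("LNC_DECOY%d", seq_len(n_decoy))),
                              lnc_sample_ids)

    list(
      lnc = as_expr_mat(lnc_raw, cohort = "SYNTH"),
      coding = as_expr_mat(coding_raw, cohort = "SYNTH"),
      sets = gene_sets(member_ids, description = "synthetic"),
      truth = list(sets = dplyr::bind_rows(sets_truth),
                   genes = tibble(gene_id = gene_ids,
                                  responsive = responsive,
                                  effect_beta = beta_vec)),
      target_id = "LNC_TARGET"
    )
  })
}

#' Catalog of degenerate inputs and the handling each must elicit
#'
#' Small in-memory fixtures covering the failure and edge modes of the
#' pipeline: a zero-variance coding gene (excluded from correlation
#' ranking), an all-tied lncRNA vector (quantile split falls back to sample
#' id order), disjoint sample ids (harmonization error), duplicate gene
#' rows in a matrix file (collapsed to the highest-mean row) and a GMT line
#' with no members (format error). Each entry carries an `expected`
#' description of the documented behavior.
#'
#' @return Named list of fixtures.
#' @export
degenerate_fixtures <- function() {
  m4 <- function(v, genes, samples) {
    as_expr_mat(matrix(v, nrow = length(genes), byrow = TRUE,
                       dimnames = list(genes, samples)))
  }
  sam8 <- sprintf("S%02d", 1:8)
  list(
    zero_variance_gene = list(
      coding = log2_transform(m4(c(1, 2, 3, 4, 5, 5, 5, 5), c("GV", "GC"),
                                 c("S1", "S2", "S3", "S4"))),
      target = stats::setNames(c(4, 3, 2, 1), c("S1", "S2", "S3", "S4")),
      expected = "rank_by_gba excludes the constant gene and reports the count"
    ),
    all_tied_lnc = list(
      target = stats::setNames(rep(2, 8), sam8),
      expected = "split_by_quantile fills both groups in sample-id order, sizes ceiling(q*n)"
    ),
    disjoint_samples = list(
      lnc = m4(c(1, 2), "L1", c("TCGA-AA-0001-01A", "TCGA-AA-0002-01A")),
      coding = m4(c(3, 4), "G1", c("TCGA-BB-0001-01A", "TCGA-BB-0002-01A")),
      expected = "harmonize_samples raises a harmonization error naming example ids"
    ),
    duplicate_gene_rows = list(
      tsv_lines = c("gene_id\tS1\tS2", "A\t5\t5", "A\t2\t2", "B\t1\t1"),
      expected = "read_expression_matrix keeps the duplicate row with the higher mean (5)"
    ),
    empty_gene_set_line = list(
      gmt_lines = c("SET1\tdesc\tA\tB", "SET2\tdesc"),
      expected = "read_gmt raises a format error naming the offending line"
    )
  )
}
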