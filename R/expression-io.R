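#' Expression matrix objects
#'
#' An expression matrix is a tibble with a `gene_id` column followed by one
#' numeric column per sample, carrying `cohort` (free-text label, e.g.
#' `"PRAD"`) and `log_transformed` (whether values are on log2(x + 1) scale)
#' as attributes. Abundances are FPKM/TPM-like: non-negative on the raw
#' scale, finite everywhere.
#'
#' @param x A data frame with a `gene_id` character column and numeric sample
#'   columns, or a numeric matrix with gene rownames and sample colnames.
#' @param cohort Free-text cohort label.
#' @param log_transformed Logical; `TRUE` if values are already log2(x + 1).
#' @return A tibble of class `expr_mat`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' as_expr_mat(m, cohort = "TOY")
#' @export
as_expr_mat <- function(x, cohort = "", log_transformed = FALSE) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs gene rownames and sample colnames.",
            class = "lncpath_validation_error")
    }
    x <- tibble(gene_id = rownames(x), as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x, .name_repair = "minimal")
  if (!"gene_id" %in% names(x)) {
    names(x)[1] <- "gene_id"
  }
  x$gene_id <- as.character(x$gene_id)
  out <- new_expr_mat(x, cohort = cohort, log_transformed = log_transformed)
  validate_expr_mat(out)
}

new_expr_mat <- function(x, cohort, log_transformed) {
  structure(x,
            cohort = cohort,
            log_transformed = isTRUE(log_transformed),
            class = c("expr_mat", class(tibble())))
}

validate_expr_mat <- function(m) {
  if (nrow(m) == 0L || ncol(m) < 2L) {
    abort("expression matrix is empty (needs >= 1 gene and >= 1 sample).",
          class = "lncpath_validation_error")
  }
  if (anyDuplicated(m$gene_id)) {
    abort("duplicate gene ids in expression matrix; collapse them first.",
          class = "lncpath_validation_error")
  }
  sam <- sample_ids(m)
  if (anyDuplicated(sam)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sam[duplicated(sam)]), collapse = ", ")),
          class = "lncpath_validation_error")
  }
  v <- expr_values(m)
  if (!all(is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite abundance at gene '%s', sample '%s'.",
                  m$gene_id[bad[1]], sam[bad[2]]),
          class = "lncpath_validation_error")
  }
  if (!is_logged(m) && any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative abundance at gene '%s', sample '%s' on raw scale.",
                  m$gene_id[bad[1]], sam[bad[2]]),
          class = "lncpath_validation_error")
  }
  m
}

#' @rdname as_expr_mat
#' @export
is_logged <- function(x) isTRUE(attr(x, "log_transformed"))

#' @rdname as_expr_mat
#' @export
sample_ids <- function(x) names(x)[names(x) != "gene_id"]

#' Extract the numeric abundance matrix (genes x samples)
#'
#' @param x An `expr_mat`.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
expr_values <- function(x) {
  v <- as.matrix(x[which(names(x) != "gene_id")])
  storage.mode(v) <- "double"
  rownames(v) <- x$gene_id
  v
}

#' Read a delimited expression matrix
#'
#' Parses a genes x samples (or samples x genes) table with identifiers in
#' the first row and column. Duplicate gene rows are collapsed by keeping the
#' row with the highest mean abundance, the standard rule for transcript-level
#' duplicates.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator (default tab).
#' @param genes_in_rows `FALSE` if the file stores samples in rows.
#' @param cohort,log_transformed Metadata recorded on the result.
#' @return An [as_expr_mat()] tibble.
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   genes_in_rows = TRUE,
                                   cohort = "", log_transformed = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("expression matrix file not found: %s", path),
          class = "lncpath_io_error")
  }
  raw <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(.default = "c"),
                           progress = FALSE, name_repair = "minimal")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort(sprintf("empty expression matrix in %s", path),
          class = "lncpath_validation_error")
  }
  ids <- as.character(raw[[1]])
  num <- as.matrix(raw[-1])
  col_ids <- colnames(num)
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "malformed numeric cell at row '%s', column '%s' in %s",
      ids[bad[1]], col_ids[bad[2]], path),
      class = "lncpath_parse_error")
  }
  rownames(num) <- ids
  if (!genes_in_rows) {
    num <- t(num)
  }
  num <- collapse_duplicate_genes(num)
  as_expr_mat(num, cohort = cohort, log_transformed = log_transformed)
}

# Keep, for each duplicated gene id, the row with the highest mean abundance
# (ties: first occurrence).
collapse_duplicate_genes <- function(num) {
  ids <- rownames(num)
  if (!anyDuplicated(ids)) {
    return(num)
  }
  means <- rowMeans(num)
  keep <- unlist(lapply(split(seq_along(ids), factor(ids, levels = unique(ids))),
                        function(idx) idx[which.max(means[idx])]),
                 use.names = FALSE)
  dropped <- length(ids) - length(keep)
  inform(sprintf("collapsed %d duplicate gene row(s), keeping highest-mean rows.",
                 dropped))
  num[sort(keep), , drop = FALSE]
}

#' Write an expression matrix as delimited text
#'
#' @param m An `expr_mat`.
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, delimiter = "\t") {
  readr::write_delim(as_tibble(m), path, delim = delimiter, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line, tab-separated: name, description, then member genes.
#' Duplicate members within a line are dropped; duplicate set names and empty
#' member lists are errors.
#'
#' @param path Path to a GMT file.
#' @return A tibble of class `gene_sets` with columns `set`, `description`
#'   and a `genes` list-column, plus a `source_path` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GMT file not found: %s", path), class = "lncpath_io_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(sprintf("GMT file %s has no gene sets.", path),
          class = "lncpath_validation_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    abort(sprintf("GMT line %d has %d field(s); need name, description, members.",
                  which(n_fields < 3L)[1], n_fields[which(n_fields < 3L)[1]]),
          class = "lncpath_parse_error")
  }
  sets <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(sets)) {
    abort(paste0("duplicate gene-set name(s): ",
                 paste(unique(sets[duplicated(sets)]), collapse = ", ")),
          class = "lncpath_validation_error")
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(lengths(genes) == 0L)) {
    abort(sprintf("gene set '%s' has no members.",
                  sets[which(lengths(genes) == 0L)[1]]),
          class = "lncpath_validation_error")
  }
  new_gene_sets(tibble(
    set = sets,
    description = vapply(fields, `[[`, character(1), 2L),
    genes = genes
  ), source_path = path)
}

new_gene_sets <- function(x, source_path = "") {
  structure(x, source_path = source_path,
            class = c("gene_sets", class(tibble())))
}

#' Build a gene-set collection from a named list
#'
#' @param sets Named list of character vectors of member genes.
#' @param description Optional descriptions, recycled.
#' @return A `gene_sets` tibble, as from [read_gmt()].
#' @export
gene_sets <- function(sets, description = "") {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list.",
          class = "lncpath_validation_error")
  }
  genes <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(genes) == 0L)) {
    abort("every gene set must be non-empty.",
          class = "lncpath_validation_error")
  }
  new_gene_sets(tibble(
    set = names(sets),
    description = rep_len(as.character(description), length(sets)),
    genes = unname(genes)
  ))
}

#' @rdname read_gmt
#' @param collection A `gene_sets` tibble.
#' @export
gene_set_list <- function(collection) {
  stats::setNames(collection$genes, collection$set)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_sets` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- mapply(function(s, d, g) paste(c(s, d, g), collapse = "\t"),
                  collection$set, collection$description, collection$genes)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Match two matrices on shared samples (TCGA-barcode aware)
#'
#' lncRNA and coding matrices quantified by different projects often label
#' the same aliquot with barcodes of different lengths. Sample ids are
#' truncated to the first `barcode_fields` dash-separated fields (4 reaches
#' the sample/vial field of a TCGA barcode) and both matrices are subset and
#' column-ordered to the intersection of the truncated ids.
#'
#' @param lnc,coding `expr_mat` tibbles.
#' @param barcode_fields Number of leading dash-fields to keep when matching.
#' @return A list with harmonized `lnc` and `coding` matrices (columns renamed
#'   to the truncated ids, identical order) and `n_shared`.
#' @export
harmonize_samples <- function(lnc, coding, barcode_fields = 4) {
  check_number(barcode_fields, "barcode_fields", lower = 1, integer = TRUE)
  key_l <- truncate_barcode(sample_ids(lnc), barcode_fields)
  key_c <- truncate_barcode(sample_ids(coding), barcode_fields)
  if (anyDuplicated(key_l) || anyDuplicated(key_c)) {
    abort("barcode truncation produced duplicate sample ids; increase `barcode_fields`.",
          class = "lncpath_validation_error")
  }
  shared <- intersect(key_l, key_c)
  if (length(shared) == 0L) {
    abort(sprintf(
      "no shared samples after barcode truncation (e.g. lnc '%s' vs coding '%s').",
      key_l[1], key_c[1]),
      class = "lncpath_harmonization_error")
  }
  inform(sprintf("harmonized on %d shared sample(s).", length(shared)))
  list(
    lnc = subset_rename(lnc, key_l, shared),
    coding = subset_rename(coding, key_c, shared),
    n_shared = length(shared)
  )
}

truncate_barcode <- function(ids, k) {
  vapply(strsplit(ids, "-", fixed = TRUE),
         function(f) paste(f[seq_len(min(k, length(f)))], collapse = "-"),
         character(1))
}

subset_rename <- function(m, keys, shared) {
  old <- sample_ids(m)[match(shared, keys)]
  out <- m[c("gene_id", old)]
  names(out) <- c("gene_id", shared)
  new_expr_mat(out, cohort = attr(m, "cohort"),
               log_transformed = is_logged(m))
}

#' Extract one gene's abundance vector
#'
#' @param m An `expr_mat`.
#' @param target_id Gene identifier to extract.
#' @param case_sensitive Match the id exactly (`TRUE`) or ignoring case.
#' @return Named numeric vector indexed by sample id, in column order.
#' @export
extract_target_vector <- function(m, target_id, case_sensitive = TRUE) {
  idx <- if (case_sensitive) {
    match(target_id, m$gene_id)
  } else {
    match(tolower(target_id), tolower(m$gene_id))
  }
  if (is.na(idx)) {
    near <- m$gene_id[order(utils::adist(tolower(target_id), tolower(m$gene_id)))]
    abort(sprintf("gene '%s' not found; nearest ids: %s", target_id,
                  paste(utils::head(near, 5), collapse = ", ")),
          class = "lncpath_lookup_error")
  }
  v <- expr_values(m)[idx, ]
  stats::setNames(as.numeric(v), sample_ids(m))
}

#' Put an expression matrix on log2(x + 1) scale
#'
#' Fold changes and Pearson correlations on raw FPKM/TPM are dominated by
#' high-abundance outliers, so the ranking metrics operate on
#' log2(value + pseudocount).
#'
#' @param m An `expr_mat` with `log_transformed = FALSE`.
#' @param pseudocount Positive offset added before the log (default 1).
#' @return The transformed `expr_mat` with `log_transformed = TRUE`.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  check_number(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  if (is_logged(m)) {
    abort("matrix is already log-transformed.",
          class = "lncpath_validation_error")
  }
  out <- m
  for (s in sample_ids(m)) {
    out[[s]] <- log2(m[[s]] + pseudocount)
  }
  new_expr_mat(out, cohort = attr(m, "cohort"), log_transformed = TRUE)
}
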