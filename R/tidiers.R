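#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an enrichment result
#'
#' @param x A `lnc_enrichment` tibble.
#' @param ... Unused.
#' @return A plain tibble with the leading edge as a comma-joined string
#'   plus its size.
#' @method tidy lnc_enrichment
#' @export
tidy.lnc_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  out$leading_edge_size <- lengths(out$leading_edge)
  out$leading_edge <- vapply(out$leading_edge, paste, character(1),
                             collapse = ",")
  out
}

#' One-row summary of an enrichment run
#'
#' @param x A `lnc_enrichment` tibble.
#' @param ... Unused.
#' @return A one-row tibble: target, metric, sets tested and significant at
#'   `q_fdr < 0.05`, permutations and seed.
#' @method glance lnc_enrichment
#' @export
glance.lnc_enrichment <- function(x, ...) {
  info <- attr(x, "run_info") %||% list()
  tibble(
    target_id = info$target_id %||% NA_character_,
    metric = info$metric %||% NA_character_,
    n_sets_tested = nrow(x),
    n_sets_skipped = nrow(attr(x, "skipped") %||% tibble()),
    n_significant = sum(x$q_fdr < 0.05, na.rm = TRUE),
    n_perm = info$n_perm %||% NA_integer_,
    seed = info$seed %||% NA_integer_
  )
}

#' @method tidy lnc_similarity
#' @export
tidy.lnc_similarity <- function(x, ...) as_tibble(x)

#' @export
print.lnc_enrichment <- function(x, ...) {
  info <- attr(x, "run_info")
  if (!is.null(info)) {
    cat(sprintf("# lncRNA pathway enrichment: target '%s', metric %s, %d permutations\n",
                info$target_id, info$metric, info$n_perm))
  }
  NextMethod()
}
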