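#' Bubble chart of enrichment results across runs
#'
#' The standard summary figure: gene sets on the vertical axis, one column
#' per run (target lncRNA x ranking metric), point color by normalized
#' enrichment score and point size by `-log10(q_fdr)` (capped at the
#' permutation floor of the run). Sets are kept if significant at
#' `q_fdr < q_threshold` in at least one run and ordered by mean NES, so the
#' layout is deterministic.
#'
#' @param results A `lnc_enrichment` tibble or a named list of them; names
#'   label the runs (defaults to `target/metric` from run metadata).
#' @param top_k Keep at most this many gene sets (default 20).
#' @param q_threshold Significance cutoff for inclusion (default 0.05).
#' @param file Optional image path (`.png`, `.pdf` or `.svg`); when given
#'   the figure is saved and a sidecar TSV of exactly the plotted numbers is
#'   written next to it, so the plot is never the only record.
#' @return A ggplot; the plotted table is in `attr(, "plot_data")`.
#' @export
plot_enrichment <- function(results, top_k = 20, q_threshold = 0.05,
                            file = NULL) {
  if (inherits(results, "lnc_enrichment")) {
    results <- list(results)
  }
  labs <- names(results) %||% vapply(results, function(r) {
    info <- attr(r, "run_info") %||% list()
    paste0(info$target_id %||% "run", "/", info$metric %||% "?")
  }, character(1))
  labs <- make.unique(labs)
  df <- dplyr::bind_rows(lapply(seq_along(results), function(i) {
    r <- results[[i]]
    info <- attr(r, "run_info") %||% list(n_perm = 1000)
    floor_q <- 1 / ((info$n_perm %||% 1000) + 1)
    tibble(run = labs[i], pathway = r$pathway, nes = r$nes,
           q_fdr = r$q_fdr,
           neg_log10_q = -log10(pmax(r$q_fdr, floor_q)))
  }))
  keep <- df |>
    dplyr::summarise(min_q = min(.data$q_fdr, na.rm = TRUE),
                     mean_nes = mean(.data$nes, na.rm = TRUE),
                     .by = "pathway") |>
    dplyr::filter(.data$min_q < q_threshold) |>
    dplyr::arrange(dplyr::desc(.data$mean_nes)) |>
    utils::head(top_k)

  if (nrow(keep) == 0L) {
    warn(sprintf("no gene set reaches q_fdr < %g in any run.", q_threshold))
    p <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0,
                        label = sprintf("no gene set with q_fdr < %g",
                                        q_threshold)) +
      ggplot2::theme_void()
    plot_df <- df[0, ]
  } else {
    plot_df <- df[df$pathway %in% keep$pathway, ]
    plot_df$pathway <- factor(plot_df$pathway, levels = rev(keep$pathway))
    p <- ggplot2::ggplot(plot_df,
                         ggplot2::aes(x = .data$run, y = .data$pathway,
                                      size = .data$neg_log10_q,
                                      color = .data$nes)) +
      ggplot2::geom_point() +
      ggplot2::scale_color_gradient2(low = "#2166AC", mid = "grey85",
                                     high = "#B2182B", midpoint = 0) +
      ggplot2::labs(x = NULL, y = NULL, color = "NES",
                    size = expression(-log[10] * "(q)")) +
      ggplot2::theme_bw()
  }
  attr(p, "plot_data") <- tibble::as_tibble(plot_df)
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 5)
    readr::write_tsv(dplyr::mutate(tibble::as_tibble(plot_df),
                                   pathway = as.character(.data$pathway)),
                     paste0(tools::file_path_sans_ext(file), "_data.tsv"),
                     progress = FALSE)
  }
  p
}

#' @rdname plot_enrichment
#' @param object A `lnc_enrichment` tibble.
#' @param ... Passed to [plot_enrichment()].
#' @method autoplot lnc_enrichment
#' @export
autoplot.lnc_enrichment <- function(object, ...) {
  plot_enrichment(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
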