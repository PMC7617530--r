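#' Volcano plot of gene-level damage enrichment
#'
#' ddG_rank difference against -log10 p, with the Bonferroni threshold drawn
#' per structure source. Genes to the right of zero are enriched in
#' structurally damaging mutations.
#'
#' @param x Stacked `gene_enrichment` rows (after [add_significance()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_enrichment <- function(x, ...) {
  df <- as_tibble(x) |> filter(!is.na(.data$p_value))
  thr <- attr(x, "thresholds", exact = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ddg_rank_diff,
                                        y = -log10(.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant %in% TRUE),
                        alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey50"),
                                 name = "significant") +
    ggplot2::facet_wrap(ggplot2::vars(.data$structure_source)) +
    ggplot2::labs(x = "ddG_rank difference (observed - unobserved)",
                  y = "-log10 p (Wilcoxon)")
  if (!is.null(thr) && any(!is.na(thr$threshold))) {
    p <- p + ggplot2::geom_hline(
      data = thr[!is.na(thr$threshold), ],
      ggplot2::aes(yintercept = -log10(.data$threshold)),
      linetype = "dashed")
  }
  p
}

#' @rdname autoplot.gene_enrichment
#' @export
plot_volcano <- function(x, ...) autoplot.gene_enrichment(x, ...)

#' Distribution of EDC values
#'
#' Boxplot of EDC per dataset (optionally split by gene role when a `role`
#' column has been joined on), with the random-expectation line at 1.
#'
#' @param x `edc_result` rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edc_result <- function(x, ...) {
  df <- as_tibble(x) |> filter(!is.na(.data$edc))
  grouping <- if ("role" %in% names(df)) "role" else "dataset"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[grouping]], y = .data$edc)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "EDC")
}

#' @rdname autoplot.edc_result
#' @export
plot_edc <- function(x, ...) autoplot.edc_result(x, ...)

#' Rank-normalised stability landscape overview
#'
#' Histogram of ddG_rank (flat by construction) overlaid per protein, and
#' useful mainly to inspect observed-mutation subsets: pass `observed` to
#' highlight where the observed mutations sit on the rank scale.
#'
#' @param x A `stability_table`.
#' @param observed Optional tibble of observed variants (`protein_id`,
#'   `position`, `ref_aa`, `alt_aa`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_table <- function(x, observed = NULL, ...) {
  df <- as_tibble(x)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ddg_rank)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), fill = "grey70",
                            colour = "white") +
    ggplot2::labs(x = "ddG_rank", y = "possible substitutions")
  if (!is.null(observed)) {
    hl <- df |>
      inner_join(as_tibble(observed),
                 by = intersect(c("protein_id", "position", "ref_aa",
                                  "alt_aa"), names(observed)))
    p <- p + ggplot2::geom_rug(data = hl, colour = "#c0392b")
  }
  p
}

#' @rdname autoplot.stability_table
#' @export
plot_rank_landscape <- function(x, observed = NULL, ...) {
  autoplot.stability_table(x, observed = observed, ...)
}
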