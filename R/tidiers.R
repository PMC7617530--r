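#' @export
tidy.gene_enrichment <- function(x, ...) {
  as_tibble(x) |>
    select("protein_id", estimate = "ddg_rank_diff", p.value = "p_value",
           "n_observed", "n_unobserved", "structure_source", "significant")
}

#' @export
glance.gene_enrichment <- function(x, ...) {
  thr <- attr(x, "thresholds", exact = TRUE)
  as_tibble(x) |>
    group_by(.data$structure_source) |>
    summarise(n_genes = n(), n_tested = sum(!is.na(.data$p_value)),
              n_significant = sum(.data$significant %in% TRUE),
              .groups = "drop") |>
    left_join(if (!is.null(thr)) thr[, c("structure_source", "threshold")]
              else tibble(structure_source = character(),
                          threshold = numeric()),
              by = "structure_source")
}

#' @export
tidy.edc_result <- function(x, ...) {
  as_tibble(x) |>
    select("protein_id", "dataset", "recurrent", estimate = "edc",
           "n_mutated", "n_unmutated", "excluded_low_confidence",
           "skip_reason")
}

#' @export
glance.edc_result <- function(x, ...) {
  as_tibble(x) |>
    summarise(n_proteins = n(), n_reported = sum(!is.na(.data$edc)),
              n_skipped = sum(is.na(.data$edc)),
              median_edc = median(.data$edc, na.rm = TRUE),
              frac_clustered = mean(.data$edc > 1, na.rm = TRUE))
}

#' @export
tidy.group_comparison <- function(x, ...) {
  as_tibble(x) |>
    select("group_a", "group_b", method = "statistic", "estimate",
           p.value = "p_value", "n_a", "n_b")
}

#' @export
tidy.candidate_rankings <- function(x, ...) {
  bind_rows(
    x$damage |>
      transmute(list = "damage", .data$rank, .data$protein_id,
                score = -log10(.data$p_value)),
    x$clustering |>
      transmute(list = "clustering", .data$rank, .data$protein_id,
                score = .data$edc))
}

#' @export
glance.candidate_rankings <- function(x, ...) {
  tibble(n_damage = nrow(x$damage), n_clustering = nrow(x$clustering),
         n_overlap = length(x$overlap),
         top_n = attr(x, "top_n", exact = TRUE))
}

#' @export
print.candidate_rankings <- function(x, ...) {
  cat("Candidate rankings (top ", attr(x, "top_n", exact = TRUE), ")\n",
      sep = "")
  cat("- damage-enriched genes:", nrow(x$damage), "\n")
  cat("- clustering (recurrent EDC) genes:", nrow(x$clustering), "\n")
  cat("- overlap:", if (length(x$overlap)) paste(x$overlap, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
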