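#' Gene-level enrichment in structurally damaging mutations
#'
#' Splits a protein's rank-normalised stability landscape into the
#' substitutions observed as mutations and the possible-but-unobserved rest,
#' and reports the difference of mean ddG_rank (observed minus unobserved)
#' together with a two-sided rank-sum p-value. Positive differences mean the
#' observed mutations are more structurally damaging than expected under
#' random mutation; negative differences mean they are milder. Observed keys
#' absent from the landscape are dropped and counted in the `n_dropped`
#' attribute.
#'
#' @param table A `stability_table` for one protein (see [ddg_rank()]).
#' @param observed Tibble of observed variants with `position`, `ref_aa`,
#'   `alt_aa` (extra columns ignored).
#' @param structure_source `"experimental"` or `"predicted"`, echoed into
#'   the result.
#' @param exact_limit Passed to [wilcoxon_two_sample()].
#' @return One-row `gene_enrichment` tibble: `protein_id`, `ddg_rank_diff`,
#'   `p_value`, `n_observed`, `n_unobserved`, `structure_source`,
#'   `significant` (`NA` until [add_significance()] is applied),
#'   `skip_reason`.
#' @export
gene_damage_enrichment <- function(table, observed,
                                   structure_source = c("predicted",
                                                        "experimental"),
                                   exact_limit = 40) {
  structure_source <- match.arg(structure_source)
  pid <- unique(table$protein_id)
  if (length(pid) != 1) abort("stability table must cover a single protein.")
  obs_keys <- as_tibble(observed) |>
    distinct(.data$position, .data$ref_aa, .data$alt_aa) |>
    mutate(.obs = TRUE)
  joined <- as_tibble(table) |>
    left_join(obs_keys, by = c("position", "ref_aa", "alt_aa"))
  joined$.obs[is.na(joined$.obs)] <- FALSE
  n_dropped <- nrow(obs_keys) - sum(joined$.obs)
  a <- joined$ddg_rank[joined$.obs]
  b <- joined$ddg_rank[!joined$.obs]
  row <- function(diff, p, skip = NA_character_) {
    structure(
      tibble(protein_id = pid, ddg_rank_diff = diff, p_value = p,
             n_observed = length(a), n_unobserved = length(b),
             structure_source = structure_source, significant = NA,
             skip_reason = skip),
      class = c("gene_enrichment", class(tibble())), n_dropped = n_dropped)
  }
  if (length(a) == 0 || length(b) == 0) {
    return(row(NA_real_, NA_real_, "observed or unobserved side empty"))
  }
  w <- wilcoxon_two_sample(a, b, exact_limit = exact_limit)
  row(mean(a) - mean(b), w$p_value)
}

#' Flag Bonferroni-significant gene-level results
#'
#' `N` is the number of genes actually tested (non-missing p-values) within
#' each structure source, computed from the data at hand; a result is
#' significant when `p <= alpha / N`. The per-source thresholds are recorded
#' in the `thresholds` attribute.
#'
#' @param results Stacked `gene_enrichment` rows.
#' @param alpha Family-wise error rate, default 0.05.
#' @return The input with the `significant` column filled.
#' @export
add_significance <- function(results, alpha = 0.05) {
  cls <- class(results)
  out <- results |>
    as_tibble() |>
    group_by(.data$structure_source) |>
    mutate(significant = if (sum(!is.na(.data$p_value)) > 0) {
      .data$p_value <= bonferroni_threshold(alpha,
                                            sum(!is.na(.data$p_value)))
    } else NA) |>
    ungroup()
  thr <- out |>
    group_by(.data$structure_source) |>
    summarise(n_tested = sum(!is.na(.data$p_value)),
              threshold = ifelse(.data$n_tested > 0,
                                 alpha / .data$n_tested, NA_real_),
              .groups = "drop")
  structure(out, class = cls, alpha = alpha, thresholds = thr)
}

#' Compare a numeric property between two mutation groups
#'
#' Two-sided Wilcoxon comparison of a value (typically ddG_rank) between two
#' dataset labels, reporting the difference in means as the estimate.
#'
#' @param data Tibble with at least `dataset` and the value column.
#' @param value Name of the numeric column to compare.
#' @param group_a,group_b Dataset labels.
#' @param exact_limit Passed to [wilcoxon_two_sample()].
#' @return One-row `group_comparison` tibble.
#' @export
compare_groups <- function(data, value, group_a, group_b, exact_limit = 40) {
  a <- data[[value]][data$dataset == group_a]
  b <- data[[value]][data$dataset == group_b]
  w <- wilcoxon_two_sample(a, b, exact_limit = exact_limit)
  structure(
    tibble(group_a = group_a, group_b = group_b, statistic = "wilcoxon",
           estimate = mean(a) - mean(b), p_value = w$p_value,
           n_a = length(a), n_b = length(b)),
    class = c("group_comparison", class(tibble())))
}

#' Compare a category's prevalence between two mutation groups
#'
#' Fisher's exact test on the 2x2 table of (in category vs not) by (group a
#' vs group b), e.g. interior+interface location in cancer vs benign
#' mutations. The estimate is the sample odds ratio.
#'
#' @param data Tibble with `dataset` and a logical/categorical column.
#' @param category Name of a logical column (`TRUE` = in category).
#' @param group_a,group_b Dataset labels.
#' @return One-row `group_comparison` tibble.
#' @export
compare_category <- function(data, category, group_a, group_b) {
  a <- data[[category]][data$dataset == group_a]
  b <- data[[category]][data$dataset == group_b]
  tab <- matrix(c(sum(a), sum(!a), sum(b), sum(!b)), nrow = 2)
  f <- fisher_2x2(tab)
  structure(
    tibble(group_a = group_a, group_b = group_b, statistic = "fisher",
           estimate = f$odds_ratio, p_value = f$p_value,
           n_a = length(a), n_b = length(b)),
    class = c("group_comparison", class(tibble())))
}

#' Rank candidate cancer-driver genes
#'
#' Builds two ranked tables. The damage table keeps genes with a positive
#' ddG_rank difference and ranks them by their most significant p-value
#' across structure sources (experimental and predicted analyses of the same
#' gene are collapsed to the better p). The clustering table ranks genes by
#' recurrent EDC, descending. Ties are broken by larger absolute ddG_rank
#' difference and then gene name, so rankings are deterministic.
#'
#' @param enrichments Stacked `gene_enrichment` rows (one or more structure
#'   sources).
#' @param edcs `edc_result` rows from the recurrent analysis (may be empty).
#' @param top_n Table depth, default 50.
#' @return A `candidate_rankings` list: `damage` and `clustering` tibbles
#'   (each with a `rank` column) and `overlap`, the genes present in both.
#' @export
rank_candidates <- function(enrichments, edcs = NULL, top_n = 50) {
  enr <- as_tibble(enrichments) |> filter(!is.na(.data$p_value))
  if (nrow(enr) == 0) abort("no enrichment results supplied.")
  damage <- enr |>
    filter(.data$ddg_rank_diff > 0) |>
    group_by(.data$protein_id) |>
    arrange(.data$p_value, desc(abs(.data$ddg_rank_diff))) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$p_value, desc(abs(.data$ddg_rank_diff)),
            .data$protein_id) |>
    head(top_n) |>
    mutate(rank = row_number()) |>
    select("rank", "protein_id", "ddg_rank_diff", "p_value",
           "structure_source")
  clustering <- if (is.null(edcs) || nrow(as_tibble(edcs)) == 0) {
    tibble(rank = integer(), protein_id = character(), edc = numeric(),
           n_mutated = integer())
  } else {
    as_tibble(edcs) |>
      filter(!is.na(.data$edc)) |>
      arrange(desc(.data$edc), .data$protein_id) |>
      head(top_n) |>
      mutate(rank = row_number()) |>
      select("rank", "protein_id", "edc", "n_mutated")
  }
  structure(list(damage = damage, clustering = clustering,
                 overlap = intersect(damage$protein_id,
                                     clustering$protein_id)),
            class = "candidate_rankings", top_n = top_n)
}
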