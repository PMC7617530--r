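obs_keys <- function(st, rows) {
  tibble::as_tibble(st)[rows, c("position", "ref_aa", "alt_aa")]
}

test_that("the ddG_rank difference reproduces the worked example", {
  st <- toy_stability(c(0.1, 0.5, -1.2, 2.0))  # ranks 0, 1/3, 2/3, 1
  top <- which(st$ddg_rank == 1)
  enr <- gene_damage_enrichment(st, obs_keys(st, top))
  expect_equal(enr$ddg_rank_diff, 1 - mean(c(0, 1 / 3, 2 / 3)),
               tolerance = 1e-12)
  expect_equal(enr$ddg_rank_diff, 0.667, tolerance = 1e-3)
  expect_equal(enr$n_observed, 1L)
  expect_equal(enr$n_unobserved, 3L)
})

test_that("observed top ranks in a 6-variant toy give the enumerated p", {
  st <- toy_stability(c(1, 2, 3, 4, 5, 6))
  enr <- gene_damage_enrichment(st, obs_keys(st, 4:6))
  expect_equal(enr$p_value, 0.10, tolerance = 1e-12)  # 2 * (1 / C(6,3) ... tail)
  expect_equal(enr$p_value,
               wilcox_enum_oracle(st$ddg_rank[4:6], st$ddg_rank[1:3]),
               tolerance = 1e-12)
})

test_that("swapping observed and unobserved flips the sign of the difference", {
  set.seed(23)
  st <- toy_stability(rnorm(40))
  rows <- sample(40, 12)
  d1 <- gene_damage_enrichment(st, obs_keys(st, rows))$ddg_rank_diff
  d2 <- gene_damage_enrichment(st, obs_keys(st, setdiff(1:40, rows)))
  # the complements do not partition symmetrically: compare via means directly
  a <- mean(st$ddg_rank[rows]); b <- mean(st$ddg_rank[-rows])
  expect_equal(d1, a - b, tolerance = 1e-12)
  expect_equal(d2$ddg_rank_diff, b - a, tolerance = 1e-12)
  expect_equal(d1, -d2$ddg_rank_diff, tolerance = 1e-12)
})

test_that("interleaved observed ranks give a null difference and p near 1", {
  st <- toy_stability(1:20)
  enr <- gene_damage_enrichment(st, obs_keys(st, seq(1, 20, by = 2)))
  expect_lt(abs(enr$ddg_rank_diff), 0.06)
  expect_gt(enr$p_value, 0.5)
})

test_that("unmatched observed keys are dropped and empty sides skipped", {
  st <- toy_stability(c(1, 2, 3))
  ghost <- tibble::tibble(position = 99, ref_aa = "A", alt_aa = "V")
  enr <- gene_damage_enrichment(st, dplyr::bind_rows(obs_keys(st, 1), ghost))
  expect_equal(attr(enr, "n_dropped"), 1L)
  expect_equal(enr$n_observed, 1L)

  none <- gene_damage_enrichment(st, ghost)
  expect_true(is.na(none$p_value))
  expect_match(none$skip_reason, "empty")

  all_obs <- gene_damage_enrichment(st, obs_keys(st, 1:3))
  expect_true(is.na(all_obs$p_value))
})

test_that("significance flags use per-source Bonferroni on tested genes", {
  set.seed(29)
  rows <- purrr::map(1:8, function(i) {
    st <- toy_stability(rnorm(30))
    gene_damage_enrichment(st, obs_keys(st, sample(30, 10)))
  }) |> purrr::list_rbind()
  rows$protein_id <- sprintf("G%02d", 1:8)
  rows$p_value <- c(1e-8, 0.2, 0.004, 0.007, NA, 0.9, 1e-3, 0.05)
  rows <- structure(rows, class = c("gene_enrichment", class(tibble::tibble())))
  out <- add_significance(rows, alpha = 0.05)
  thr <- attr(out, "thresholds")
  expect_equal(thr$n_tested, 7)          # the NA row is not a test
  expect_equal(thr$threshold, 0.05 / 7)
  expect_equal(out$significant,
               c(TRUE, FALSE, TRUE, TRUE, NA, FALSE, TRUE, FALSE))
})

test_that("candidate ranking takes the best p across sources and breaks ties", {
  enr <- tibble::tibble(
    protein_id = c("A", "A", "B", "C", "D"),
    ddg_rank_diff = c(0.2, 0.25, 0.3, -0.4, 0.3),
    p_value = c(1e-8, 1e-3, 1e-5, 1e-9, 1e-5),
    n_observed = 10, n_unobserved = 100,
    structure_source = c("experimental", "predicted", "predicted",
                         "predicted", "predicted"),
    significant = TRUE, skip_reason = NA_character_)
  edcs <- tibble::tibble(protein_id = c("X", "B"), dataset = "cancer_all",
                         recurrent = TRUE, edc = c(1.9, 1.2),
                         n_mutated = 6L, n_unmutated = 100L,
                         excluded_low_confidence = 0L,
                         skip_reason = NA_character_)
  rk <- rank_candidates(enr, edcs, top_n = 50)
  # gene A ranked by its most significant source; C excluded (negative diff)
  expect_equal(rk$damage$protein_id, c("A", "B", "D"))
  expect_equal(rk$damage$p_value[1], 1e-8)
  expect_equal(rk$damage$structure_source[1], "experimental")
  # B and D tie on p; equal |diff|; name breaks the tie
  expect_equal(rk$damage$protein_id[2:3], c("B", "D"))
  expect_equal(rk$clustering$protein_id, c("X", "B"))
  expect_equal(rk$overlap, "B")

  empty_edc <- rank_candidates(enr, NULL)
  expect_equal(nrow(empty_edc$clustering), 0)
  expect_equal(length(empty_edc$overlap), 0)
})

test_that("group comparisons wrap the shared statistics", {
  df <- tibble::tibble(dataset = rep(c("pathogenic", "putatively_benign"),
                                     each = 4),
                       ddg_rank = c(0.9, 0.8, 0.7, 0.6, 0.1, 0.2, 0.3, 0.4),
                       buried = c(TRUE, TRUE, TRUE, FALSE,
                                  FALSE, FALSE, TRUE, FALSE))
  gw <- compare_groups(df, "ddg_rank", "pathogenic", "putatively_benign")
  expect_equal(gw$estimate, 0.5)
  expect_equal(gw$p_value,
               wilcox_enum_oracle(c(0.9, 0.8, 0.7, 0.6),
                                  c(0.1, 0.2, 0.3, 0.4)),
               tolerance = 1e-12)
  gf <- compare_category(df, "buried", "pathogenic", "putatively_benign")
  expect_equal(gf$estimate, 9)  # (3*3)/(1*1)
  expect_equal(gf$p_value, fisher_enum_oracle(matrix(c(3, 1, 1, 3), 2)),
               tolerance = 1e-9)
})

test_that("null cohorts stay below the family-wise error budget", {
  set.seed(31)
  n_sig <- 0L
  n_cohorts <- 60
  for (i in seq_len(n_cohorts)) {
    rows <- purrr::map(1:10, function(g) {
      st <- toy_stability(rnorm(25))
      gene_damage_enrichment(st, obs_keys(st, sample(25, 8)))
    }) |> purrr::list_rbind()
    rows <- structure(rows,
                      class = c("gene_enrichment", class(tibble::tibble())))
    out <- add_significance(rows, alpha = 0.05)
    n_sig <- n_sig + sum(out$significant, na.rm = TRUE)
  }
  # under the null the expected number of Bonferroni hits is <= alpha/cohort
  expect_lte(n_sig / n_cohorts, 0.05 + 2 * sqrt(0.05 / n_cohorts))
})
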