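test_that("replicate ddG values are averaged per variant", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protein_id,position,ref_aa,alt_aa,ddg,replicate",
               "P1,12,G,R,1.0,1", "P1,12,G,R,1.2,2", "P1,12,G,R,1.4,3",
               "P1,30,A,V,0.7,1"), path)
  tab <- read_foldx_output(path)
  expect_equal(tab$ddg[tab$position == 12], 1.2)
  expect_equal(tab$n_replicates[tab$position == 12], 3)
  expect_equal(tab$ddg[tab$position == 30], 0.7)
  expect_equal(tab$n_replicates[tab$position == 30], 1)
})

test_that("FoldX-style variant tokens parse and ref inconsistencies error", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("GA12R\t1.5", "GA12R\t1.7", "AA30V\t-0.2"), path)
  tab <- read_foldx_output(path)
  expect_equal(sort(tab$position), c(12, 30))
  expect_equal(tab$ddg[tab$position == 12], 1.6)
  expect_equal(tab$ref_aa, c("A", "G")[order(c(30, 12))])

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protein_id,position,ref_aa,alt_aa,ddg",
               "P1,12,A,R,1.0", "P1,12,G,R,1.2"), bad)
  expect_error(read_foldx_output(bad), "inconsistent ref_aa")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protein_id,position,ref_aa,alt_aa", "P1,12,A,R"), nocol)
  expect_error(read_foldx_output(nocol), "lacks column")
})

test_that("ddG averaging over structural models records coverage", {
  t1 <- tibble::tibble(protein_id = "P", position = c(1, 2),
                       ref_aa = "A", alt_aa = "V", ddg = c(1.0, 0.4))
  t2 <- tibble::tibble(protein_id = "P", position = 1,
                       ref_aa = "A", alt_aa = "V", ddg = 3.0)
  avg <- average_over_models(list(t1, t2))
  expect_equal(avg$ddg[avg$position == 1], 2.0)
  expect_equal(avg$n_models_averaged[avg$position == 1], 2)
  expect_equal(avg$ddg[avg$position == 2], 0.4)
  expect_equal(avg$n_models_averaged[avg$position == 2], 1)
  expect_error(average_over_models(list()), "no model tables")
})

test_that("single-nucleotide reachability follows the standard genetic code", {
  expect_equal(enumerate_snv_reachable("GGA"), c("A", "E", "R", "V"),
               ignore_attr = TRUE)
  expect_equal(enumerate_snv_reachable("ATG"),
               c("I", "K", "L", "R", "T", "V"), ignore_attr = TRUE)
  trp <- enumerate_snv_reachable("TGG")
  expect_false("W" %in% trp)
  expect_false("*" %in% trp)
  expect_false(attr(enumerate_snv_reachable("GGA"), "codon_agnostic"))
  expect_true(attr(enumerate_snv_reachable("G"), "codon_agnostic"))
  # codon-agnostic reachability is the union over the residue's codons
  expect_true(all(enumerate_snv_reachable("GGA") %in%
                    enumerate_snv_reachable("G")))
  expect_error(enumerate_snv_reachable("GGX"), "invalid")
})

test_that("a coding sequence restricts the background to reachable variants", {
  raw <- tibble::tibble(protein_id = "P", position = 1,
                        ref_aa = "G", alt_aa = c("R", "W"),
                        ddg = c(1, 2))
  out <- filter_snv_reachable(raw, cds = "GGA")
  expect_equal(out$alt_aa, "R")  # W is not one change away from GGA
  expect_false(attr(out, "codon_agnostic"))
  out2 <- filter_snv_reachable(raw)
  expect_true(attr(out2, "codon_agnostic"))
  expect_error(filter_snv_reachable(raw, cds = "GG"), "multiple of 3")
  expect_error(
    filter_snv_reachable(dplyr::mutate(raw, ref_aa = "A"), cds = "GGA"),
    "does not encode")
})

test_that("ddg_rank reproduces the hand-ranked worked examples", {
  st <- toy_stability(c(0.1, 0.5, -1.2, 2.0))
  expect_equal(st$ddg_rank, c(0, 1 / 3, 2 / 3, 1))
  expect_equal(st$ddg_rank[st$ddg == -1.2], 2 / 3, tolerance = 1e-12)
  expect_equal(st$abs_ddg, abs(st$ddg))

  tied <- toy_stability(c(1.0, 1.0, 2.0))
  expect_equal(tied$ddg_rank, c(0.25, 0.25, 1.0))
  expect_equal(mean(tied$ddg_rank), 0.5)

  expect_error(toy_stability(1.0), "at least 2")
  expect_error(
    ddg_rank(tibble::tibble(protein_id = "P", position = 1,
                            ref_aa = "A", alt_aa = "A", ddg = 1)),
    "missense")
})

# independent rank oracle: counts of smaller/equal values, no rank() call
brute_rank01 <- function(v) {
  r <- vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
  (r - 1) / (length(v) - 1)
}

test_that("rank normalisation matches a brute-force re-sort oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    ddg <- round(rnorm(n, sd = 2), sample(0:2, 1))  # rounding induces ties
    if (length(unique(abs(ddg))) < 2) next
    st <- toy_stability(ddg)
    expect_equal(st$ddg_rank, brute_rank01(abs(ddg)), tolerance = 1e-12)
    expect_equal(mean(st$ddg_rank), 0.5, tolerance = 1e-12)
    # invariance under strictly monotone transform of |ddg|
    st2 <- toy_stability(sign(ddg) * (exp(abs(ddg)) - 0.5))
    expect_equal(st2$ddg_rank, st$ddg_rank, tolerance = 1e-12)
    # shifting ddg re-ranks exactly as the re-sorted |ddg| dictates
    st3 <- toy_stability(ddg + 1.3)
    expect_equal(st3$ddg_rank, brute_rank01(abs(ddg + 1.3)),
                 tolerance = 1e-12)
  }
})

test_that("multi-protein tables are ranked independently per protein", {
  raw <- dplyr::bind_rows(
    tibble::tibble(protein_id = "P1", position = 1:3, ref_aa = "A",
                   alt_aa = c("C", "D", "E"), ddg = c(1, 2, 3)),
    tibble::tibble(protein_id = "P2", position = 1:2, ref_aa = "A",
                   alt_aa = c("C", "D"), ddg = c(5, 4)))
  st <- ddg_rank(raw)
  expect_equal(st$ddg_rank[st$protein_id == "P1"], c(0, 0.5, 1))
  expect_equal(st$ddg_rank[st$protein_id == "P2"], c(1, 0))
})
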