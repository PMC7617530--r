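test_that("PDB reading preserves residues, coordinates and B-factors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(ca_pdb_lines(c(91.2, 45.0, 88.0)), path)
  m <- read_structure(path)
  expect_equal(nrow(m), 3)
  expect_equal(unique(m$chain_id), "A")
  expect_true(all(m$has_ca))
  expect_equal(m$bfactor, c(91.2, 45.0, 88.0))
  expect_equal(structure_source(m), "predicted")
})

test_that("round-trip through write_chain_pdb reproduces the model", {
  sp <- synthetic_spec(gene = "RT", seed = 11, n_residues = 40)
  ch <- generate_chain(sp)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_chain_pdb(ch, path)
  back <- read_structure(path)
  expect_equal(nrow(back), nrow(ch))
  expect_equal(back$chain_id, ch$chain_id)
  expect_equal(back$aa, ch$aa)
  expect_equal(back$x, ch$x, tolerance = 1e-3)
  expect_equal(back$y, ch$y, tolerance = 1e-3)
  expect_equal(back$z, ch$z, tolerance = 1e-3)
})

test_that("files without standard polypeptide residues are rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1 ZN    ZN A 101      10.000  10.000  10.000  1.00 20.00",
    "END"), path)
  expect_error(read_structure(path), "empty structure")
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("sequence-structure mapping enforces identity and length rules", {
  sp <- synthetic_spec(gene = "MAP", seed = 21, n_residues = 60)
  m <- generate_chain(sp)
  seq <- chain_sequence(m, "A")

  full <- map_sequence_to_chain(seq, m, "A")
  expect_s3_class(full, "seq_structure_mapping")
  expect_equal(nrow(full), 60)
  expect_equal(attr(full, "percent_identity"), 100)
  expect_equal(full$seq_position, full$residue_index)

  # identical sequence but only 45 residues resolved: too short
  short_model <- as_structure_model(tibble::as_tibble(m)[1:45, ],
                                    structure_id = "MAP45")
  rej_len <- map_sequence_to_chain(chain_sequence(short_model, "A"),
                                   short_model, "A")
  expect_true(is_rejection(rej_len))
  expect_equal(rej_len$reason, "length")

  # 9 substitutions in 60 residues: 85% identity, below the >90% bar
  mut_seq <- strsplit(seq, "")[[1]]
  pos <- seq(3, 59, by = 7)[1:9]
  mut_seq[pos] <- vapply(mut_seq[pos], function(a) {
    setdiff(c("A", "C", "D"), a)[1]
  }, character(1))
  rej_id <- map_sequence_to_chain(paste(mut_seq, collapse = ""), m, "A")
  expect_true(is_rejection(rej_id))
  expect_equal(rej_id$reason, "identity")
  expect_lt(rej_id$percent_identity, 90)

  expect_error(map_sequence_to_chain(seq, m, "Z"), "unknown chain")
  expect_error(map_sequence_to_chain("", m, "A"), "empty")
})

test_that("mapping positions increase strictly in both coordinates", {
  sp <- synthetic_spec(gene = "MON", seed = 31, n_residues = 80)
  m <- generate_chain(sp)
  seq <- chain_sequence(m, "A")
  # delete an internal stretch from the model to force a gapped alignment
  kept <- tibble::as_tibble(m)[-(30:34), ]
  kept$residue_index <- seq_len(nrow(kept))
  gap_model <- as_structure_model(kept, structure_id = "GAP")
  mp <- map_sequence_to_chain(seq, gap_model, "A")
  expect_s3_class(mp, "seq_structure_mapping")
  expect_true(all(diff(mp$seq_position) > 0))
  expect_true(all(diff(mp$residue_index) > 0))
})

make_candidate <- function(id, resolution, n_chains) {
  res <- purrr::map(seq_len(n_chains), function(ci) {
    tibble::tibble(chain_id = LETTERS[ci], residue_index = 1:6,
                   aa = "A", x = (1:6) * 3.8, y = ci * 10, z = 0)
  }) |> purrr::list_rbind()
  model <- as_structure_model(
    res, structure_id = id,
    source = if (is.na(resolution)) "predicted" else "experimental",
    resolution = resolution)
  list(model = model, mapping = NULL)
}

test_that("chain selection prefers resolution, then assembly size", {
  a <- make_candidate("2res", 2.0, 1)
  b <- make_candidate("1res", 1.5, 1)
  expect_equal(structure_id(select_best_chain(list(a, b))$model), "1res")

  big <- make_candidate("big", 2.0, 4)
  expect_equal(structure_id(select_best_chain(list(a, big))$model), "big")

  expect_equal(structure_id(select_best_chain(list(a))$model), "2res")
  expect_error(select_best_chain(list()), "no candidate")

  # predicted models (no resolution) rank behind any experimental structure
  af <- make_candidate("af", NA, 1)
  expect_equal(structure_id(select_best_chain(list(af, a))$model), "2res")
})

test_that("chain selection is invariant to candidate order", {
  cands <- list(make_candidate("b", 2.0, 2), make_candidate("a", 2.0, 2),
                make_candidate("c", 1.8, 1), make_candidate("d", 2.0, 4))
  picks <- vapply(1:10, function(i) {
    set.seed(i)
    structure_id(select_best_chain(sample(cands))$model)
  }, character(1))
  expect_true(all(picks == picks[1]))
  expect_equal(picks[1], "c")
})

test_that("pLDDT mask retains the threshold value itself", {
  res <- tibble::tibble(chain_id = "A", residue_index = 1:3, aa = "A",
                        x = (1:3) * 3.8, y = 0, z = 0,
                        bfactor = c(91.2, 45.0, 70.0))
  m <- as_structure_model(res, source = "predicted")
  expect_equal(plddt_mask(m), c(TRUE, FALSE, TRUE))
  expect_true(all(plddt_mask(m, threshold = 0)))
  expect_false(any(plddt_mask(m, threshold = 100.01)))

  exp_m <- as_structure_model(res, source = "experimental", resolution = 2)
  expect_warning(msk <- plddt_mask(exp_m), "experimental")
  expect_true(all(msk))
})
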