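#' Read per-protein stability (ddG) predictions
#'
#' Accepts either the generic delimited layout (columns `protein_id`,
#' `position`, `ref_aa`, `alt_aa`, `ddg` and optionally `replicate`,
#' `model_id`) or FoldX-style two-column output whose first token encodes the
#' variant as `<ref><chain?><position><alt>` (e.g. `GA12R` or `G12R`) and the
#' second the energy in kcal/mol. Replicates of the same variant are averaged
#' (arithmetic mean) and the replicate count recorded.
#'
#' @param paths One or more file paths. FoldX-style files need a
#'   `protein_id`; it is taken from the file name (without extension).
#' @return Tibble `protein_id`, `position`, `ref_aa`, `alt_aa`, `ddg`,
#'   `n_replicates` (and `model_id` when present in the input).
#' @export
read_foldx_output <- function(paths) {
  one <- function(path) {
    first <- readLines(path, n = 1, warn = FALSE)
    if (grepl("protein_id", first)) {
      delim <- if (grepl("\t", first)) "\t" else ","
      df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                              progress = FALSE)
      need <- c("protein_id", "position", "ref_aa", "alt_aa", "ddg")
      miss <- setdiff(need, names(df))
      if (length(miss)) {
        abort(paste0("stability table ", path, " lacks column(s): ",
                     paste(miss, collapse = ", ")))
      }
      df
    } else {
      toks <- str_split(str_trim(readLines(path, warn = FALSE)), "\\s+")
      toks <- toks[lengths(toks) >= 2]
      m <- regmatches(map_chr(toks, 1),
                      regexec("^([A-Z])([A-Za-z]?)([0-9]+)([A-Z])$",
                              map_chr(toks, 1)))
      if (any(lengths(m) != 5)) {
        abort(paste0("unrecognised variant token in ", path))
      }
      tibble(protein_id = sub("\\.[^.]*$", "", basename(path)),
             position = as.integer(map_chr(m, 4)),
             ref_aa = map_chr(m, 2),
             alt_aa = map_chr(m, 5),
             ddg = as.numeric(map_chr(toks, 2)))
    }
  }
  raw <- map(paths, one) |> list_rbind()
  refs <- raw |>
    distinct(.data$protein_id, .data$position, .data$ref_aa)
  if (anyDuplicated(refs[, c("protein_id", "position")])) {
    abort("inconsistent ref_aa across replicates of the same position.")
  }
  grp <- c("protein_id", "position", "ref_aa", "alt_aa",
           intersect("model_id", names(raw)))
  raw |>
    group_by(across(all_of(grp))) |>
    summarise(ddg = mean(.data$ddg), n_replicates = n(), .groups = "drop")
}

#' Average ddG values over multiple structural models
#'
#' For proteins covered by several (possibly overlapping) structural models,
#' averages the predicted ddG per variant over every model in which the
#' variant appears, recording how many models contributed.
#'
#' @param tables List of variant tibbles (as from [read_foldx_output()]),
#'   all for the same protein.
#' @return Tibble with `ddg` averaged and `n_models_averaged`.
#' @export
average_over_models <- function(tables) {
  if (length(tables) == 0) abort("no model tables supplied.")
  raw <- list_rbind(map(tables, as_tibble))
  if (length(unique(raw$protein_id)) > 1) {
    abort("all model tables must refer to the same protein_id.")
  }
  raw |>
    group_by(.data$protein_id, .data$position, .data$ref_aa, .data$alt_aa) |>
    summarise(ddg = mean(.data$ddg), n_models_averaged = n(),
              .groups = "drop")
}

#' Amino acids reachable by a single nucleotide change
#'
#' Enumerates the missense substitutions accessible from a codon via exactly
#' one nucleotide change under the standard genetic code, excluding
#' synonymous changes and stops. Given a one-letter amino acid instead of a
#' codon, returns the union over all codons encoding it and flags the result
#' codon-agnostic.
#'
#' @param aa_or_codon A 3-letter codon (e.g. `"GGA"`) or one-letter amino
#'   acid.
#' @return Character vector of alternate amino acids; attribute
#'   `codon_agnostic` is `TRUE` for the amino-acid form.
#' @export
enumerate_snv_reachable <- function(aa_or_codon) {
  gc <- Biostrings::GENETIC_CODE
  from_codon <- function(codon) {
    codon <- toupper(codon)
    if (!codon %in% names(gc)) abort(paste0("invalid codon: ", codon))
    ref <- gc[[codon]]
    nts <- c("A", "C", "G", "T")
    alts <- character(0)
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- nt
        alts <- c(alts, gc[[mut]])
      }
    }
    sort(setdiff(unique(alts), c(ref, "*")))
  }
  x <- toupper(aa_or_codon)
  if (nchar(x) == 3) {
    structure(from_codon(x), codon_agnostic = FALSE)
  } else if (nchar(x) == 1 && x %in% AA1) {
    codons <- names(gc)[gc == x]
    structure(sort(unique(unlist(map(codons, from_codon)))),
              codon_agnostic = TRUE)
  } else {
    abort(paste0("invalid amino acid or codon: ", aa_or_codon))
  }
}

#' Rank-normalised stability landscape (ddG_rank)
#'
#' Sorts the complete set of possible substitutions of a protein by absolute
#' ddG and maps the ranks onto \[0, 1\]: 0 is the mildest possible missense
#' change, 1 the most destabilising. Ties receive average ranks and the
#' normalisation is (rank - 1) / (n - 1), which keeps the mean over the full
#' landscape at exactly 0.5, tied or not. A set of random mutations is
#' therefore expected to average about 0.5, making per-protein landscapes
#' directly comparable.
#'
#' @param raw Variant tibble with `protein_id`, `position`, `ref_aa`,
#'   `alt_aa`, `ddg`; several proteins may be stacked and are ranked
#'   independently.
#' @param provenance `"experimental-complex"` or `"predicted-monomer"`,
#'   recorded as an attribute.
#' @return A `stability_table` tibble with added `abs_ddg` and `ddg_rank`.
#' @export
ddg_rank <- function(raw, provenance = c("predicted-monomer",
                                         "experimental-complex")) {
  provenance <- match.arg(provenance)
  raw <- as_tibble(raw)
  if (any(raw$ref_aa == raw$alt_aa)) {
    abort("ref_aa == alt_aa: not a missense substitution.")
  }
  sizes <- table(raw$protein_id)
  if (any(sizes < 2)) abort("each protein needs at least 2 variants to rank.")
  out <- raw |>
    group_by(.data$protein_id) |>
    mutate(abs_ddg = abs(.data$ddg),
           ddg_rank = (rank(.data$abs_ddg, ties.method = "average") - 1) /
             (n() - 1)) |>
    ungroup()
  structure(out, class = c("stability_table", class(tibble())),
            provenance = provenance)
}

#' Restrict a stability landscape to SNV-reachable substitutions
#'
#' Filters the possible-mutation background to substitutions reachable by a
#' single nucleotide change. With a coding sequence the codon at each
#' position defines reachability; without one, the codon-agnostic union over
#' all codons of the reference amino acid is used and flagged.
#'
#' @param raw Variant tibble (`position`, `ref_aa`, `alt_aa`, ...).
#' @param cds Optional coding DNA sequence (character scalar, length a
#'   multiple of 3) for the protein.
#' @return Filtered tibble; attribute `codon_agnostic` records the mode.
#' @export
filter_snv_reachable <- function(raw, cds = NULL) {
  raw <- as_tibble(raw)
  if (is.null(cds)) {
    keys <- distinct(raw, .data$ref_aa)
    reach <- set_names(map(keys$ref_aa, enumerate_snv_reachable),
                       keys$ref_aa)
    keep <- map2(raw$ref_aa, raw$alt_aa, ~ .y %in% reach[[.x]]) |>
      unlist()
    return(structure(raw[keep, ], codon_agnostic = TRUE))
  }
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3 != 0) abort("cds length is not a multiple of 3.")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- Biostrings::GENETIC_CODE
  if (any(raw$position > length(codons))) {
    abort("variant position beyond the coding sequence.")
  }
  mism <- gc[codons[raw$position]] != raw$ref_aa
  if (any(mism)) {
    abort(paste0("cds codon does not encode ref_aa at position(s): ",
                 paste(unique(raw$position[mism]), collapse = ", ")))
  }
  keep <- vapply(seq_len(nrow(raw)), function(i) {
    raw$alt_aa[i] %in% enumerate_snv_reachable(codons[raw$position[i]])
  }, logical(1))
  structure(raw[keep, ], codon_agnostic = FALSE)
}
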