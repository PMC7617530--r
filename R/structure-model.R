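#' Construct a structure model from a residue table
#'
#' A structure model is a tibble with one row per standard amino-acid residue
#' and the columns `chain_id`, `residue_index` (1-based sequential position
#' within the chain), `author_number` (residue numbering used in the source
#' file), `aa` (one-letter code), `x`, `y`, `z` (C-alpha coordinates, Angstrom;
#' `NA` when the residue has no C-alpha), `bfactor` (B-factor for experimental
#' structures, pLDDT on the 0-100 scale for predicted models) and `has_ca`.
#' Structure-level metadata travels as attributes: `structure_id`, `source`
#' (`"experimental"` or `"predicted"`), `resolution` (Angstrom, `NA` for
#' predicted models), `assembly_size` (number of polypeptide chains) and
#' `atoms` (full atom table used for surface-area computation).
#'
#' @param residues Tibble with at least `chain_id`, `residue_index`, `aa`,
#'   `x`, `y`, `z`; missing `author_number`, `bfactor`, `has_ca` are filled.
#' @param structure_id Identifier for the model.
#' @param source `"experimental"` or `"predicted"`.
#' @param resolution Resolution in Angstrom; must be `NA` for predicted models.
#' @param atoms Optional atom-level tibble (`chain_id`, `author_number`,
#'   `elety`, `element`, `x`, `y`, `z`). When omitted, C-alpha pseudo-atoms
#'   are used so coarse-grained (C-alpha only) models still support
#'   surface-area estimation.
#' @return A `structure_model` tibble.
#' @export
as_structure_model <- function(residues, structure_id = "model",
                               source = c("predicted", "experimental"),
                               resolution = NA_real_, atoms = NULL) {
  source <- match.arg(source)
  if (source == "predicted" && !is.na(resolution)) {
    abort("`resolution` must be NA for predicted models.")
  }
  res <- as_tibble(residues)
  if (!all(c("chain_id", "residue_index", "aa", "x", "y", "z") %in% names(res))) {
    abort("residue table needs chain_id, residue_index, aa, x, y, z columns.")
  }
  if (!"author_number" %in% names(res)) res$author_number <- res$residue_index
  if (!"bfactor" %in% names(res)) res$bfactor <- NA_real_
  if (!"has_ca" %in% names(res)) res$has_ca <- !is.na(res$x)
  res <- res[, c("chain_id", "residue_index", "author_number", "aa",
                 "x", "y", "z", "bfactor", "has_ca")]
  bad <- res |>
    group_by(.data$chain_id) |>
    summarise(dup = anyDuplicated(.data$residue_index) > 0 |
                any(.data$residue_index < 1), .groups = "drop")
  if (any(bad$dup)) abort("residue_index must be unique and >= 1 within a chain.")
  if (is.null(atoms)) {
    atoms <- res |>
      filter(.data$has_ca) |>
      transmute(.data$chain_id, .data$author_number,
                elety = "CA", element = "CA-pseudo",
                .data$x, .data$y, .data$z)
  }
  structure(res,
            class = c("structure_model", class(tibble())),
            structure_id = structure_id, source = source,
            resolution = if (source == "experimental") resolution else NA_real_,
            assembly_size = length(unique(res$chain_id)),
            atoms = as_tibble(atoms))
}

#' @export
#' @rdname as_structure_model
#' @param model A `structure_model`.
structure_source <- function(model) attr(model, "source", exact = TRUE)

#' @export
#' @rdname as_structure_model
structure_id <- function(model) attr(model, "structure_id", exact = TRUE)

# dplyr verbs strip attributes; re-attach when subsetting chains internally
keep_model_attrs <- function(new, old) {
  structure(new, class = class(old),
            structure_id = attr(old, "structure_id", exact = TRUE),
            source = attr(old, "source", exact = TRUE),
            resolution = attr(old, "resolution", exact = TRUE),
            assembly_size = attr(old, "assembly_size", exact = TRUE),
            atoms = attr(old, "atoms", exact = TRUE))
}

parse_resolution <- function(lines, fmt) {
  if (fmt == "pdb") {
    ln <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(ln)) {
      m <- regmatches(ln[1], regexpr("[0-9]+\\.[0-9]+", ln[1]))
      if (length(m)) return(as.numeric(m))
    }
  } else {
    ln <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(ln)) {
      m <- regmatches(ln[1], regexpr("[0-9]+\\.?[0-9]*\\s*$", ln[1]))
      if (length(m)) return(as.numeric(str_trim(m)))
    }
  }
  NA_real_
}

#' Read a protein structure file
#'
#' Parses a PDB or mmCIF file into a [as_structure_model()] residue table.
#' Only standard amino-acid `ATOM` records are retained (hetero and modified
#' residues are excluded); multi-model (e.g. NMR) files contribute the first
#' model only, mirroring the single-conformer treatment of crystallographic
#' and predicted structures. The B-factor column is carried through verbatim,
#' which is where predicted models store per-residue pLDDT confidence.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param source `"auto"` infers `"experimental"` when a resolution record is
#'   present and `"predicted"` otherwise; or state it explicitly.
#' @return A `structure_model` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           source = c("auto", "experimental", "predicted")) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) abort(paste0("cannot parse ", format, " file '", path,
                                     "': ", conditionMessage(e))))
  at <- as_tibble(parsed$atom)
  at <- at |> filter(.data$type == "ATOM", .data$resid %in% names(AA3))
  if (nrow(at) == 0) {
    abort(paste0("no standard polypeptide residues in '", path,
                 "' (empty structure)."))
  }
  # first model only: bio3d repeats atom records for multi-model PDBs
  at <- at |> distinct(.data$chain, .data$resno, .data$insert, .data$elety,
                       .keep_all = TRUE)
  at$insert[is.na(at$insert)] <- ""
  residues <- at |>
    group_by(.data$chain, .data$resno, .data$insert) |>
    summarise(resid = .data$resid[1],
              ca = list(which(.data$elety == "CA")),
              ca_x = if (length(ca[[1]])) .data$x[ca[[1]][1]] else NA_real_,
              ca_y = if (length(ca[[1]])) .data$y[ca[[1]][1]] else NA_real_,
              ca_z = if (length(ca[[1]])) .data$z[ca[[1]][1]] else NA_real_,
              bfactor = if (length(ca[[1]])) .data$b[ca[[1]][1]]
                        else mean(.data$b),
              ord = min(.data$eleno),
              .groups = "drop") |>
    arrange(.data$chain, .data$ord) |>
    group_by(.data$chain) |>
    mutate(residue_index = row_number()) |>
    ungroup() |>
    transmute(chain_id = .data$chain, .data$residue_index,
              author_number = .data$resno,
              aa = unname(AA3[.data$resid]),
              x = .data$ca_x, y = .data$ca_y, z = .data$ca_z,
              .data$bfactor, has_ca = !is.na(.data$ca_x))
  lines <- readLines(path, warn = FALSE)
  resolution <- parse_resolution(lines, format)
  if (source == "auto") {
    source <- if (is.na(resolution)) "predicted" else "experimental"
  }
  atoms <- at |>
    transmute(chain_id = .data$chain, author_number = .data$resno,
              .data$elety,
              element = ifelse(!is.na(.data$elesy) & nzchar(.data$elesy),
                               .data$elesy, substr(.data$elety, 1, 1)),
              .data$x, .data$y, .data$z)
  as_structure_model(residues,
                     structure_id = sub("\\.(pdb|cif)(\\.gz)?$", "",
                                        basename(path), ignore.case = TRUE),
                     source = source,
                     resolution = if (source == "experimental") resolution
                                  else NA_real_,
                     atoms = atoms)
}

#' One-letter sequence of a chain
#' @param model A `structure_model`.
#' @param chain_id Chain identifier.
#' @return Character scalar.
#' @export
chain_sequence <- function(model, chain_id) {
  res <- model[model$chain_id == chain_id, ]
  if (nrow(res) == 0) abort(paste0("unknown chain '", chain_id, "'."))
  paste(res$aa[order(res$residue_index)], collapse = "")
}

aa_identity_matrix <- function() {
  letters <- c(AA1, "X")
  m <- matrix(-1L, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 2L
  m
}

#' Map a protein sequence onto a structure chain
#'
#' Aligns the full-length protein sequence against the residues observed in a
#' chain (global alignment with free end gaps) and accepts the mapping only
#' when the percent identity over aligned columns exceeds `min_identity` and
#' at least `min_length` residues align. Otherwise an explicit rejection
#' object naming the failed criterion is returned.
#'
#' @param protein_seq Amino-acid string (the reference protein).
#' @param model A `structure_model`.
#' @param chain_id Chain to align against.
#' @param min_identity Required percent identity (strict `>`), default 90.
#' @param min_length Required number of aligned residues, default 50.
#' @return A `seq_structure_mapping` tibble with columns `seq_position` and
#'   `residue_index` (attributes `percent_identity`, `aligned_length`), or a
#'   `mapping_rejection` object.
#' @export
map_sequence_to_chain <- function(protein_seq, model, chain_id,
                                  min_identity = 90, min_length = 50) {
  if (!nzchar(protein_seq)) abort("protein_seq is empty.")
  chain_seq <- chain_sequence(model, chain_id)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_seq), Biostrings::AAString(chain_seq),
    type = "overlap", substitutionMatrix = aa_identity_matrix(),
    gapOpening = 5, gapExtension = 1)
  ps <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ss <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  i <- Biostrings::start(Biostrings::pattern(al)) - 1L
  j <- Biostrings::start(Biostrings::subject(al)) - 1L
  pairs <- vector("list", length(ps))
  ident <- 0L
  n_pairs <- 0L
  for (k in seq_along(ps)) {
    if (ps[k] != "-") i <- i + 1L
    if (ss[k] != "-") j <- j + 1L
    if (ps[k] != "-" && ss[k] != "-") {
      n_pairs <- n_pairs + 1L
      pairs[[n_pairs]] <- c(i, j)
      if (ps[k] == ss[k]) ident <- ident + 1L
    }
  }
  pairs <- pairs[seq_len(n_pairs)]
  pct <- if (n_pairs > 0) 100 * ident / n_pairs else 0
  reject <- function(reason) {
    structure(list(protein_id = NA_character_, chain_id = chain_id,
                   reason = reason, percent_identity = pct,
                   aligned_length = n_pairs),
              class = "mapping_rejection")
  }
  if (n_pairs < min_length) return(reject("length"))
  if (!(pct > min_identity)) return(reject("identity"))
  mapped <- tibble(seq_position = vapply(pairs, `[`, 0, 1),
                   residue_index = model$residue_index[
                     model$chain_id == chain_id][vapply(pairs, `[`, 0, 2)])
  structure(mapped, class = c("seq_structure_mapping", class(tibble())),
            chain_id = chain_id, percent_identity = pct,
            aligned_length = n_pairs)
}

#' @export
#' @rdname map_sequence_to_chain
#' @param x Object returned by `map_sequence_to_chain()`.
is_rejection <- function(x) inherits(x, "mapping_rejection")

#' Select the best structure chain for a residue
#'
#' When a residue maps to several chains/structures, prefers the highest
#' resolution (lowest Angstrom value; predicted models, which have none, sort
#' last), then the largest biological assembly, then the lexicographically
#' smallest structure id so that selection is deterministic.
#'
#' @param candidates List of `list(model = , mapping = )` entries.
#' @return The selected candidate (same list structure).
#' @export
select_best_chain <- function(candidates) {
  if (length(candidates) == 0) abort("no candidate chains supplied.")
  res <- map_dbl(candidates, function(c.) {
    r <- attr(c.$model, "resolution", exact = TRUE)
    if (is.null(r) || is.na(r)) Inf else r
  })
  asm <- map_dbl(candidates, ~ attr(.x$model, "assembly_size", exact = TRUE))
  ids <- map_chr(candidates, ~ attr(.x$model, "structure_id", exact = TRUE))
  ord <- order(res, -asm, ids)
  candidates[[ord[1]]]
}

#' Residue confidence mask for predicted models
#'
#' Marks residues whose pLDDT (stored in the B-factor column of predicted
#' models) is at least `threshold`; residues below it are excluded from
#' downstream distance calculations. Exactly `threshold` is retained (the
#' exclusion rule is strictly "less than"). For experimental structures all
#' residues are kept and a warning is raised.
#'
#' @param model A `structure_model`.
#' @param threshold pLDDT cutoff, default 70.
#' @return Logical vector along the rows of `model`.
#' @export
plddt_mask <- function(model, threshold = 70) {
  if (structure_source(model) == "experimental") {
    warn("experimental structure: pLDDT mask is all-true.")
    return(rep(TRUE, nrow(model)))
  }
  model$bfactor >= threshold
}

#' Write a C-alpha trace as a PDB file
#'
#' Writes one `ATOM` record per residue with a C-alpha, with the model's
#' B-factor column (pLDDT for predicted models) in the temperature-factor
#' field. Residues lacking coordinates are skipped.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(model, path) {
  res <- model[model$has_ca, ]
  aa3 <- setNames(names(AA3), unname(AA3))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(res)), aa3[res$aa], res$chain_id, res$author_number,
    res$x, res$y, res$z, 1.00, res$bfactor)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
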