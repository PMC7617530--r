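DATASET_LABELS <- c("cancer_all", "cancer_recurrent", "cancer_driver",
                    "pathogenic", "putatively_benign", "custom")

#' Read a missense mutation table
#'
#' Parses a delimited file of protein-level missense variants. Required
#' columns: `gene`, `protein_id`, `position`, `ref_aa`, `alt_aa`; an optional
#' `recurrence` column (number of tumour samples carrying the variant)
#' defaults to 1. Rows with missing or invalid fields -- non-positive
#' positions, non-standard amino acids, or `ref_aa == alt_aa` (not missense)
#' -- are dropped and counted in the `n_dropped` attribute.
#'
#' @param path Path to a TSV/CSV file.
#' @param dataset Dataset label attached to every record, one of
#'   `r paste0('"', DATASET_LABELS, '"', collapse = ", ")`.
#' @return Tibble of mutation records with a `dataset` column.
#' @export
read_mutations <- function(path, dataset = "custom") {
  dataset <- match.arg(dataset, DATASET_LABELS)
  first <- readLines(path, n = 1, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("gene", "protein_id", "position", "ref_aa", "alt_aa")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("mutation table ", path, " lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"recurrence" %in% names(df)) df$recurrence <- 1L
  n0 <- nrow(df)
  ok <- !is.na(df$gene) & !is.na(df$protein_id) &
    !is.na(df$position) & df$position >= 1 &
    df$ref_aa %in% AA1 & df$alt_aa %in% AA1 &
    df$ref_aa != df$alt_aa &
    !is.na(df$recurrence) & df$recurrence >= 1
  out <- df[ok, c(need, "recurrence")] |>
    mutate(position = as.integer(.data$position),
           recurrence = as.integer(.data$recurrence),
           dataset = dataset)
  structure(as_tibble(out), n_dropped = n0 - nrow(out))
}

#' Keep unique missense mutations
#'
#' One record per (protein, position, ref, alt, dataset). Recurrence counts
#' of duplicate rows are merged by maximum: the source recurrence column is a
#' per-variant sample count, so duplicated rows restate rather than add to
#' it.
#'
#' @param records Mutation tibble.
#' @return Deduplicated tibble.
#' @export
deduplicate_mutations <- function(records) {
  if (nrow(records) == 0) return(as_tibble(records))
  records |>
    group_by(.data$protein_id, .data$position, .data$ref_aa, .data$alt_aa,
             .data$dataset) |>
    summarise(gene = .data$gene[1], recurrence = max(.data$recurrence),
              .groups = "drop") |>
    select("gene", "protein_id", "position", "ref_aa", "alt_aa",
           "recurrence", "dataset")
}

#' Filter to recurrent mutations
#'
#' Keeps variants observed at least `min_recurrence` times (inclusive;
#' the default of 7 retains a variant seen exactly seven times).
#'
#' @param records Mutation tibble with a `recurrence` column.
#' @param min_recurrence Minimum sample count, default 7.
#' @return Filtered tibble.
#' @export
filter_recurrent <- function(records, min_recurrence = 7) {
  if (min_recurrence < 1) abort("min_recurrence must be >= 1.")
  records |> filter(.data$recurrence >= min_recurrence)
}

#' Assign oncogene/TSG roles to genes
#'
#' Tokenises free-text role strings (comma/semicolon separated). Recognised
#' tokens are `oncogene` and `TSG` (case-insensitive); a `fusion` token is
#' ignored because gene fusion is a different class of genomic change, so
#' `"oncogene, fusion"` is an oncogene while `"fusion"` alone confers no
#' role. Genes absent from the table, or with unparseable role strings
#' (warned about), get role `none`.
#'
#' @param genes Character vector of gene symbols.
#' @param role_table Path to a two-column delimited file (`gene`,
#'   `role_string`) or an equivalent data frame.
#' @return Tibble `gene`, `role` with role one of `oncogene`, `tsg`,
#'   `oncogene_and_tsg`, `none`.
#' @export
assign_roles <- function(genes, role_table) {
  if (is.character(role_table) && length(role_table) == 1) {
    first <- readLines(role_table, n = 1, warn = FALSE)
    delim <- if (grepl("\t", first)) "\t" else ","
    role_table <- readr::read_delim(role_table, delim = delim,
                                    show_col_types = FALSE, progress = FALSE)
  }
  role_table <- as_tibble(role_table)
  if (!all(c("gene", "role_string") %in% names(role_table))) {
    abort("role table needs columns gene, role_string.")
  }
  parse_one <- function(s) {
    if (is.na(s)) return("none")
    toks <- tolower(str_trim(unlist(str_split(s, "[,;]"))))
    toks <- toks[nzchar(toks)]
    known <- toks %in% c("oncogene", "tsg", "fusion")
    if (any(!known)) {
      warn(paste0("unrecognised role token(s): ",
                  paste(toks[!known], collapse = ", ")))
    }
    toks <- toks[known & toks != "fusion"]
    if (all(c("oncogene", "tsg") %in% toks)) "oncogene_and_tsg"
    else if ("oncogene" %in% toks) "oncogene"
    else if ("tsg" %in% toks) "tsg"
    else "none"
  }
  lookup <- set_names(map_chr(role_table$role_string, parse_one),
                      role_table$gene)
  tibble(gene = genes,
         role = factor(unname(ifelse(genes %in% names(lookup),
                                     lookup[genes], "none")),
                       levels = c("oncogene", "tsg", "oncogene_and_tsg",
                                  "none")))
}
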