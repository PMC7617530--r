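#' Extent of mutation clustering in 3D (EDC)
#'
#' For every residue of a subunit, the C-alpha distance to the nearest
#' *mutated* residue (other than itself) is found; the metric is the ratio of
#' the mean log nearest distance over non-mutated residues to that over
#' mutated residues. Values above 1 indicate that mutations cluster in space;
#' about 1 is expected for randomly placed mutations; below 1 for dispersed
#' sets. The log base cancels in the ratio (natural log is used).
#'
#' Residues excluded by `mask` (e.g. low-confidence pLDDT in predicted
#' models) or lacking a C-alpha enter neither numerator nor denominator.
#' Proteins with fewer than `min_mutated` mutated residues after exclusion
#' are not reported: the returned row has `edc = NA` and a `skip_reason`.
#' Coincident C-alpha coordinates (zero nearest distance) raise an error
#' rather than being clamped, to surface data problems.
#'
#' @param model A `structure_model`, or a numeric matrix / data frame of
#'   C-alpha coordinates (columns x, y, z; row i = residue index i).
#' @param mutated_residues Integer residue indices carrying mutations.
#' @param mask Optional logical keep-vector aligned with the residues (e.g.
#'   from [plddt_mask()]).
#' @param min_mutated Minimum mutated residues for a reported value,
#'   default 5.
#' @param chain_id For multi-chain models, which subunit to use (default:
#'   the first chain).
#' @param protein_id,dataset,recurrent Labels echoed into the result.
#' @return One-row `edc_result` tibble: `protein_id`, `dataset`, `recurrent`,
#'   `edc`, `n_mutated`, `n_unmutated`, `excluded_low_confidence`,
#'   `skip_reason`.
#' @export
compute_edc <- function(model, mutated_residues, mask = NULL,
                        min_mutated = 5, chain_id = NULL,
                        protein_id = NULL, dataset = NA_character_,
                        recurrent = FALSE) {
  if (inherits(model, "structure_model")) {
    cid <- chain_id %||% model$chain_id[1]
    res <- model[model$chain_id == cid, ]
    res <- res[order(res$residue_index), ]
    idx <- res$residue_index
    xyz <- as.matrix(res[, c("x", "y", "z")])
    ca_ok <- res$has_ca
    protein_id <- protein_id %||% structure_id(model)
  } else {
    xyz <- as.matrix(model)
    if (ncol(xyz) != 3) abort("coordinates must have three columns.")
    idx <- seq_len(nrow(xyz))
    ca_ok <- rep(TRUE, nrow(xyz))
    protein_id <- protein_id %||% "protein"
  }
  keep <- ca_ok & !is.na(xyz[, 1])
  if (!is.null(mask)) {
    if (length(mask) != length(keep)) {
      abort("mask length does not match the number of residues.")
    }
    keep <- keep & mask
  }
  n_excluded <- sum(!keep)
  is_mut <- idx %in% mutated_residues
  kept_mut <- which(keep & is_mut)
  kept_non <- which(keep & !is_mut)
  row <- function(edc, skip_reason = NA_character_) {
    structure(
      tibble(protein_id = protein_id, dataset = dataset,
             recurrent = recurrent, edc = edc,
             n_mutated = length(kept_mut), n_unmutated = length(kept_non),
             excluded_low_confidence = n_excluded,
             skip_reason = skip_reason),
      class = c("edc_result", class(tibble())))
  }
  if (length(kept_mut) < min_mutated) {
    return(row(NA_real_, paste0("fewer than ", min_mutated,
                                " mutated residues")))
  }
  if (length(kept_non) < 1) {
    abort("no non-mutated residues remain; EDC undefined.")
  }
  mut_xyz <- xyz[kept_mut, , drop = FALSE]
  all_idx <- c(kept_mut, kept_non)
  # distances from every kept residue to every kept mutated residue
  d2 <- outer(rowSums(xyz[all_idx, , drop = FALSE]^2),
              rowSums(mut_xyz^2), "+") -
    2 * xyz[all_idx, , drop = FALSE] %*% t(mut_xyz)
  d2[d2 < 0] <- 0
  nm <- length(kept_mut)
  d2[cbind(seq_len(nm), seq_len(nm))] <- Inf  # a mutated residue is not its own neighbour
  dmin <- sqrt(apply(d2, 1, min))
  if (any(dmin == 0)) {
    abort("coincident C-alpha coordinates give a zero nearest distance.")
  }
  dbar_mut <- mean(log(dmin[seq_len(nm)]))
  dbar_non <- mean(log(dmin[-seq_len(nm)]))
  row(dbar_non / dbar_mut)
}

#' EDC from recurrent mutations across proteins
#'
#' Applies the recurrence filter, collapses mutations to distinct residues
#' per protein, and computes EDC against the matching structure. Predicted
#' models are masked at the pLDDT threshold; experimental structures use all
#' residues. Proteins whose structures are missing or that fall below the
#' residue threshold are returned with `edc = NA` and a `skip_reason`.
#'
#' @param records Mutation tibble (see [read_mutations()]).
#' @param structures Named list of `structure_model`s, keyed by
#'   `protein_id`.
#' @param min_recurrence Recurrence threshold, default 7; set to 1 to use
#'   all mutations (non-recurrent EDC).
#' @param min_mutated Minimum mutated residues, default 5.
#' @param plddt_threshold Confidence cutoff for predicted models, default 70.
#' @return `edc_result` tibble, one row per protein in `records`.
#' @export
recurrent_edc <- function(records, structures, min_recurrence = 7,
                          min_mutated = 5, plddt_threshold = 70) {
  recs <- if (min_recurrence > 1) {
    filter_recurrent(records, min_recurrence)
  } else records
  all_prot <- unique(records$protein_id)
  out <- map(all_prot, function(pid) {
    sub <- recs[recs$protein_id == pid, ]
    dset <- records$dataset[records$protein_id == pid][1]
    model <- structures[[pid]]
    if (is.null(model)) {
      return(structure(
        tibble(protein_id = pid, dataset = dset,
               recurrent = min_recurrence > 1, edc = NA_real_,
               n_mutated = 0L, n_unmutated = 0L,
               excluded_low_confidence = 0L,
               skip_reason = "no structure"),
        class = c("edc_result", class(tibble()))))
    }
    mask <- if (structure_source(model) == "predicted") {
      plddt_mask(model, plddt_threshold)
    } else NULL
    compute_edc(model, unique(sub$position), mask = mask,
                min_mutated = min_mutated, protein_id = pid,
                dataset = dset, recurrent = min_recurrence > 1)
  })
  structure(list_rbind(out), class = c("edc_result", class(tibble())))
}
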