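default_config <- function() {
  list(structures_dir = NULL, stability_path = NULL, mutations = list(),
       role_table = NULL, dssp_dir = NULL, out_dir = "oncostruct-run",
       seed = 1L,
       rsa_interior = 0.3, rsa_surface = 0.5, min_recurrence = 7,
       min_mutated = 5, plddt = 70, min_identity = 90, min_length = 50,
       alpha = 0.05, interface_mode = "rsa", exact_limit = 40,
       asa_scale = "tien_theoretical", n_points = 960, probe_radius = 1.4,
       top_n = 50, compute_context = TRUE)
}

#' Read and validate a run configuration
#'
#' A configuration is a YAML file (or list) whose keys are the pipeline
#' inputs and thresholds; unknown keys raise a usage error naming the key.
#' All thresholds are echoed verbatim into every output header so a run is
#' self-describing.
#'
#' @param config Path to a YAML file or a named list.
#' @return Complete configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  base[names(config)] <- config
  base
}

threshold_header <- function(config) {
  keys <- c("rsa_interior", "rsa_surface", "min_recurrence", "min_mutated",
            "plddt", "min_identity", "min_length", "alpha", "interface_mode",
            "exact_limit", "asa_scale", "seed")
  sprintf("# %s: %s", keys, map_chr(config[keys], ~ format(.x)))
}

write_output <- function(df, path, config) {
  writeLines(threshold_header(config), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  path
}

#' Run the end-to-end structural analysis pipeline
#'
#' Orchestrates the full analysis over a directory of structures, a
#' stability table and one or more mutation tables: residue-level structural
#' context, rank-normalised stability landscapes, the gene-level volcano of
#' ddG_rank differences with Bonferroni flags, EDC and recurrent-EDC
#' clustering, dataset-level group comparisons, and top-N candidate tables.
#' Missing inputs degrade gracefully: each skipped product is logged with a
#' reason, and the run fails only on hard errors (e.g. an invalid
#' configuration). With a fixed seed the output tables are byte-identical
#' across runs.
#'
#' @param config Path to a YAML config or a named list; see
#'   [read_run_config()].
#' @return Invisibly, a list with the output tables, the log lines and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  out <- list()

  structures <- list()
  if (!is.null(cfg$structures_dir) && dir.exists(cfg$structures_dir)) {
    paths <- sort(list.files(cfg$structures_dir, "\\.(pdb|cif)$",
                             full.names = TRUE))
    structures <- map(paths, read_structure)
    structures <- set_names(structures, map_chr(structures, structure_id))
    note("read ", length(structures), " structures")
  } else {
    note("skip: no structures directory")
  }

  mutations <- imap(cfg$mutations, function(path, dataset) {
    deduplicate_mutations(read_mutations(path, dataset))
  })
  muts_all <- if (length(mutations)) list_rbind(unname(mutations)) else NULL

  if (cfg$compute_context && length(structures)) {
    ctx <- imap(structures, function(model, pid) {
      dssp_path <- if (!is.null(cfg$dssp_dir)) {
        fp <- file.path(cfg$dssp_dir, paste0(pid, ".dssp"))
        if (file.exists(fp)) fp else NULL
      }
      residue_context(model, dssp = dssp_path,
                      interface_mode = cfg$interface_mode,
                      asa_scale = cfg$asa_scale,
                      probe_radius = cfg$probe_radius,
                      n_points = cfg$n_points,
                      rsa_interior = cfg$rsa_interior,
                      rsa_surface = cfg$rsa_surface)
    }) |> list_rbind()
    out$residue_context <- ctx
    write_output(ctx, file.path(cfg$out_dir, "residue_context.tsv"), cfg)
  } else {
    note("skip: residue context (disabled or no structures)")
  }

  stab <- NULL
  if (!is.null(cfg$stability_path) && file.exists(cfg$stability_path)) {
    stab <- ddg_rank(read_foldx_output(cfg$stability_path))
    out$stability <- stab
    write_output(as_tibble(stab),
                 file.path(cfg$out_dir, "stability_ranks.tsv"), cfg)
    note("ranked stability landscapes for ",
         length(unique(stab$protein_id)), " proteins")
  } else {
    note("skip: stability landscape (no stability table)")
  }

  obs_all <- if (!is.null(muts_all)) {
    muts_all |> filter(.data$dataset == "cancer_all")
  }
  if (!is.null(stab) && !is.null(obs_all) && nrow(obs_all)) {
    volcano <- map(unique(stab$protein_id), function(pid) {
      gene_damage_enrichment(
        stab[stab$protein_id == pid, ],
        obs_all[obs_all$protein_id == pid, ],
        structure_source = "predicted", exact_limit = cfg$exact_limit)
    }) |> list_rbind() |> add_significance(alpha = cfg$alpha)
    out$volcano <- volcano
    write_output(as_tibble(volcano),
                 file.path(cfg$out_dir, "volcano.tsv"), cfg)
  } else {
    note("skip: volcano (needs stability table and cancer_all mutations)")
  }

  edc_rows <- list()
  if (length(structures) && !is.null(muts_all)) {
    drivers <- muts_all |> filter(.data$dataset == "cancer_driver")
    if (nrow(drivers)) {
      edc_rows$driver <- recurrent_edc(drivers, structures,
                                       min_recurrence = 1,
                                       min_mutated = cfg$min_mutated,
                                       plddt_threshold = cfg$plddt)
    }
    if (!is.null(obs_all) && nrow(obs_all)) {
      edc_rows$recurrent <- recurrent_edc(obs_all, structures,
                                          min_recurrence = cfg$min_recurrence,
                                          min_mutated = cfg$min_mutated,
                                          plddt_threshold = cfg$plddt)
    }
  }
  edcs <- if (length(edc_rows)) {
    structure(list_rbind(unname(map(edc_rows, as_tibble))),
              class = c("edc_result", class(tibble())))
  }
  if (!is.null(edcs)) {
    out$edc <- edcs
    write_output(edcs, file.path(cfg$out_dir, "edc.tsv"), cfg)
    note("EDC computed for ", sum(!is.na(edcs$edc)), " protein/dataset pairs; ",
         sum(!is.na(edcs$skip_reason)), " skipped")
  } else {
    note("skip: EDC (needs structures and mutations)")
  }

  if (!is.null(stab) && !is.null(muts_all) && nrow(muts_all)) {
    with_ranks <- muts_all |>
      inner_join(as_tibble(stab) |>
                   select("protein_id", "position", "ref_aa", "alt_aa",
                          "ddg_rank"),
                 by = c("protein_id", "position", "ref_aa", "alt_aa"))
    dsets <- unique(with_ranks$dataset)
    pairs <- if (length(dsets) >= 2) combn(dsets, 2, simplify = FALSE)
             else list()
    comps <- map(pairs, ~ compare_groups(with_ranks, "ddg_rank",
                                         .x[1], .x[2],
                                         exact_limit = cfg$exact_limit))
    if (length(comps)) {
      gc_tbl <- list_rbind(map(comps, as_tibble))
      out$group_comparisons <- gc_tbl
      write_output(gc_tbl, file.path(cfg$out_dir, "group_comparisons.tsv"),
                   cfg)
    }
  } else {
    note("skip: group comparisons (needs stability table and mutations)")
  }

  if (!is.null(out$volcano)) {
    ranks <- rank_candidates(out$volcano,
                             if (!is.null(edcs)) {
                               edcs |> filter(.data$recurrent)
                             },
                             top_n = cfg$top_n)
    out$rankings <- ranks
    write_output(ranks$damage, file.path(cfg$out_dir, "top_damage.tsv"), cfg)
    write_output(ranks$clustering,
                 file.path(cfg$out_dir, "top_clustering.tsv"), cfg)
    write_output(tibble(protein_id = ranks$overlap),
                 file.path(cfg$out_dir, "top_overlap.tsv"), cfg)
  } else {
    note("skip: candidate rankings (needs volcano)")
  }

  manifest <- list(package = "oncostruct",
                   version = as.character(utils::packageVersion("oncostruct")),
                   config = cfg[!map_lgl(cfg, is.null)],
                   outputs = sort(list.files(cfg$out_dir, "\\.tsv$")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(c(out, list(log = log_lines, out_dir = cfg$out_dir)))
}

#' Write a self-contained synthetic input bundle
#'
#' Generates a labelled cohort with [generate_mutation_cohort()] and writes
#' it in the same formats the pipeline reads: per-gene PDB files (C-alpha
#' traces with pLDDT in the B-factor column), a generic stability CSV, a
#' cancer_all mutation TSV, a gene-role table derived from the truth labels,
#' the truth table itself and a ready-to-run pipeline config YAML.
#'
#' @param out_dir Directory to create the bundle in.
#' @param n_genes Number of genes, default 12.
#' @param seed Base seed, default 1.
#' @param n_residues Residues per gene, default 120.
#' @param frac_tsg,frac_onco Cohort composition, defaults 0.25 each.
#' @param ... Passed to [synthetic_spec()] via [cohort_specs()].
#' @return Path to the written config YAML, invisibly.
#' @export
simulate_bundle <- function(out_dir, n_genes = 12, seed = 1,
                            n_residues = 120, frac_tsg = 0.25,
                            frac_onco = 0.25, ...) {
  dir.create(file.path(out_dir, "structures"), showWarnings = FALSE,
             recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  if (n_genes == 0) {
    warn("n_genes = 0: writing an empty bundle.")
    cohort <- list(mutations = tibble(), truth = tibble(),
                   structures = list(), stability = tibble())
  } else {
    cohort <- generate_mutation_cohort(
      cohort_specs(n_genes = n_genes, frac_tsg = frac_tsg,
                   frac_onco = frac_onco, seed = seed,
                   n_residues = n_residues, ...))
  }
  for (pid in names(cohort$structures)) {
    write_chain_pdb(cohort$structures[[pid]],
                    file.path(out_dir, "structures", paste0(pid, ".pdb")))
  }
  readr::write_csv(cohort$stability, file.path(out_dir, "stability.csv"))
  readr::write_tsv(cohort$mutations,
                   file.path(out_dir, "mutations_cancer_all.tsv"))
  if (nrow(cohort$truth)) {
    roles <- cohort$truth |>
      mutate(role_string = c(tsg_like = "TSG", oncogene_like = "oncogene",
                             neutral = "")[.data$label]) |>
      select("gene", "role_string")
    readr::write_tsv(roles, file.path(out_dir, "role_table.tsv"))
    readr::write_tsv(cohort$truth, file.path(out_dir, "truth.tsv"))
  }
  cfg <- list(structures_dir = file.path(out_dir, "structures"),
              stability_path = file.path(out_dir, "stability.csv"),
              mutations = list(
                cancer_all = file.path(out_dir, "mutations_cancer_all.tsv")),
              role_table = file.path(out_dir, "role_table.tsv"),
              out_dir = file.path(out_dir, "results"),
              seed = seed)
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
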