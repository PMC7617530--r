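#' Specification for one synthetic gene/protein
#'
#' Bundles the parameters of the synthetic generators: chain geometry,
#' stability-landscape model and mutation model. The seed fully determines
#' every generated artefact. Default effect sizes (damage fraction 0.75 from
#' the top 30% of |ddG|; spatial cluster of 5% of residues) are chosen so
#' that recovery of the implanted signal is strong but not trivial.
#'
#' @param gene Gene/protein identifier.
#' @param n_residues Chain length (>= 5), default 200.
#' @param chain_geometry `"compact_random_walk"` (default), `"line"` or
#'   `"ideal_helix"`.
#' @param ca_spacing Consecutive C-alpha distance in Angstrom, default 3.8.
#' @param ddg_model `"lognormal"` (default) or `"mixture"` (adds a 10%
#'   heavy-tail component of strongly destabilising outliers).
#' @param ddg_meanlog,ddg_sdlog Log-normal parameters of |ddG| in kcal/mol;
#'   the defaults give a median of 1 kcal/mol, keeping most values below the
#'   ~3 kcal/mol bulk seen in real predictor output.
#' @param prob_destabilizing Probability a ddG is positive, default 0.85.
#' @param mutation_model `"uniform"` (neutral gene), `"damage_enriched"`
#'   (TSG-like: observed mutations drawn preferentially from the most
#'   destabilising substitutions) or `"clustered"` (oncogene-like: observed
#'   mutations drawn from a spatial neighbourhood).
#' @param n_observed Number of observed variants to draw, default 50.
#' @param damage_q Quantile of |ddG| defining the damaging pool, default 0.7.
#' @param damage_f Fraction of draws taken from the damaging pool,
#'   default 0.75.
#' @param cluster_frac Cluster size as a fraction of residues, default 0.05.
#' @param cluster_f Fraction of draws taken from the cluster, default 0.75.
#' @param recurrence_mean Mean of the zero-truncated geometric recurrence
#'   distribution, default 3 (so the recurrence >= 7 filter retains a
#'   realistic minority).
#' @param cluster_recurrence_mean Recurrence mean for cluster draws,
#'   default 12 (recurrent hotspot behaviour).
#' @param plddt Constant pLDDT written into the model's B-factor column,
#'   default 90.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(gene = "GENE1", n_residues = 200,
                           chain_geometry = c("compact_random_walk", "line",
                                              "ideal_helix"),
                           ca_spacing = 3.8,
                           ddg_model = c("lognormal", "mixture"),
                           ddg_meanlog = 0, ddg_sdlog = 1,
                           prob_destabilizing = 0.85,
                           mutation_model = c("uniform", "damage_enriched",
                                              "clustered"),
                           n_observed = 50, damage_q = 0.7, damage_f = 0.75,
                           cluster_frac = 0.05, cluster_f = 0.75,
                           recurrence_mean = 3, cluster_recurrence_mean = 12,
                           plddt = 90, seed = NULL) {
  if (n_residues < 5) abort("n_residues must be >= 5.")
  if (ca_spacing <= 0) abort("ca_spacing must be positive.")
  structure(list(gene = gene, n_residues = n_residues,
                 chain_geometry = match.arg(chain_geometry),
                 ca_spacing = ca_spacing, ddg_model = match.arg(ddg_model),
                 ddg_meanlog = ddg_meanlog, ddg_sdlog = ddg_sdlog,
                 prob_destabilizing = prob_destabilizing,
                 mutation_model = match.arg(mutation_model),
                 n_observed = n_observed, damage_q = damage_q,
                 damage_f = damage_f, cluster_frac = cluster_frac,
                 cluster_f = cluster_f, recurrence_mean = recurrence_mean,
                 cluster_recurrence_mean = cluster_recurrence_mean,
                 plddt = plddt, seed = seed),
            class = "synthetic_spec")
}

walk_coords <- function(n, spacing, min_sep = 3.5, pull = 0.35,
                        max_tries = 200, max_restarts = 50) {
  for (restart in seq_len(max_restarts)) {
    xyz <- matrix(0, n, 3)
    failed <- FALSE
    for (i in seq(2, n)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        d <- rnorm(3)
        d <- d / sqrt(sum(d^2))
        ctr <- colMeans(xyz[seq_len(i - 1), , drop = FALSE])
        to_ctr <- ctr - xyz[i - 1, ]
        np <- sqrt(sum(to_ctr^2))
        if (np > 1e-9) {
          d <- d + pull * to_ctr / np
          d <- d / sqrt(sum(d^2))
        }
        cand <- xyz[i - 1, ] + spacing * d
        if (i > 2) {
          prev <- xyz[seq_len(i - 2), , drop = FALSE]
          dd2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
            (prev[, 3] - cand[3])^2
          if (min(dd2) < min_sep^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) return(xyz)
  }
  abort("could not pack a self-avoiding chain (infeasible geometry).")
}

helix_coords <- function(n, spacing) {
  rise <- 1.5; radius <- 2.3; turn <- 100 * pi / 180
  th <- (seq_len(n) - 1) * turn
  xyz <- cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
  step <- sqrt(sum((xyz[2, ] - xyz[1, ])^2))
  xyz * (spacing / step)  # honour the requested consecutive spacing
}

#' Generate a synthetic C-alpha chain
#'
#' Builds a single-chain predicted-model [as_structure_model()] with the
#' requested geometry: a straight line, an ideal alpha-helix (1.5 Angstrom
#' rise, 100 degrees per residue, 2.3 Angstrom radius, scaled so consecutive
#' C-alpha atoms sit `ca_spacing` apart) or a compact self-avoiding random
#' walk (non-consecutive residues kept at least 3.5 Angstrom apart, with a
#' centroid-bias that yields globule-like compactness). A random amino-acid
#' sequence is attached. Seed-deterministic.
#'
#' @param spec A [synthetic_spec()].
#' @return A `structure_model` (source `"predicted"`, pLDDT in `bfactor`).
#' @export
generate_chain <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_residues
  xyz <- switch(spec$chain_geometry,
    line = cbind((seq_len(n) - 1) * spec$ca_spacing, 0, 0),
    ideal_helix = helix_coords(n, spec$ca_spacing),
    compact_random_walk = walk_coords(n, spec$ca_spacing))
  res <- tibble(chain_id = "A", residue_index = seq_len(n),
                author_number = seq_len(n),
                aa = sample(AA1, n, replace = TRUE),
                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                bfactor = spec$plddt, has_ca = TRUE)
  as_structure_model(res, structure_id = spec$gene, source = "predicted")
}

#' Generate a synthetic stability landscape
#'
#' One ddG value per possible substitution per residue (19 per position).
#' Magnitudes are log-normal (median `exp(ddg_meanlog)` kcal/mol, so the
#' bulk of values stays small with occasional large outliers, as real
#' predictor output does); the sign is destabilising with probability
#' `prob_destabilizing`. The `"mixture"` model adds a 10% strongly
#' destabilising component. Seed-deterministic (offset from the chain seed
#' so chain and landscape are independent draws).
#'
#' @param spec A [synthetic_spec()].
#' @param model Optional `structure_model` supplying the reference sequence;
#'   when omitted a sequence is drawn from the generator seed.
#' @return Tibble `protein_id`, `position`, `ref_aa`, `alt_aa`, `ddg`.
#' @export
generate_ddg_landscape <- function(spec, model = NULL) {
  if (!is.null(spec$seed)) set.seed(spec$seed + 1L)
  n <- spec$n_residues
  ref <- if (is.null(model)) sample(AA1, n, replace = TRUE) else model$aa
  land <- tibble(position = rep(seq_len(n), each = length(AA1)),
                 ref_aa = rep(ref, each = length(AA1)),
                 alt_aa = rep(AA1, n)) |>
    filter(.data$ref_aa != .data$alt_aa)
  m <- nrow(land)
  mag <- rlnorm(m, spec$ddg_meanlog, spec$ddg_sdlog)
  if (spec$ddg_model == "mixture") {
    heavy <- runif(m) < 0.1
    mag[heavy] <- rlnorm(sum(heavy), spec$ddg_meanlog + 2, 0.5)
  }
  sgn <- ifelse(runif(m) < spec$prob_destabilizing, 1, -1)
  land |>
    mutate(protein_id = spec$gene, ddg = mag * sgn) |>
    select("protein_id", "position", "ref_aa", "alt_aa", "ddg")
}

rtrunc_geom <- function(n, mean) {
  if (mean <= 1) return(rep(1L, n))
  1L + rgeom(n, 1 / mean)
}

draw_mutations <- function(spec, model, landscape) {
  if (!is.null(spec$seed)) set.seed(spec$seed + 2L)
  n_obs <- min(spec$n_observed, nrow(landscape))
  pick <- function(pool, k) pool[sample(nrow(pool), min(k, nrow(pool))), ]
  if (spec$mutation_model == "uniform") {
    drawn <- pick(landscape, n_obs)
    drawn$recurrence <- rtrunc_geom(nrow(drawn), spec$recurrence_mean)
  } else if (spec$mutation_model == "damage_enriched") {
    thr <- stats::quantile(abs(landscape$ddg), spec$damage_q)
    top <- landscape[abs(landscape$ddg) >= thr, ]
    rest <- landscape[abs(landscape$ddg) < thr, ]
    n_top <- stats::rbinom(1, n_obs, spec$damage_f)
    drawn <- bind_rows(pick(top, n_top), pick(rest, n_obs - n_top))
    drawn$recurrence <- rtrunc_geom(nrow(drawn), spec$recurrence_mean)
  } else {  # clustered
    k <- max(3, round(spec$cluster_frac * spec$n_residues))
    center <- sample(spec$n_residues, 1)
    cxyz <- as.matrix(model[, c("x", "y", "z")])
    d2 <- rowSums(sweep(cxyz, 2, cxyz[center, ])^2)
    cluster_res <- order(d2)[seq_len(k)]
    in_cluster <- landscape$position %in% cluster_res
    n_cl <- stats::rbinom(1, n_obs, spec$cluster_f)
    cl <- pick(landscape[in_cluster, ], n_cl)
    cl$recurrence <- rtrunc_geom(nrow(cl), spec$cluster_recurrence_mean)
    away <- pick(landscape[!in_cluster, ], n_obs - n_cl)
    away$recurrence <- rtrunc_geom(nrow(away), spec$recurrence_mean)
    drawn <- bind_rows(cl, away)
  }
  drawn |>
    mutate(gene = spec$gene, dataset = "cancer_all") |>
    select("gene", "protein_id", "position", "ref_aa", "alt_aa",
           "recurrence", "dataset") |>
    deduplicate_mutations() |>
    arrange(.data$position, .data$alt_aa)
}

truth_label <- c(uniform = "neutral", damage_enriched = "tsg_like",
                 clustered = "oncogene_like")

#' Generate a synthetic mutation cohort with truth labels
#'
#' For each per-gene [synthetic_spec()], generates the chain, the stability
#' landscape and an observed mutation set according to the gene's mutation
#' model: TSG-like genes draw preferentially from the most destabilising
#' substitutions, oncogene-like genes draw from a spatial cluster with
#' hotspot-like high recurrence, neutral genes draw uniformly. Everything is
#' seed-deterministic.
#'
#' @param specs List of [synthetic_spec()]s (one per gene, each seeded).
#' @return List with `mutations` (tibble), `truth` (tibble `gene`,
#'   `protein_id`, `label`), `structures` (named list of models) and
#'   `stability` (stacked landscape tibble).
#' @export
generate_mutation_cohort <- function(specs) {
  if (inherits(specs, "synthetic_spec")) specs <- list(specs)
  models <- map(specs, generate_chain)
  lands <- map2(specs, models, generate_ddg_landscape)
  muts <- pmap(list(specs, models, lands), draw_mutations) |> list_rbind()
  list(mutations = muts,
       truth = tibble(gene = map_chr(specs, "gene"),
                      protein_id = map_chr(specs, "gene"),
                      label = unname(truth_label[
                        map_chr(specs, "mutation_model")])),
       structures = set_names(models, map_chr(specs, "gene")),
       stability = list_rbind(lands))
}

#' Default per-gene specs for a labelled study cohort
#'
#' Convenience builder for a cohort with a given mixture of TSG-like,
#' oncogene-like and neutral genes, with per-gene seeds derived from `seed`.
#'
#' @param n_genes Total genes, default 200.
#' @param frac_tsg,frac_onco Fractions of TSG-like and oncogene-like genes,
#'   defaults 0.15 each (rest neutral).
#' @param seed Base seed.
#' @param ... Further arguments passed to [synthetic_spec()].
#' @return List of `synthetic_spec`s.
#' @export
cohort_specs <- function(n_genes = 200, frac_tsg = 0.15, frac_onco = 0.15,
                         seed = 1, ...) {
  n_tsg <- round(frac_tsg * n_genes)
  n_onco <- round(frac_onco * n_genes)
  labels <- c(rep("damage_enriched", n_tsg), rep("clustered", n_onco),
              rep("uniform", n_genes - n_tsg - n_onco))
  map(seq_len(n_genes), function(i) {
    synthetic_spec(gene = sprintf("G%04d", i), mutation_model = labels[i],
                   seed = seed + 13L * i, ...)
  })
}
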