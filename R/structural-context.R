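#' Reference maximum accessible surface areas
#'
#' Per-amino-acid maximum ASA used to normalise SASA into relative solvent
#' accessibility (RSA). The default is the theoretical scale of Tien et al.
#' (2013); the empirical Tien and Miller (1987) scales can be swapped in by
#' configuration, and the scale used is recorded in the output metadata.
#'
#' @param scale One of `"tien_theoretical"`, `"tien_empirical"`, `"miller"`.
#' @return Named numeric vector (Angstrom^2) over the 20 amino acids.
#' @export
max_asa_scale <- function(scale = c("tien_theoretical", "tien_empirical",
                                    "miller")) {
  scale <- match.arg(scale)
  switch(scale,
    tien_theoretical = c(
      A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
      H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
      T = 172, W = 285, Y = 263, V = 174),
    tien_empirical = c(
      A = 121, R = 265, N = 187, D = 187, C = 148, E = 214, Q = 214, G = 97,
      H = 216, I = 195, L = 191, K = 230, M = 203, F = 228, P = 154, S = 143,
      T = 163, W = 264, Y = 255, V = 165),
    miller = c(
      A = 113, R = 241, N = 158, D = 151, C = 140, E = 183, Q = 189, G = 85,
      H = 194, I = 182, L = 180, K = 211, M = 204, F = 218, P = 143, S = 122,
      T = 146, W = 259, Y = 229, V = 160))
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               `CA-pseudo` = 3.00)
CA_PSEUDO_RADIUS <- 3.00

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.80
  unname(r)
}

sasa_atoms <- function(coords, radii, probe_radius, n_points) {
  n <- nrow(coords)
  pts <- sphere_points(n_points)
  rad <- radii + probe_radius
  out <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2 +
      (coords[, 3] - coords[i, 3])^2
    nb <- which(d2 < (rad + rad[i])^2 & d2 > 0)
    p <- sweep(pts * rad[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      acc <- acc & dj > rad[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  out
}

#' Per-residue solvent-accessible surface area
#'
#' Sphere-sampling (Shrake-Rupley style) SASA over the model's atom table,
#' summed per residue. Coarse-grained models carrying only C-alpha
#' pseudo-atoms are supported with a 3 Angstrom per-residue sphere.
#'
#' @param model A `structure_model`.
#' @param probe_radius Solvent probe radius in Angstrom, default 1.4.
#' @param n_points Sampling points per atom, default 960.
#' @param chains Optional subset of chain ids to include (atoms from other
#'   chains are removed before computing, for isolated-chain SASA).
#' @return Tibble `chain_id`, `author_number`, `sasa`.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                         chains = NULL) {
  atoms <- attr(model, "atoms", exact = TRUE)
  if (!is.null(chains)) atoms <- atoms[atoms$chain_id %in% chains, ]
  atoms <- atoms[!is.na(atoms$x), ]
  if (is.null(atoms) || nrow(atoms) == 0) abort("structure has no atoms.")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  a_sasa <- sasa_atoms(coords, atom_radius(atoms$element), probe_radius,
                       n_points)
  atoms |>
    mutate(.sasa = a_sasa) |>
    group_by(.data$chain_id, .data$author_number) |>
    summarise(sasa = sum(.data$.sasa), .groups = "drop")
}

#' Classify residue location from relative solvent accessibility
#'
#' Interior: RSA <= `interior`; interface: `interior` < RSA < `surface`;
#' surface: RSA >= `surface`. The default thresholds (0.3 and 0.5) follow the
#' published rule; both boundaries belong to the non-interface classes.
#'
#' @param rsa Numeric vector of RSA values (>= 0).
#' @param interior,surface Class thresholds.
#' @return Factor with levels interior, interface, surface.
#' @export
classify_location <- function(rsa, interior = 0.3, surface = 0.5) {
  if (any(is.na(rsa))) abort("rsa contains NA.")
  if (any(rsa < 0)) abort("rsa must be non-negative.")
  out <- ifelse(rsa <= interior, "interior",
                ifelse(rsa >= surface, "surface", "interface"))
  factor(out, levels = c("interior", "interface", "surface"))
}

collapse_ss8 <- function(ss8) {
  out <- ifelse(ss8 %in% c("H", "G", "I"), "helix",
                ifelse(ss8 %in% c("E", "B"), "strand", "other"))
  factor(out, levels = c("helix", "strand", "other"))
}

#' Read a classic-format DSSP output file
#'
#' Parses the fixed-width per-residue block and collapses the 8-state codes
#' to three classes: H/G/I to helix, E/B to strand, everything else to other.
#' The original 8-state code is retained in the `ss8` column.
#'
#' @param path Path to a DSSP output file.
#' @return Tibble `chain_id`, `author_number`, `aa`, `ss8`, `ss_class`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1) abort(paste0("not a classic DSSP file: ", path))
  body <- lines[seq(hdr + 1, length(lines))]
  body <- body[nchar(body) >= 17 & substr(body, 14, 14) != "!"]
  if (length(body) == 0) abort("DSSP file has no residue records.")
  num <- suppressWarnings(as.integer(str_trim(substr(body, 6, 10))))
  if (any(is.na(num))) abort("malformed DSSP residue records.")
  ss8 <- substr(body, 17, 17)
  ss8[ss8 == " "] <- "-"
  tibble(chain_id = substr(body, 12, 12),
         author_number = num,
         aa = substr(body, 14, 14),
         ss8 = ss8,
         ss_class = collapse_ss8(ss8))
}

#' Approximate secondary structure from C-alpha geometry
#'
#' Fallback assigner for when no DSSP output is available: classifies
#' residues from the characteristic C-alpha(i)-C-alpha(i+3) and
#' C-alpha(i)-C-alpha(i+4) distance signatures of helices (about 5.1 and
#' 6.2 Angstrom) and extended strands (> 8.5 Angstrom between i and i+3).
#' Chains shorter than five residues are all "other". Results are flagged
#' approximate in the `ss_source` column.
#'
#' @param model A `structure_model`.
#' @return Tibble `chain_id`, `residue_index`, `ss_class`, `ss_source`.
#' @export
assign_ss_fallback <- function(model) {
  per_chain <- function(res) {
    res <- res[order(res$residue_index), ]
    n <- nrow(res)
    helix_votes <- integer(n)
    strand_votes <- integer(n)
    xyz <- as.matrix(res[, c("x", "y", "z")])
    ok <- res$has_ca
    d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (n >= 5) {
      for (i in seq_len(n - 4)) {
        idx <- i:(i + 4)
        if (!all(ok[idx])) next
        d13 <- d(i, i + 3); d14 <- d(i, i + 4)
        if (d13 >= 4.2 && d13 <= 6.2 && d14 >= 5.2 && d14 <= 7.2) {
          helix_votes[idx] <- helix_votes[idx] + 1L
        }
      }
      for (i in seq_len(n - 3)) {
        idx <- i:(i + 3)
        if (!all(ok[idx])) next
        if (d(i, i + 3) > 8.5) strand_votes[idx] <- strand_votes[idx] + 1L
      }
    }
    cls <- ifelse(helix_votes > 0 & helix_votes >= strand_votes, "helix",
                  ifelse(strand_votes > 0, "strand", "other"))
    tibble(chain_id = res$chain_id, residue_index = res$residue_index,
           ss_class = factor(cls, levels = c("helix", "strand", "other")),
           ss_source = "ca_geometry_approx")
  }
  model |>
    as_tibble() |>
    group_by(.data$chain_id) |>
    group_split() |>
    map(per_chain) |>
    list_rbind()
}

#' Residue-level structural context table
#'
#' Computes SASA, RSA, the interior/interface/surface location class and a
#' secondary-structure class for every residue of a model. Secondary
#' structure comes from a DSSP output file when one is supplied, otherwise
#' from the approximate C-alpha geometry assigner. Two interface definitions
#' are available: the default RSA-interval rule (0.3 < RSA < 0.5) and a
#' burial-on-assembly rule (`"delta_rsa"`) that calls interface wherever the
#' isolated-chain RSA exceeds the assembly RSA, with the remaining residues
#' split interior/surface at the interior threshold.
#'
#' @param model A `structure_model`.
#' @param dssp Optional path to a DSSP output file for this structure.
#' @param interface_mode `"rsa"` (default, published interval rule) or
#'   `"delta_rsa"`.
#' @param asa_scale Reference maximum-ASA scale name; see [max_asa_scale()].
#' @param probe_radius,n_points SASA sampling parameters.
#' @param rsa_interior,rsa_surface Location thresholds (defaults 0.3, 0.5).
#' @return Tibble `structure_id`, `chain_id`, `residue_index`, `aa`, `sasa`,
#'   `rsa`, `location`, `ss_class`, `ss_source`; the ASA scale and mode are
#'   recorded as attributes.
#' @export
residue_context <- function(model, dssp = NULL,
                            interface_mode = c("rsa", "delta_rsa"),
                            asa_scale = "tien_theoretical",
                            probe_radius = 1.4, n_points = 960,
                            rsa_interior = 0.3, rsa_surface = 0.5) {
  interface_mode <- match.arg(interface_mode)
  ref <- max_asa_scale(asa_scale)
  atoms <- attr(model, "atoms", exact = TRUE)
  pseudo <- all(atoms$element == "CA-pseudo")
  ref_pseudo <- 4 * pi * (CA_PSEUDO_RADIUS + probe_radius)^2
  rsa_of <- function(sasa_tbl) {
    joined <- as_tibble(model) |>
      left_join(sasa_tbl, by = c("chain_id", "author_number"))
    joined$sasa[is.na(joined$sasa)] <- 0
    if (pseudo) joined$rsa <- joined$sasa / ref_pseudo
    else joined$rsa <- joined$sasa / unname(ref[joined$aa])
    joined
  }
  ctx <- rsa_of(compute_sasa(model, probe_radius, n_points))
  if (interface_mode == "rsa") {
    ctx$location <- classify_location(ctx$rsa, rsa_interior, rsa_surface)
  } else {
    iso <- as_tibble(model) |>
      group_by(.data$chain_id) |>
      group_split() |>
      map(function(res) {
        compute_sasa(model, probe_radius, n_points,
                     chains = res$chain_id[1])
      }) |>
      list_rbind()
    ctx$rsa_isolated <- rsa_of(iso)$rsa
    at_interface <- (ctx$rsa_isolated - ctx$rsa) > 1e-9
    loc <- ifelse(at_interface, "interface",
                  ifelse(ctx$rsa <= rsa_interior, "interior", "surface"))
    ctx$location <- factor(loc, levels = c("interior", "interface", "surface"))
  }
  if (!is.null(dssp)) {
    ss <- read_dssp(dssp) |>
      select("chain_id", "author_number", "ss_class") |>
      mutate(ss_source = "dssp")
    ctx <- ctx |> left_join(ss, by = c("chain_id", "author_number"))
    ctx$ss_class[is.na(ctx$ss_class)] <- "other"
    ctx$ss_source[is.na(ctx$ss_source)] <- "dssp"
  } else {
    ss <- assign_ss_fallback(model)
    ctx <- ctx |> left_join(ss, by = c("chain_id", "residue_index"))
  }
  out <- ctx |>
    transmute(structure_id = structure_id(model), .data$chain_id,
              .data$residue_index, .data$aa, .data$sasa, .data$rsa,
              .data$location, .data$ss_class, .data$ss_source)
  structure(out, asa_scale = if (pseudo) "ca_pseudo_sphere" else asa_scale,
            interface_mode = interface_mode)
}
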