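# Shrake-Rupley solvent-accessible surface area, shell classification at the
# 20 A^2 exposure criterion, and haloadaptation composition statistics.

# Deterministic golden-spiral point set on the unit sphere. Near-uniform, so
# the exposed fraction of test points estimates the exposed solid angle.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

# Covariant local frame for atom i, built from the directions to its nearest
# neighbours (ties broken by atom index; both distance ordering and index are
# unchanged by a global rotation, so the frame rotates exactly with the
# structure and SASA is rigid-motion invariant to machine precision).
# Isolated atoms get the identity frame (every point is exposed anyway) and
# collinear structures an arbitrary azimuth (occlusion is then axially
# symmetric, so the azimuth cannot matter).
local_frame <- function(i, coords) {
  n <- nrow(coords)
  if (n < 2) return(diag(3))
  d2 <- colSums((t(coords) - coords[i, ])^2)
  d2[i] <- Inf
  ord <- order(d2, seq_len(n))
  u1 <- coords[ord[1], ] - coords[i, ]
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- NULL
  for (j in ord[-1]) {
    if (!is.finite(d2[j])) break
    w <- coords[j, ] - coords[i, ]
    w <- w - sum(w * u1) * u1
    nw <- sqrt(sum(w^2))
    if (nw > 1e-8 * sqrt(d2[j])) {
      u2 <- w / nw
      break
    }
  }
  if (is.null(u2)) {
    # collinear: any perpendicular will do (axially symmetric occlusion)
    e <- diag(3)[, which.min(abs(u1))]
    u2 <- e - sum(e * u1) * u1
    u2 <- u2 / sqrt(sum(u2^2))
  }
  cbind(u2, pracma_cross(u1, u2), u1)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the structure by testing, for every atom, a
#' deterministic golden-spiral set of points on its probe-expanded sphere;
#' the accessible area is the exposed fraction of points times the sphere
#' area `4 pi (r + probe)^2`. Each atom's point set is expressed in a local
#' frame built from its nearest-neighbour directions, which rotates with the
#' structure, so the result is exactly invariant under global rigid motion.
#'
#' @param atoms Atoms tibble (see [parse_pdb()]); needs `x`, `y`, `z`,
#'   `vdw_radius` and, for residue aggregation, `chain_id`, `residue_seq`,
#'   `residue_name`.
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Test points per atom (default 960; at least 16).
#' @param include_hydrogens Include H atoms? Default `FALSE`: homology models
#'   are typically heavy-atom and surface work excludes hydrogens.
#' @return The atoms tibble (minus excluded hydrogens) with an added `sasa`
#'   column in Angstrom^2.
#' @examples
#' one_c <- gen_toy_structure("isolated")
#' shrake_rupley_sasa(one_c)$sasa  # 4*pi*3.1^2 = 120.76
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960,
                               include_hydrogens = FALSE) {
  check_columns(atoms, c("x", "y", "z", "vdw_radius"), "atoms")
  check_number(probe, "probe", non_negative = TRUE)
  if (!is.numeric(n_points) || n_points < 16) {
    abort("`n_points` must be at least 16.",
          class = "halokin_invalid_parameter")
  }
  if (nrow(atoms) == 0) {
    abort("Structure is empty.", class = "halokin_empty_structure")
  }
  if (!include_hydrogens && "element" %in% names(atoms)) {
    atoms <- atoms[atoms$element != "H", ]
    if (nrow(atoms) == 0) {
      abort("Structure contains only hydrogens.",
            class = "halokin_empty_structure")
    }
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(coords))) {
    abort("Coordinates must be finite.", class = "halokin_invalid_parameter")
  }
  radii <- atoms$vdw_radius + probe
  n <- nrow(coords)
  pts <- golden_spiral_points(n_points)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- radii[i]
    # neighbours whose expanded spheres can occlude atom i's sphere surface
    d2 <- colSums((t(coords) - coords[i, ])^2)
    d2[i] <- Inf
    nb <- which(d2 < (Ri + radii)^2)
    if (length(nb) == 0) {
      sasa[i] <- 4 * pi * Ri^2
      next
    }
    frame <- local_frame(i, coords)
    surf <- pts %*% t(frame) * Ri
    surf <- sweep(surf, 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (surf[, 1] - coords[j, 1])^2 + (surf[, 2] - coords[j, 2])^2 +
        (surf[, 3] - coords[j, 3])^2
      exposed <- exposed & dj2 > radii[j]^2
      if (!any(exposed)) break
    }
    sasa[i] <- sum(exposed) / n_points * 4 * pi * Ri^2
  }
  dplyr::mutate(as_tibble(atoms), sasa = sasa)
}

backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Aggregate per-atom SASA to residues
#'
#' @param per_atom Output of [shrake_rupley_sasa()].
#' @param sidechain_only Sum only side-chain atoms (backbone N, CA, C, O, OXT
#'   excluded)? Exposure criteria are sometimes defined on side-chain area
#'   only; the default sums all atoms of the residue.
#' @return A tibble `chain_id`, `residue_seq`, `residue_name`, `sasa`.
#' @export
residue_sasa <- function(per_atom, sidechain_only = FALSE) {
  check_columns(per_atom, c("chain_id", "residue_seq", "residue_name", "sasa"),
                "per_atom")
  df <- per_atom
  if (sidechain_only) df <- df[!(df$atom_name %in% backbone_atoms), ]
  df |>
    dplyr::group_by(.data$chain_id, .data$residue_seq, .data$residue_name) |>
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop")
}

#' Classify residues into exposed and core shells
#'
#' A residue is part of the exposed (external) shell when its solvent
#' accessible surface is at least `threshold` (boundary inclusive: exactly
#' 20 A^2 counts as exposed); otherwise it belongs to the core (internal
#' shell).
#'
#' @param res_sasa Per-residue tibble with a `sasa` column (see
#'   [residue_sasa()]), or an already-classified table to re-threshold.
#' @param threshold Exposure criterion in A^2 (default 20).
#' @return The input with an added `shell` column, `"exposed"` or `"core"`.
#' @export
classify_shells <- function(res_sasa, threshold = 20) {
  check_columns(res_sasa, "sasa", "res_sasa")
  if (any(res_sasa$sasa < 0)) {
    abort("SASA values must be >= 0.", class = "halokin_invalid_parameter")
  }
  dplyr::mutate(as_tibble(res_sasa),
                shell = ifelse(.data$sasa >= threshold, "exposed", "core"))
}

# Standard amino-acid volumes (A^3), Zamyatnin-style, keyed by 3-letter code.
#' Standard residue volumes
#'
#' Mean residue volumes in Angstrom^3 used for the core-fraction-by-volume
#' statistic.
#' @return Named numeric vector keyed by 3-letter residue code.
#' @export
residue_volumes <- function() {
  c(ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
    GLN = 143.8, GLU = 138.4, GLY = 60.1, HIS = 153.2, ILE = 166.7,
    LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
    SER = 89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)
}

default_hydrophobic <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                         "CYS", "GLY")

#' Shell composition statistics
#'
#' The per-shell residue-type percentages and the summary statistics used to
#' characterise haloadaptation: the core fraction by residue count and by
#' summed standard residue volume, the acidic (Asp+Glu) fraction per shell,
#' and per-type exposure counts (e.g. how many tryptophans are exposed).
#'
#' @param shells Classified table from [classify_shells()] with
#'   `residue_name` and `shell` columns.
#' @param hydrophobic Residue set counted as the hydrophobic core (default
#'   A, V, L, I, M, F, W, C, G as 3-letter codes).
#' @param volumes Named volume table (default [residue_volumes()]); unknown
#'   residue types contribute the mean tabulated volume.
#' @return A list of class `shell_composition` with tibbles `by_type`
#'   (shell, residue_name, n, pct), `overall` (core fractions by count and
#'   by volume, plus the same restricted to the hydrophobic set), `acidic`
#'   (per-shell Asp+Glu percentage) and `exposure` (per-type exposed/total
#'   counts).
#' @export
shell_composition <- function(shells, hydrophobic = default_hydrophobic,
                              volumes = residue_volumes()) {
  check_columns(shells, c("residue_name", "shell"), "shells")
  if (nrow(shells) == 0) {
    abort("Shell table is empty.", class = "halokin_invalid_parameter")
  }
  shells <- as_tibble(shells)
  by_type <- shells |>
    dplyr::count(.data$shell, .data$residue_name, name = "n") |>
    dplyr::group_by(.data$shell) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  vol <- unname(volumes[shells$residue_name])
  vol[is.na(vol)] <- mean(volumes)
  core <- shells$shell == "core"
  hydro <- shells$residue_name %in% hydrophobic
  overall <- tibble(
    n_residues = nrow(shells),
    core_fraction_count = 100 * mean(core),
    core_fraction_volume = 100 * sum(vol[core]) / sum(vol),
    hydrophobic_core_fraction_count = 100 * sum(core & hydro) / nrow(shells),
    hydrophobic_core_fraction_volume = 100 * sum(vol[core & hydro]) / sum(vol))
  acidic <- shells |>
    dplyr::group_by(.data$shell) |>
    dplyr::summarise(
      n = dplyr::n(),
      acidic_pct = 100 * mean(.data$residue_name %in% c("ASP", "GLU")),
      .groups = "drop")
  exposure <- shells |>
    dplyr::group_by(.data$residue_name) |>
    dplyr::summarise(n_exposed = sum(.data$shell == "exposed"),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(exposure = paste0(.data$n_exposed, "/", .data$n_total))
  structure(list(by_type = by_type, overall = overall, acidic = acidic,
                 exposure = exposure,
                 shell_levels = sort(unique(shells$shell))),
            class = "shell_composition")
}

#' @export
print.shell_composition <- function(x, ...) {
  cat("Shell composition (", x$overall$n_residues, " residues)\n", sep = "")
  cat(sprintf("  core fraction: %.1f%% by count, %.1f%% by volume\n",
              x$overall$core_fraction_count, x$overall$core_fraction_volume))
  print(x$by_type, n = 10)
  invisible(x)
}

#' Compare two shell-composition reports
#'
#' Pairs the per-type percentages of two structures (e.g. a halophilic
#' protein against a non-halophilic homolog) shell by shell and sorts by the
#' magnitude of the difference.
#'
#' @param report_a,report_b `shell_composition` objects over the same shell
#'   scheme.
#' @return A tibble `shell`, `residue_name`, `pct_a`, `pct_b`, `diff`
#'   (`pct_a - pct_b`), ordered by decreasing `|diff|`. Types absent from one
#'   report count as 0%.
#' @export
compare_compositions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "shell_composition"),
            inherits(report_b, "shell_composition"))
  if (!identical(report_a$shell_levels, report_b$shell_levels)) {
    abort("Reports use different shell schemes.",
          class = "halokin_invalid_parameter")
  }
  a <- dplyr::select(report_a$by_type, "shell", "residue_name", pct_a = "pct")
  b <- dplyr::select(report_b$by_type, "shell", "residue_name", pct_b = "pct")
  dplyr::full_join(a, b, by = c("shell", "residue_name")) |>
    tidyr::replace_na(list(pct_a = 0, pct_b = 0)) |>
    dplyr::mutate(diff = .data$pct_a - .data$pct_b) |>
    dplyr::arrange(dplyr::desc(abs(.data$diff)))
}

#' Write a per-residue shell table as TSV
#'
#' Columns `chain,resseq,resname,sasa_A2,shell`.
#'
#' @param shells Classified table from [classify_shells()].
#' @param path Output file.
#' @return `shells`, invisibly.
#' @export
write_shell_tsv <- function(shells, path) {
  check_columns(shells, c("chain_id", "residue_seq", "residue_name", "sasa",
                          "shell"), "shells")
  out <- tibble(chain = shells$chain_id, resseq = shells$residue_seq,
                resname = shells$residue_name, sasa_A2 = shells$sasa,
                shell = shells$shell)
  readr::write_tsv(out, path)
  invisible(shells)
}
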