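# Seeded synthetic-data generators. These stand in for the study's wet-lab
# and simulation inputs: saturation datasets with assay-like multiplicative
# noise, toy atom clusters with known burial, stochastic trajectories with
# known fluctuation amplitude, and noisy coupled-assay progress curves.
# Every generator is a pure function of (parameters, seed): the RNG state is
# scoped locally with withr, never leaked.

#' Generate a Michaelis-Menten saturation dataset
#'
#' Velocities `v = Vmax s / (KM + s) (1 + e)`, `e ~ Normal(0, cv)` —
#' multiplicative noise of constant coefficient of variation, the usual
#' error structure of plate-reader initial velocities. `cv = 0` gives exact
#' model values.
#'
#' @param Vmax,KM Generating parameters (velocity unit free; `KM` in mM).
#' @param s_values Substrate concentrations in mM.
#' @param cv Coefficient of variation of the noise (default 0).
#' @param replicates Number of replicates over the same concentration grid.
#' @param seed RNG seed.
#' @param condition,substrate Labels carried into the output.
#' @return A kinetics tibble `condition`, `substrate`, `s_mM`, `v`,
#'   `replicate`, with the seed recorded in the `seed` attribute.
#' @examples
#' gen_mm_dataset(49.1, 2.34, c(0.5, 1, 2, 4, 8, 16, 30), cv = 0.05, seed = 1)
#' @export
gen_mm_dataset <- function(Vmax, KM, s_values, cv = 0, replicates = 1,
                           seed = 1, condition = "synthetic",
                           substrate = "G6P") {
  check_number(Vmax, "Vmax", positive = TRUE)
  check_number(KM, "KM", positive = TRUE)
  check_number(cv, "cv", non_negative = TRUE)
  if (length(s_values) == 0 || any(s_values < 0)) {
    abort("`s_values` must be non-empty and >= 0.",
          class = "halokin_invalid_parameter")
  }
  grid <- tidyr::expand_grid(replicate = seq_len(replicates),
                             s_mM = as.numeric(s_values))
  model <- mm_model(grid$s_mM, Vmax, KM)
  noise <- withr::with_seed(seed, rnorm(nrow(grid), mean = 0, sd = cv))
  out <- tibble(condition = condition, substrate = substrate,
                s_mM = grid$s_mM, v = model * (1 + noise),
                replicate = grid$replicate)
  attr(out, "seed") <- seed
  out
}

# unit icosahedron vertices
icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)
}

#' Generate a toy structure with known burial
#'
#' Three kinds: `"isolated"` (one atom, fully exposed), `"pair"` (two atoms
#' at distance `d`), and `"caged"` (a central atom surrounded by an
#' icosahedral shell of 12 atoms at radius `d_shell`, burying the centre
#' when the shell is tight).
#'
#' @param kind `"isolated"`, `"pair"` or `"caged"`.
#' @param d Pair distance in Angstrom (kind `"pair"`).
#' @param d_shell Shell radius in Angstrom (kind `"caged"`).
#' @param element Element symbol for all atoms (default carbon).
#' @return An atoms tibble in the [parse_pdb()] schema; each atom is its own
#'   residue so burial labels are per-atom.
#' @examples
#' gen_toy_structure("caged", d_shell = 3)
#' @export
gen_toy_structure <- function(kind = c("isolated", "pair", "caged"),
                              d = 100, d_shell = 3, element = "C") {
  kind <- match.arg(kind)
  coords <- switch(kind,
    isolated = matrix(0, 1, 3),
    pair = rbind(c(0, 0, 0), c(d, 0, 0)),
    caged = rbind(c(0, 0, 0), icosahedron_vertices() * d_shell))
  n <- nrow(coords)
  el <- rep(element, length.out = n)
  tibble(serial = seq_len(n),
         atom_name = el,
         element = el,
         residue_name = "UNK",
         chain_id = "A",
         residue_seq = seq_len(n),
         x = coords[, 1], y = coords[, 2], z = coords[, 3],
         vdw_radius = lookup_vdw(el),
         mass = lookup_mass(el))
}

random_rotation <- function() {
  # uniform rotation via a normalised random quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate a stochastic trajectory with known fluctuation amplitude
#'
#' Frame coordinates are the reference plus isotropic per-coordinate
#' Gaussian noise of per-atom standard deviation `sigma` (so the expected
#' per-atom RMSF is `sigma * sqrt(3)`), optionally followed by a random
#' rigid rotation and translation per frame to emulate global tumbling.
#'
#' @param reference Atoms tibble providing topology and mean coordinates.
#' @param sigma Per-atom coordinate SD in Angstrom; scalar or one value per
#'   atom.
#' @param n_frames Number of frames (>= 2).
#' @param rigid_motion Apply a random rigid motion per frame? Default
#'   `FALSE`.
#' @param seed RNG seed.
#' @return A [trajectory()].
#' @examples
#' ref <- gen_toy_structure("caged", d_shell = 6)
#' gen_trajectory(ref, sigma = 0.5, n_frames = 10, seed = 7)
#' @export
gen_trajectory <- function(reference, sigma, n_frames, rigid_motion = FALSE,
                           seed = 1) {
  check_columns(reference, c("x", "y", "z"), "reference")
  n_atoms <- nrow(reference)
  if (length(sigma) == 1) sigma <- rep(sigma, n_atoms)
  if (length(sigma) != n_atoms || any(sigma < 0)) {
    abort("`sigma` must be a non-negative scalar or one value per atom.",
          class = "halokin_invalid_parameter")
  }
  if (n_frames < 2) {
    abort("`n_frames` must be >= 2.", class = "halokin_invalid_parameter")
  }
  ref <- as.matrix(reference[, c("x", "y", "z")])
  frames <- withr::with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      f <- ref + matrix(rnorm(n_atoms * 3), ncol = 3) * sigma
      if (rigid_motion) {
        rot <- random_rotation()
        shift <- rnorm(3, sd = 5)
        f <- f %*% t(rot) + matrix(shift, n_atoms, 3, byrow = TRUE)
      }
      f
    })
  })
  trajectory(reference, frames)
}

#' Generate a noisy coupled-assay progress curve
#'
#' The deterministic [simulate_coupled_assay()] curve with additive Gaussian
#' noise of SD `noise_sd` on the observed auxiliary velocity, emulating
#' detector noise on a coupled-assay trace.
#'
#' @param spec An [assay_spec()] with `V2` set.
#' @param noise_sd Additive noise SD on `v2`, mM/min.
#' @param seed RNG seed.
#' @param t_end,dt Passed to [simulate_coupled_assay()].
#' @return The progress tibble with `v2_mM_min` replaced by its noisy
#'   version and the clean curve kept as `v2_true`.
#' @export
gen_progress_curve <- function(spec, noise_sd = 0, seed = 1, t_end = 30,
                               dt = NULL) {
  check_number(noise_sd, "noise_sd", non_negative = TRUE)
  curve <- simulate_coupled_assay(spec, t_end = t_end, dt = dt)
  noise <- withr::with_seed(seed, rnorm(nrow(curve), sd = noise_sd))
  out <- dplyr::mutate(curve, v2_true = .data$v2_mM_min,
                       v2_mM_min = .data$v2_mM_min + noise)
  attr(out, "seed") <- seed
  out
}
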