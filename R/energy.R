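# Selection-pair nonbonded energies: direct-sum Coulomb plus Lennard-Jones
# with Lorentz-Berthelot combination. This is selection-pair analysis (e.g.
# substrate vs binding loop), not a total-system energy: no periodic imaging
# or Ewald summation is applied, so input trajectories must already be imaged.

#' Coulomb constant in kcal A mol^-1 e^-2
#' @export
COULOMB_KCAL <- 332.0636

#' Read a per-atom nonbonded parameter table
#'
#' TSV with columns `chain,resseq,atom_name,charge_e,eps_kcal,sigma_A`,
#' matched to topology atoms by (chain, residue number, atom name).
#'
#' @param path TSV file.
#' @return A tibble with those columns.
#' @export
read_nb_params <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("chain", "resseq", "atom_name", "charge_e", "eps_kcal",
                      "sigma_A"), "params tsv")
  as_tibble(df)
}

#' Convert Lennard-Jones (A, B) coefficients to (epsilon, sigma)
#'
#' For the 12-6 potential written `A/r^12 - B/r^6`:
#' `sigma = (A/B)^(1/6)`, `epsilon = B^2 / (4 A)`.
#'
#' @param A,B Coefficients (vectorised), `A` in kcal A^12/mol, `B` in
#'   kcal A^6/mol.
#' @return A tibble `eps_kcal`, `sigma_A`.
#' @export
lj_ab_to_eps_sigma <- function(A, B) {
  if (any(A <= 0) || any(B <= 0)) {
    abort("A and B must be > 0.", class = "halokin_invalid_parameter")
  }
  tibble(eps_kcal = B^2 / (4 * A), sigma_A = (A / B)^(1 / 6))
}

match_params <- function(topology, idx, params) {
  key_top <- paste(topology$chain_id[idx], topology$residue_seq[idx],
                   topology$atom_name[idx])
  key_par <- paste(params$chain, params$resseq, params$atom_name)
  pos <- match(key_top, key_par)
  if (any(is.na(pos))) {
    missing <- key_top[is.na(pos)]
    abort(paste0("Missing nonbonded parameters for atom(s): ",
                 paste(utils::head(missing, 5), collapse = "; "),
                 if (length(missing) > 5) " ..." else ""),
          class = "halokin_missing_parameters")
  }
  params[pos, ]
}

#' Selection-pair electrostatic and van der Waals interaction energy
#'
#' Direct pairwise sums between two disjoint atom selections:
#' electrostatic `sum k q_i q_j / r_ij` with `k = 332.0636` kcal A/(mol e^2),
#' and Lennard-Jones `sum 4 eps_ij ((sigma_ij/r_ij)^12 - (sigma_ij/r_ij)^6)`
#' with Lorentz-Berthelot combination (arithmetic-mean sigma, geometric-mean
#' epsilon). No cutoff is applied unless requested.
#'
#' @param traj A [trajectory()] (all frames evaluated) or a bare `n x 3`
#'   coordinate matrix for its topology (single frame).
#' @param sel_a,sel_b Disjoint selections ([atom_selection()] or indices).
#' @param params Parameter tibble from [read_nb_params()] (or with the same
#'   columns), covering every selected atom.
#' @param cutoff Optional distance cutoff in Angstrom; pairs beyond it
#'   contribute nothing.
#' @param topology Required when `traj` is a bare matrix.
#' @return A tibble `frame`, `electrostatic_kcal`, `vdw_kcal`.
#' @export
interaction_energy <- function(traj, sel_a, sel_b, params, cutoff = NULL,
                               topology = NULL) {
  if (is.matrix(traj)) {
    if (is.null(topology)) {
      abort("Supply `topology` with a bare coordinate matrix.",
            class = "halokin_invalid_parameter")
    }
    frames <- list(traj)
  } else {
    stopifnot(inherits(traj, "trajectory"))
    topology <- traj$topology
    frames <- traj$frames
  }
  ia <- select_atoms(topology, sel_a)
  ib <- select_atoms(topology, sel_b)
  if (length(intersect(ia, ib)) > 0) {
    abort("Selections overlap; interaction energy needs disjoint groups.",
          class = "halokin_invalid_parameter")
  }
  pa <- match_params(topology, ia, params)
  pb <- match_params(topology, ib, params)
  if (any(pa$eps_kcal < 0) || any(pb$eps_kcal < 0) ||
      any(pa$sigma_A <= 0) || any(pb$sigma_A <= 0)) {
    abort("epsilon must be >= 0 and sigma > 0.",
          class = "halokin_invalid_parameter")
  }
  qq <- outer(pa$charge_e, pb$charge_e)
  sig <- outer(pa$sigma_A, pb$sigma_A, function(x, y) (x + y) / 2)
  eps <- sqrt(outer(pa$eps_kcal, pb$eps_kcal))
  res <- purrr::map_dfr(seq_along(frames), function(k) {
    ca <- frames[[k]][ia, , drop = FALSE]
    cb <- frames[[k]][ib, , drop = FALSE]
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
    r <- sqrt(pmax(d2, 0))
    if (any(r < 0.1)) {
      abort(sprintf(
        "Atomic clash in frame %d: minimum pair distance %.3g A < 0.1 A.",
        k, min(r)), class = "halokin_clash")
    }
    keep <- if (is.null(cutoff)) 1 else (r <= cutoff) * 1
    sr6 <- (sig / r)^6
    tibble(frame = k,
           electrostatic_kcal = sum(COULOMB_KCAL * qq / r * keep),
           vdw_kcal = sum(4 * eps * (sr6^2 - sr6) * keep))
  })
  res
}
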