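# Independent oracles and fixture builders shared across tests. Each oracle
# is written against the definition, not the package code path it checks.

# Brute-force 2-D grid search for Michaelis-Menten least squares.
grid_search_mm <- function(s, v, km_grid, vmax_grid) {
  best <- c(sse = Inf, Vmax = NA, KM = NA)
  for (km in km_grid) {
    m <- s / (km + s)
    # SSE for every Vmax on this KM slice
    sse <- colSums((outer(v, rep(1, length(vmax_grid))) -
                      outer(m, vmax_grid))^2)
    j <- which.min(sse)
    if (sse[j] < best["sse"]) best <- c(sse = sse[j], Vmax = vmax_grid[j], KM = km)
  }
  best
}

# Exhaustive Euler-angle rotation search for minimal RMSD (coarse grid with
# local refinement well past 0.1 degrees). Centroids matched analytically.
euler_rotation <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}

euler_grid_rmsd <- function(mobile, reference) {
  m <- sweep(mobile, 2, colMeans(mobile))
  r <- sweep(reference, 2, colMeans(reference))
  n <- nrow(m)
  eval_rmsd <- function(a, b, g) {
    sqrt(sum((m %*% t(euler_rotation(a, b, g)) - r)^2) / n)
  }
  best <- c(Inf, 0, 0, 0)
  step <- 10 * pi / 180
  for (a in seq(0, 2 * pi - step, by = step))
    for (b in seq(0, pi, by = step))
      for (g in seq(0, 2 * pi - step, by = step)) {
        v <- eval_rmsd(a, b, g)
        if (v < best[1]) best <- c(v, a, b, g)
      }
  # local refinement: shrink the step far below 0.1 degrees
  while (step > 1e-5) {
    step <- step / 5
    centre <- best[2:4]
    for (a in centre[1] + step * (-5:5))
      for (b in centre[2] + step * (-5:5))
        for (g in centre[3] + step * (-5:5)) {
          v <- eval_rmsd(a, b, g)
          if (v < best[1]) best <- c(v, a, b, g)
        }
  }
  best[1]
}

# Independent all-pairs nonbonded sum, scalar double loop.
brute_force_energy <- function(coords_a, coords_b, qa, qb, epsa, epsb,
                               siga, sigb, k = 332.0636) {
  elec <- 0
  vdw <- 0
  for (i in seq_len(nrow(coords_a))) {
    for (j in seq_len(nrow(coords_b))) {
      rij <- sqrt(sum((coords_a[i, ] - coords_b[j, ])^2))
      elec <- elec + k * qa[i] * qb[j] / rij
      sij <- (siga[i] + sigb[j]) / 2
      eij <- sqrt(epsa[i] * epsb[j])
      vdw <- vdw + 4 * eij * ((sij / rij)^12 - (sij / rij)^6)
    }
  }
  c(electrostatic = elec, vdw = vdw)
}

# Protein-like synthetic fixture: a jittered chain of 5-atom residues cycling
# through a fixed residue alphabet, some residues pushed into a compact core.
make_fake_protein <- function(n_res = 40, seed = 42, chain = "A") {
  res_names <- rep(c("LEU", "ALA", "ASP", "GLU", "TRP", "VAL", "GLY", "LYS",
                     "SER", "PHE"), length.out = n_res)
  atom_names <- c("N", "CA", "C", "O", "CB")
  elements <- c("N", "C", "C", "O", "C")
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_res), function(i) {
      # half the residues on a compact ball, half on an extended arc
      centre <- if (i %% 2 == 0) {
        u <- rnorm(3)
        u / sqrt(sum(u^2)) * runif(1, 0, 4)
      } else {
        ang <- i / n_res * 2 * pi
        c(12 * cos(ang), 12 * sin(ang), i * 0.8)
      }
      tibble::tibble(
        serial = (i - 1) * 5 + 1:5,
        atom_name = atom_names,
        element = elements,
        residue_name = res_names[i],
        chain_id = chain,
        residue_seq = i,
        x = centre[1] + rnorm(5, sd = 0.8),
        y = centre[2] + rnorm(5, sd = 0.8),
        z = centre[3] + rnorm(5, sd = 0.8))
    })
    atoms <- dplyr::bind_rows(rows)
    atoms$vdw_radius <- c(N = 1.55, C = 1.70, O = 1.52)[atoms$element]
    atoms$mass <- c(N = 14.007, C = 12.011, O = 15.999)[atoms$element]
    atoms
  })
}

rotate_atoms <- function(atoms, axis_angle = c(0.3, 0.8, 0.5),
                         shift = c(5, -3, 2)) {
  th <- sqrt(sum(axis_angle^2))
  u <- axis_angle / th
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

rotation_matrix <- function(axis_angle) {
  th <- sqrt(sum(axis_angle^2))
  u <- axis_angle / th
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# simple parameter table covering an atoms tibble
uniform_params <- function(atoms, charge = 0, eps = 0.1, sigma = 3) {
  tibble::tibble(chain = atoms$chain_id, resseq = atoms$residue_seq,
                 atom_name = atoms$atom_name,
                 charge_e = rep_len(charge, nrow(atoms)),
                 eps_kcal = rep_len(eps, nrow(atoms)),
                 sigma_A = rep_len(sigma, nrow(atoms)))
}
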