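# Selection-pair Coulomb / Lennard-Jones energies.

two_atom_system <- function(d, q = c(1, 1), eps = c(0.1, 0.1),
                            sigma = c(3, 3)) {
  topo <- gen_toy_structure("pair", d = d)
  params <- uniform_params(topo)
  params$charge_e <- q
  params$eps_kcal <- eps
  params$sigma_A <- sigma
  list(topo = topo, coords = as.matrix(topo[, c("x", "y", "z")]),
       params = params)
}

test_that("unit charges at 3.320636 A give +100 kcal/mol", {
  sys <- two_atom_system(3.320636)
  e <- interaction_energy(sys$coords, 1, 2, sys$params, topology = sys$topo)
  expect_equal(e$electrostatic_kcal, 100, tolerance = 1e-8)
})

test_that("the LJ minimum distance gives -epsilon", {
  eps <- 0.25
  sigma <- 3.2
  sys <- two_atom_system(2^(1 / 6) * sigma, q = c(0, 0),
                         eps = c(eps, eps), sigma = c(sigma, sigma))
  e <- interaction_energy(sys$coords, 1, 2, sys$params, topology = sys$topo)
  expect_equal(e$vdw_kcal, -eps, tolerance = 1e-10)
  expect_equal(e$electrostatic_kcal, 0)
})

test_that("both components equal an independent brute-force pair sum", {
  atoms <- make_fake_protein(n_res = 2, seed = 13)  # 10 atoms, 3 vs 2 below
  params <- uniform_params(atoms)
  params$charge_e <- withr::with_seed(1, runif(10, -0.8, 0.8))
  params$eps_kcal <- withr::with_seed(2, runif(10, 0.05, 0.3))
  params$sigma_A <- withr::with_seed(3, runif(10, 2.5, 3.5))
  ia <- 1:3
  ib <- 6:7
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  ours <- interaction_energy(coords, ia, ib, params, topology = atoms)
  oracle <- brute_force_energy(coords[ia, , drop = FALSE],
                               coords[ib, , drop = FALSE],
                               params$charge_e[ia], params$charge_e[ib],
                               params$eps_kcal[ia], params$eps_kcal[ib],
                               params$sigma_A[ia], params$sigma_A[ib])
  expect_equal(ours$electrostatic_kcal, oracle[["electrostatic"]],
               tolerance = 1e-10)
  expect_equal(ours$vdw_kcal, oracle[["vdw"]], tolerance = 1e-10)
  # symmetry under swapping the selections
  swapped <- interaction_energy(coords, ib, ia, params, topology = atoms)
  expect_equal(swapped$electrostatic_kcal, ours$electrostatic_kcal)
  expect_equal(swapped$vdw_kcal, ours$vdw_kcal)
})

test_that("electrostatics is linear in a charge; vdw ignores charges", {
  sys <- two_atom_system(4, q = c(0.5, -0.7))
  e1 <- interaction_energy(sys$coords, 1, 2, sys$params, topology = sys$topo)
  p2 <- sys$params
  p2$charge_e[1] <- 2 * p2$charge_e[1]
  e2 <- interaction_energy(sys$coords, 1, 2, p2, topology = sys$topo)
  expect_equal(e2$electrostatic_kcal, 2 * e1$electrostatic_kcal)
  expect_equal(e2$vdw_kcal, e1$vdw_kcal)
})

test_that("energies are invariant under global rigid motion", {
  atoms <- make_fake_protein(n_res = 4, seed = 17)
  params <- uniform_params(atoms, charge = 0.2)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  moved <- rotate_atoms(atoms)
  coords2 <- as.matrix(moved[, c("x", "y", "z")])
  e1 <- interaction_energy(coords, 1:5, 11:20, params, topology = atoms)
  e2 <- interaction_energy(coords2, 1:5, 11:20, params, topology = atoms)
  expect_equal(e1$electrostatic_kcal, e2$electrostatic_kcal,
               tolerance = 1e-9)
  expect_equal(e1$vdw_kcal, e2$vdw_kcal, tolerance = 1e-9)
})

test_that("a charged ligand is repelled by a like-charged loop and attracted by an opposite one", {
  # phosphate-like ligand (net negative) 5 A from a 3-atom loop
  lig <- gen_toy_structure("pair", d = 1.5)
  loop <- gen_toy_structure("caged", d_shell = 2)[2:4, ]
  loop$x <- loop$x + 6
  loop$serial <- loop$residue_seq <- 3:5
  topo <- dplyr::bind_rows(lig, loop)
  coords <- as.matrix(topo[, c("x", "y", "z")])
  params <- uniform_params(topo)
  params$charge_e <- c(-1, -0.5, rep(-0.4, 3))   # acidic loop
  acidic <- interaction_energy(coords, 1:2, 3:5, params, topology = topo)
  expect_gt(acidic$electrostatic_kcal, 0)
  params$charge_e <- c(-1, -0.5, rep(+0.4, 3))   # basic loop
  basic <- interaction_energy(coords, 1:2, 3:5, params, topology = topo)
  expect_lt(basic$electrostatic_kcal, 0)
})

test_that("selection, parameter and clash errors are raised", {
  sys <- two_atom_system(3)
  expect_error(interaction_energy(sys$coords, 1:2, 2, sys$params,
                                  topology = sys$topo),
               class = "halokin_invalid_parameter")
  p_missing <- sys$params[1, ]
  expect_error(interaction_energy(sys$coords, 1, 2, p_missing,
                                  topology = sys$topo),
               class = "halokin_missing_parameters")
  clash <- two_atom_system(0.05)
  expect_error(interaction_energy(clash$coords, 1, 2, clash$params,
                                  topology = clash$topo),
               class = "halokin_clash")
})

test_that("a cutoff silences distant pairs", {
  sys <- two_atom_system(8, q = c(1, 1))
  full <- interaction_energy(sys$coords, 1, 2, sys$params, topology = sys$topo)
  cut <- interaction_energy(sys$coords, 1, 2, sys$params, cutoff = 5,
                            topology = sys$topo)
  expect_gt(full$electrostatic_kcal, 0)
  expect_equal(cut$electrostatic_kcal, 0)
})

test_that("(A,B) Lennard-Jones coefficients convert to (eps, sigma)", {
  eps <- 0.21; sigma <- 3.4
  A <- 4 * eps * sigma^12
  B <- 4 * eps * sigma^6
  out <- lj_ab_to_eps_sigma(A, B)
  expect_equal(out$eps_kcal, eps)
  expect_equal(out$sigma_A, sigma)
  expect_error(lj_ab_to_eps_sigma(-1, 1), class = "halokin_invalid_parameter")
})

test_that("nonbonded parameter TSVs read back with the documented columns", {
  atoms <- make_fake_protein(n_res = 2, seed = 1)
  params <- uniform_params(atoms, charge = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(params, path)
  back <- read_nb_params(path)
  expect_equal(back$charge_e, params$charge_e)
  expect_equal(names(back),
               c("chain", "resseq", "atom_name", "charge_e", "eps_kcal",
                 "sigma_A"))
})
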