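# Shrake-Rupley SASA against analytic sphere geometry, shell classification
# at the 20 A^2 criterion, and composition statistics.

test_that("isolated and well-separated atoms get the full sphere area", {
  sphere <- 4 * pi * (1.70 + 1.4)^2
  iso <- shrake_rupley_sasa(gen_toy_structure("isolated"))
  expect_equal(iso$sasa, sphere, tolerance = 5e-3)
  far <- shrake_rupley_sasa(gen_toy_structure("pair", d = 100))
  expect_equal(far$sasa, rep(sphere, 2), tolerance = 5e-3)
})

test_that("two-sphere burial matches the analytic spherical cap", {
  # expanded radius R = 3.10, centres 3.10 apart: cap height h = R/2,
  # remaining area 4 pi R^2 - 2 pi R h = 90.57
  pair <- shrake_rupley_sasa(gen_toy_structure("pair", d = 3.10))
  R <- 3.10
  expected <- 4 * pi * R^2 - 2 * pi * R * (R / 2)
  expect_equal(pair$sasa, rep(expected, 2), tolerance = 0.02)
})

test_that("a caged atom is fully buried", {
  caged <- shrake_rupley_sasa(gen_toy_structure("caged", d_shell = 3))
  expect_lt(caged$sasa[1], 1)
  res <- classify_shells(residue_sasa(caged))
  expect_equal(res$shell[res$residue_seq == 1], "core")
})

test_that("SASA never exceeds the isolated-sphere bound and is non-negative", {
  atoms <- make_fake_protein(n_res = 20, seed = 7)
  out <- shrake_rupley_sasa(atoms)
  expect_true(all(out$sasa >= 0))
  expect_true(all(out$sasa <= 4 * pi * (out$vdw_radius + 1.4)^2 + 1e-9))
})

test_that("adding an occluding atom never increases another atom's SASA", {
  atoms <- make_fake_protein(n_res = 8, seed = 3)
  before <- shrake_rupley_sasa(atoms)$sasa
  # new atom placed farther than any existing nearest-neighbour pair so the
  # covariant point sets of existing atoms are unchanged
  extra <- atoms[1, ]
  extra$serial <- max(atoms$serial) + 1L
  extra$residue_seq <- max(atoms$residue_seq) + 1L
  extra$x <- max(atoms$x) + 4.0
  after <- shrake_rupley_sasa(dplyr::bind_rows(atoms, extra))$sasa
  expect_true(all(after[seq_along(before)] <= before + 1e-9))
})

test_that("SASA is exactly invariant under global rigid motion", {
  atoms <- make_fake_protein(n_res = 15, seed = 21)
  s1 <- shrake_rupley_sasa(atoms)$sasa
  s2 <- shrake_rupley_sasa(rotate_atoms(atoms))$sasa
  expect_lt(max(abs(s1 - s2) / pmax(s1, 1e-9)), 1e-9)
})

test_that("shell labels are converged in the point count", {
  atoms <- make_fake_protein(n_res = 40, seed = 42)
  lab1 <- classify_shells(residue_sasa(shrake_rupley_sasa(atoms, n_points = 960)))
  lab2 <- classify_shells(residue_sasa(shrake_rupley_sasa(atoms, n_points = 1920)))
  expect_lt(mean(lab1$shell != lab2$shell), 0.01)
})

test_that("n_points below 16 is refused", {
  expect_error(shrake_rupley_sasa(gen_toy_structure("isolated"), n_points = 8),
               class = "halokin_invalid_parameter")
})

test_that("the 20 A^2 exposure boundary is inclusive", {
  tbl <- tibble::tibble(chain_id = "A", residue_seq = 1:3,
                        residue_name = c("LEU", "ALA", "TRP"),
                        sasa = c(20.0, 19.99, 0))
  out <- classify_shells(tbl)
  expect_equal(out$shell, c("exposed", "core", "core"))
  empty <- classify_shells(tbl[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("side-chain-only aggregation drops backbone atoms", {
  atoms <- make_fake_protein(n_res = 4, seed = 5)
  pa <- shrake_rupley_sasa(atoms)
  full <- residue_sasa(pa)
  side <- residue_sasa(pa, sidechain_only = TRUE)
  expect_true(all(side$sasa <= full$sasa + 1e-9))
})

test_that("shell composition reports counts, volumes, acidity and exposure", {
  tbl <- tibble::tibble(
    chain_id = "A", residue_seq = 1:10,
    residue_name = c("LEU", "LEU", "ALA", "VAL", "ASP", "GLU", "TRP", "TRP",
                     "GLY", "LYS"),
    sasa = c(0, 5, 1, 2, 50, 60, 30, 40, 3, 70))
  comp <- shell_composition(classify_shells(tbl))
  expect_equal(comp$overall$core_fraction_count, 50)
  # core residues L,L,A,V,G are all in the hydrophobic set
  expect_equal(comp$overall$hydrophobic_core_fraction_count, 50)
  core_types <- dplyr::filter(comp$by_type, shell == "core")
  expect_equal(core_types$pct[core_types$residue_name == "LEU"], 40)
  vols <- residue_volumes()
  core_vol <- sum(vols[c("LEU", "LEU", "ALA", "VAL", "GLY")])
  expect_equal(comp$overall$core_fraction_volume,
               100 * core_vol / sum(vols[tbl$residue_name]))
  acidic_exposed <- dplyr::filter(comp$acidic, shell == "exposed")
  expect_equal(acidic_exposed$acidic_pct, 40)
  trp <- dplyr::filter(comp$exposure, residue_name == "TRP")
  expect_equal(trp$exposure, "2/2")
})

test_that("composition comparison pairs types and honours the shell scheme", {
  tbl_a <- tibble::tibble(chain_id = "A", residue_seq = 1:4,
                          residue_name = c("LEU", "ALA", "ASP", "TRP"),
                          sasa = c(0, 0, 50, 50))
  tbl_b <- tibble::tibble(chain_id = "A", residue_seq = 1:4,
                          residue_name = c("LEU", "LEU", "ASP", "TRP"),
                          sasa = c(0, 0, 50, 50))
  ca <- shell_composition(classify_shells(tbl_a))
  cb <- shell_composition(classify_shells(tbl_b))
  cmp <- compare_compositions(ca, cb)
  leu_core <- dplyr::filter(cmp, shell == "core", residue_name == "LEU")
  expect_equal(leu_core$diff, 50 - 100)
  same <- compare_compositions(ca, ca)
  expect_true(all(same$diff == 0))
  # mismatched schemes: one report with a single shell level
  all_exposed <- shell_composition(classify_shells(
    dplyr::mutate(tbl_a, sasa = 100)))
  expect_error(compare_compositions(ca, all_exposed),
               class = "halokin_invalid_parameter")
})

test_that("shell tables write the documented TSV dialect", {
  atoms <- make_fake_protein(n_res = 5, seed = 1)
  shells <- classify_shells(residue_sasa(shrake_rupley_sasa(atoms)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_shell_tsv(shells, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("chain", "resseq", "resname", "sasa_A2", "shell"))
  expect_equal(nrow(back), 5)
})
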