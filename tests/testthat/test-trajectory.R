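# Kabsch superposition and the observables built on it.

test_that("superposing a set onto itself gives identity and zero RMSD", {
  a <- matrix(withr::with_seed(1, rnorm(12)), 4, 3)
  fit <- kabsch_superpose(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
})

test_that("a pure rigid motion is recovered exactly", {
  a <- matrix(withr::with_seed(2, rnorm(15)), 5, 3)
  R <- rotation_matrix(c(0, 0, pi / 2))
  b <- a %*% t(R) + matrix(c(5, 0, 0), 5, 3, byrow = TRUE)
  fit <- kabsch_superpose(b, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  # the recovered transform is the inverse rigid motion
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-10)
  expect_equal(fit$transformed, a, tolerance = 1e-10)
})

test_that("Kabsch equals the exhaustive Euler-grid oracle on a 4-point toy", {
  a <- matrix(c(0, 0, 0, 1.2, 0, 0, 0, 1.5, 0, 0.3, 0.4, 1.1), 4, 3,
              byrow = TRUE)
  b <- a + matrix(withr::with_seed(7, rnorm(12, sd = 0.15)), 4, 3)
  ours <- kabsch_superpose(b, a)$rmsd
  oracle <- euler_grid_rmsd(b, a)
  expect_lt(abs(ours - oracle), 1e-6)
  expect_lte(ours, oracle + 1e-12)
})

test_that("Kabsch RMSD matches bio3d's least-squares fit", {
  a <- matrix(withr::with_seed(3, rnorm(30)), 10, 3)
  b <- a + matrix(withr::with_seed(4, rnorm(30, sd = 0.3)), 10, 3)
  ours <- kabsch_superpose(b, a)$rmsd
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(a)), mobile = as.vector(t(b))))
  ref <- sqrt(mean(colSums(matrix(fitted - as.vector(t(a)), nrow = 3)^2)))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("degenerate and mismatched geometries are refused", {
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), class = "halokin_degenerate")
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               class = "halokin_invalid_parameter")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "halokin_invalid_parameter")
})

test_that("RMSD series is zero for static and rigid-body trajectories", {
  ref <- gen_toy_structure("caged", d_shell = 6)
  static <- gen_trajectory(ref, sigma = 0, n_frames = 5, seed = 1)
  expect_equal(rmsd_series(static)$rmsd, rep(0, 5), tolerance = 1e-10)
  rigid <- gen_trajectory(ref, sigma = 0, n_frames = 5, rigid_motion = TRUE,
                          seed = 2)
  expect_equal(rmsd_series(rigid)$rmsd, rep(0, 5), tolerance = 1e-9)
})

test_that("superposition never increases the RMSD of a frame", {
  ref <- gen_toy_structure("caged", d_shell = 6)
  traj <- gen_trajectory(ref, sigma = 0.4, n_frames = 20, rigid_motion = TRUE,
                         seed = 11)
  fitted <- rmsd_series(traj)$rmsd
  raw <- vapply(traj$frames, function(f) {
    sqrt(mean(rowSums((f - traj$frames[[1]])^2)))
  }, numeric(1))
  expect_true(all(fitted <= raw + 1e-9))
})

test_that("single-atom displacement gives the direct-formula RMSD", {
  coords <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0), 3, 3, byrow = TRUE)
  topo <- gen_toy_structure("caged")[1:3, ]
  topo[, c("x", "y", "z")] <- coords
  d <- 0.6
  f2 <- coords
  f2[1, 3] <- f2[1, 3] + d
  traj <- trajectory(topo, list(coords, f2))
  unaligned <- sqrt(d^2 / 3)
  expect_equal(sqrt(mean(rowSums((f2 - coords)^2))), unaligned)
  fitted <- rmsd_series(traj)$rmsd[2]
  expect_equal(fitted, kabsch_superpose(f2, coords)$rmsd, tolerance = 1e-12)
  expect_lte(fitted, unaligned)
})

test_that("RMSF recovers the generating fluctuation amplitude", {
  ref <- make_fake_protein(n_res = 12, seed = 6)  # 60 atoms
  traj <- gen_trajectory(ref, sigma = 0.5, n_frames = 2000, seed = 7)
  out <- rmsf(traj, align = FALSE)
  expect_equal(mean(out$rmsf), 0.5 * sqrt(3), tolerance = 0.03)
  aligned <- rmsf(traj, align = TRUE)
  expect_equal(mean(aligned$rmsf), 0.5 * sqrt(3), tolerance = 0.03)
  static <- gen_trajectory(ref, sigma = 0, n_frames = 3, seed = 1)
  expect_equal(rmsf(static)$rmsf, rep(0, 12), tolerance = 1e-10)
  expect_error(rmsf(trajectory(ref, list(as.matrix(ref[, c("x", "y", "z")])))),
               class = "halokin_invalid_parameter")
})

test_that("two alternating positions give RMSF equal to the half-spread", {
  topo <- gen_toy_structure("caged")[1:3, ]
  base <- as.matrix(topo[, c("x", "y", "z")])
  d <- 0.8
  up <- base; up[, 1] <- up[, 1] + d
  dn <- base; dn[, 1] <- dn[, 1] - d
  traj <- trajectory(topo, list(up, dn))
  out <- rmsf(traj, align = FALSE, per = "atom")
  expect_equal(out$rmsf, rep(d, 3))
})

test_that("radius of gyration matches closed forms", {
  # single atom
  one <- matrix(0, 1, 3)
  expect_equal(radius_of_gyration(one, masses = 12), 0)
  # two equal masses d apart -> d/2
  two <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two, masses = c(1, 1)), 2)
  # 8 unit masses at cube corners, edge 2 -> sqrt(3)
  cube <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  expect_equal(radius_of_gyration(cube, masses = rep(1, 8)), sqrt(3))
  # rigid-motion invariance on a trajectory
  ref <- gen_toy_structure("caged", d_shell = 6)
  rigid <- gen_trajectory(ref, sigma = 0, n_frames = 4, rigid_motion = TRUE,
                          seed = 9)
  rgs <- radius_of_gyration(rigid)$rg
  expect_lt(max(abs(rgs - rgs[1]) / rgs[1]), 1e-9)
})

test_that("replicate statistics pool series point by point", {
  s <- list(a = c(1, 2, 3, 4), b = c(3, 2, 3, 4), c = c(2, 2, 3, 4))
  st <- replicate_stats(s)
  expect_equal(st$pointwise$mean[1], 2)
  expect_equal(st$pointwise$sd[1], 1)
  expect_equal(st$pointwise$sd[2], 0)
  # identical series: SD zero everywhere
  same <- replicate_stats(list(1:5, 1:5, 1:5))
  expect_true(all(same$pointwise$sd == 0))
  # a window covering everything reproduces the global mean
  all_win <- replicate_stats(s, window = seq_len(4))
  expect_equal(all_win$window$mean, mean(unlist(s)))
  # trailing-fraction window convention
  tail_win <- replicate_stats(s, window = 0.5)
  expect_equal(tail_win$window$from, 3)
  expect_equal(tail_win$window$mean, mean(c(3, 4)))
  expect_error(replicate_stats(list(1:3, 1:4)),
               class = "halokin_invalid_parameter")
  expect_error(replicate_stats(s, window = 9),
               class = "halokin_invalid_parameter")
})
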