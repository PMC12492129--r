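test_that("kabsch superposition is exact on rigid motions", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  same <- kabsch_superpose(ref, ref)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$coords, ref, tolerance = 1e-12)

  motion <- random_rigid_motion(2)
  moved <- apply_rigid(ref, motion)
  fit <- kabsch_superpose(moved, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$coords, ref, tolerance = 1e-9)
})

test_that("kabsch finds the global rotational optimum (brute-force oracle)", {
  euler_rmsd <- function(ang, A, B) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    A0 <- sweep(A, 2, colMeans(A))
    B0 <- sweep(B, 2, colMeans(B))
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  for (seed in 1:3) {
    set.seed(seed)
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    # coarse grid then local refinement, independent of the SVD route
    grid <- expand.grid(a = seq(0, 2 * pi, length.out = 7)[-7],
                        b = seq(0, pi, length.out = 5),
                        c = seq(0, 2 * pi, length.out = 7)[-7])
    vals <- apply(grid, 1, euler_rmsd, A = A, B = B)
    best <- unlist(grid[order(vals)[1:5], ])
    starts <- matrix(best, ncol = 3)
    refined <- min(apply(starts, 1, function(s) {
      optim(s, euler_rmsd, A = A, B = B, method = "Nelder-Mead",
            control = list(reltol = 1e-14, maxit = 5000))$value
    }))
    expect_equal(kabsch_superpose(A, B)$rmsd, refined, tolerance = 1e-6)
  }
})

test_that("a collinear selection is rejected as degenerate", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + 0.0, line), "degenerac")
})

test_that("RMSF is zero on a static trajectory and d/2 for a 2-frame jump", {
  topo <- make_structure(dplyr::bind_rows(
    atom_row("CA", "C", 0, "ALA", 0, 0, 0),
    atom_row("CA", "C", 1, "ALA", 3.8, 0, 0),
    atom_row("CA", "C", 2, "ALA", 7.6, 0, 0),
    atom_row("CA", "C", 3, "ALA", 7.6, 3.8, 0)
  ))
  base <- as.matrix(topo$atoms[, c("x", "y", "z")])
  static <- thermadk:::new_adk_trajectory(topo, list(base, base, base))
  expect_equal(compute_rmsf(static)$rmsf, rep(0, 4), tolerance = 1e-12)

  d <- 1.6
  f2 <- base
  f2[4, 3] <- f2[4, 3] + d
  jump <- thermadk:::new_adk_trajectory(topo, list(base, f2))
  r <- compute_rmsf(jump, superpose = FALSE)
  expect_equal(r$rmsf[4], d / 2, tolerance = 1e-12)
  expect_equal(r$rmsf[1:3], rep(0, 3), tolerance = 1e-12)
  single <- thermadk:::new_adk_trajectory(topo, list(base))
  expect_error(compute_rmsf(single), "frames")
})

test_that("RMSF of isotropic Gaussian displacement converges to sigma*sqrt(3)", {
  sigma <- 0.4
  set.seed(10)
  topo <- make_structure(dplyr::bind_rows(lapply(0:7, function(i) {
    atom_row("CA", "C", i, "ALA", 3.8 * i, 0, 0)
  })))
  base <- as.matrix(topo$atoms[, c("x", "y", "z")])
  frames <- lapply(1:10000, function(f) base + matrix(rnorm(24, 0, sigma), ncol = 3))
  traj <- thermadk:::new_adk_trajectory(topo, frames)
  r <- compute_rmsf(traj, superpose = FALSE)
  expect_equal(mean(r$rmsf), sigma * sqrt(3), tolerance = 0.02)
})

test_that("radius of gyration matches closed forms and scales linearly", {
  one <- make_structure(atom_row("CA", "C", 0, "ALA", 1, 2, 3))
  traj1 <- thermadk:::new_adk_trajectory(one, list(matrix(c(1, 2, 3), 1)))
  expect_equal(attr(compute_rgyr(traj1), "mean"), 0)

  d <- 3.0
  two <- make_structure(dplyr::bind_rows(
    atom_row("CA", "C", 0, "ALA", 0, 0, 0),
    atom_row("CA", "C", 1, "ALA", d, 0, 0)
  ))
  traj2 <- thermadk:::new_adk_trajectory(two, list(as.matrix(two$atoms[, c("x", "y", "z")])))
  expect_equal(attr(compute_rgyr(traj2), "mean"), d / 2)

  a <- 2.5
  sq_coords <- matrix(c(0, 0, 0, a, 0, 0, a, a, 0, 0, a, 0), 4, 3, byrow = TRUE)
  sq <- make_structure(dplyr::bind_rows(lapply(0:3, function(i) {
    atom_row("CA", "C", i, "ALA", sq_coords[i + 1, 1], sq_coords[i + 1, 2], sq_coords[i + 1, 3])
  })))
  traj4 <- thermadk:::new_adk_trajectory(sq, list(sq_coords))
  expect_equal(attr(compute_rgyr(traj4), "mean"), a / sqrt(2))

  c_scale <- 2.7
  traj4s <- thermadk:::new_adk_trajectory(sq, list(sq_coords * c_scale))
  expect_equal(attr(compute_rgyr(traj4s), "mean"), c_scale * a / sqrt(2))
})

test_that("SASA matches the lone-sphere closed form and burial limits", {
  lone <- make_structure(atom_row("O", "O", 0, "SER", 0, 0, 0))
  got <- compute_sasa(lone)$total
  expect_equal(got, 4 * pi * (1.52 + 1.4)^2, tolerance = 0.005)

  r_tot <- 1.70 + 1.4
  far <- make_structure(dplyr::bind_rows(
    atom_row("C1", "C", 0, "ALA", 0, 0, 0),
    atom_row("C2", "C", 1, "ALA", 2 * r_tot + 1, 0, 0)
  ))
  expect_equal(compute_sasa(far)$total, 2 * 4 * pi * r_tot^2, tolerance = 0.005)

  # hydrogen (r 1.2) centred inside a sulfur sphere (r 1.8): fully buried
  buried <- make_structure(dplyr::bind_rows(
    atom_row("S", "S", 0, "ALA", 0, 0, 0),
    atom_row("H", "H", 0, "ALA", 0.1, 0, 0)
  ))
  expect_equal(compute_sasa(buried)$per_atom[2], 0)

  expect_error(compute_sasa(make_structure(atom_row("X", "ZZ", 0, "ALA", 0, 0, 0))),
               "ZZ")
})

test_that("SASA shrinks weakly as two spheres approach", {
  vals <- sapply(seq(8, 1, by = -0.5), function(gap) {
    s <- make_structure(dplyr::bind_rows(
      atom_row("C1", "C", 0, "ALA", 0, 0, 0),
      atom_row("C2", "C", 1, "ALA", gap, 0, 0)
    ))
    compute_sasa(s)$total
  })
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("SASA estimate is converged at 960 sphere points", {
  sim <- simulate_trajectory(8, seed = 3, n_frames = 1,
                             planted = tibble::tibble(res_i = 1L, res_j = 6L,
                                                      name_i = "ASP", name_j = "ARG",
                                                      occupancy = 1))
  topo <- sim$trajectory$topology
  expect_gte(nrow(topo$atoms), 15)
  coarse <- compute_sasa(topo, n_sphere_points = 960)$total
  fine <- compute_sasa(topo, n_sphere_points = 9600)$total
  expect_lt(abs(coarse - fine) / fine, 0.01)
})

test_that("descriptors are invariant under rigid motion of every frame", {
  sim <- simulate_trajectory(10, seed = 6, n_frames = 20)
  traj <- sim$trajectory
  motion <- random_rigid_motion(7)
  moved <- thermadk:::new_adk_trajectory(
    traj$topology, lapply(traj$frames, apply_rigid, motion = motion))

  expect_equal(compute_rmsf(moved)$rmsf, compute_rmsf(traj)$rmsf, tolerance = 1e-8)
  expect_equal(compute_rgyr(moved)$rgyr, compute_rgyr(traj)$rgyr, tolerance = 1e-9)
  # SASA is invariant only up to the sphere-point discretisation (~0.1 %)
  expect_equal(
    compute_sasa(traj$topology, coords = moved$frames[[1]])$total,
    compute_sasa(traj$topology, coords = traj$frames[[1]])$total,
    tolerance = 5e-3
  )
})

test_that("replicate aggregation returns mean and standard error", {
  expect_equal(aggregate_replicates(c(2, 2, 2)),
               tibble::tibble(mean = 2, se = 0, n_replicates = 3L))
  agg <- aggregate_replicates(c(1, 2, 3))
  expect_equal(agg$mean, 2)
  expect_equal(agg$se, 1 / sqrt(3))
  expect_warning(one <- aggregate_replicates(5), "single replicate")
  expect_true(is.na(one$se))
  expect_error(aggregate_replicates(numeric(0)))
})

test_that("replicate means concentrate as the sampling property predicts", {
  mu <- 3; tau <- 0.5
  hits <- sapply(1:200, function(s) {
    set.seed(s)
    abs(aggregate_replicates(rnorm(10, mu, tau))$mean - mu) <= 4 * tau / sqrt(10)
  })
  expect_gte(mean(hits), 0.99)
})

test_that("descriptor rows aggregate replicate trajectories", {
  reps <- lapply(1:3, function(r) simulate_trajectory(8, seed = r, n_frames = 10)$trajectory)
  row <- descriptor_row(reps, adk = "sp01", temperature = 300,
                        n_sphere_points = 240)
  expect_equal(row$n_replicates, 3)
  expect_true(all(c(row$rmsf_mean, row$sasa_mean, row$rgyr_mean) > 0))
  expect_true(all(c(row$rmsf_se, row$sasa_se, row$rgyr_se) >= 0))
  expect_equal(row$rmsf_mean_nm, row$rmsf_mean / 10)
  expect_equal(row$sasa_mean_nm2, row$sasa_mean / 100)
})
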