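# tiny trajectory helpers
toy_roster <- function(n = 4) {
  tibble::tibble(chain = "A", resno = seq_len(n), resname = "GLY",
                 atom = rep("CA", n))
}
toy_protein <- function(n = 4) {
  cbind(seq_len(n) * 3.8, 0, 0)
}

test_that("superposition returns the identity on an already-aligned frame", {
  prot <- toy_protein(5)
  traj <- new_water_trajectory(toy_roster(5), list(prot, prot),
                               list(matrix(c(1, 2, 3), 1), matrix(c(1, 2, 3), 1)))
  out <- superimpose_frames(traj)
  expect_lt(max(abs(out$protein[[2]] - prot)), 1e-9)
  expect_lt(max(attr(out, "ca_rmsd")), 1e-9)
})

test_that("a known rigid motion is exactly undone, waters included", {
  prot <- toy_protein(6) + matrix(rnorm(18, 0, 0.5), 6, 3)
  R <- inphelix:::rotation_about(c(1, 2, -1), 0.8)
  shift <- c(3, -2, 5)
  moved <- prot %*% t(R) + matrix(shift, 6, 3, byrow = TRUE)
  wat <- matrix(c(0, 5, 0, 2, 6, 1), 2, 3, byrow = TRUE)
  wat_moved <- wat %*% t(R) + matrix(shift, 2, 3, byrow = TRUE)
  traj <- new_water_trajectory(toy_roster(6), list(prot, moved),
                               list(wat, wat_moved))
  out <- superimpose_frames(traj)
  expect_lt(max(abs(out$protein[[2]] - prot)), 1e-6)
  expect_lt(max(abs(out$waters[[2]] - wat)), 1e-6)
})

test_that("superposition agrees with the bio3d least-squares fit", {
  set.seed(21)
  prot <- toy_protein(8) + matrix(rnorm(24, 0, 0.4), 8, 3)
  R <- inphelix:::rotation_about(c(0, 1, 1), -0.5)
  moved <- prot %*% t(R) + matrix(c(-1, 4, 2), 8, 3, byrow = TRUE) +
    matrix(rnorm(24, 0, 0.1), 8, 3)
  fit <- kabsch(moved, prot)
  ours <- inphelix:::apply_rigid(moved, fit$rotation, fit$translation)
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(prot)),
                                         mobile = as.vector(t(moved))))
  expect_lt(max(abs(ours - matrix(ref, ncol = 3, byrow = TRUE))), 1e-6)
})

test_that("superposition is idempotent and needs 3 C-alphas", {
  prot <- toy_protein(4)
  set.seed(2)
  frames <- lapply(1:3, function(i) prot + matrix(rnorm(12, 0, 0.2), 4, 3))
  traj <- new_water_trajectory(toy_roster(4), frames,
                               rep(list(matrix(numeric(0), 0, 3)), 3))
  once <- superimpose_frames(traj)
  twice <- superimpose_frames(once)
  for (f in 1:3) {
    expect_lt(max(abs(once$protein[[f]] - twice$protein[[f]])), 1e-9)
  }
  small <- new_water_trajectory(toy_roster(2), list(toy_protein(2)),
                                list(matrix(numeric(0), 0, 3)))
  expect_error(superimpose_frames(small), "3 C-alpha")
})

test_that("one water deposits unit mass with its maximum at the node", {
  prot <- toy_protein(3)
  water <- matrix(c(7.6, 0, 0), 1)   # on a protein atom -> inside shell
  traj <- new_water_trajectory(toy_roster(3), list(prot), list(water))
  traj <- superimpose_frames(traj)
  g <- accumulate_density(traj, density_params(shell_radius = 6,
                                               grid_spacing = 0.33))
  expect_lt(abs(sum(g$values) * g$spacing^3 - 1), 0.005)
  peak <- arrayInd(which.max(g$values), dim(g$values))
  peak_xyz <- g$origin + (peak - 1) * g$spacing
  expect_lt(max(abs(peak_xyz - water)), g$spacing)
})

test_that("the kernel route agrees with a brute-force Gaussian sum", {
  set.seed(31)
  centers <- matrix(runif(9, 2, 8), 3, 3)
  dims <- c(12L, 12L, 12L)
  origin <- c(1, 1, 1)
  spacing <- 1.0
  sigma <- 1.0 / (2 * sqrt(2 * log(2)))
  fast <- inphelix:::cpp_accumulate_gaussian(dims, origin, spacing, centers,
                                             sigma, cutoff = 50)
  dim(fast) <- dims
  norm <- 1 / (2 * pi * sigma^2)^1.5
  slow <- array(0, dims)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    p <- origin + (c(i, j, k) - 1) * spacing
    slow[i, j, k] <- sum(norm * exp(-rowSums(sweep(centers, 2, p)^2) /
                                      (2 * sigma^2)))
  }
  expect_lt(max(abs(fast - slow)), 1e-9)
})

test_that("repeated jittered observations of one site peak at the sample mean", {
  site <- c(8, 1, 0.5)
  set.seed(17)
  n <- 1000
  obs <- matrix(site, n, 3, byrow = TRUE) + matrix(rnorm(3 * n, 0, 0.2), n, 3)
  prot <- toy_protein(3)
  frames <- split.data.frame(obs, rep(1:50, each = 20))
  traj <- new_water_trajectory(toy_roster(3), rep(list(prot), 50),
                               lapply(frames, as.matrix))
  traj <- superimpose_frames(traj)
  g <- accumulate_density(traj, density_params(shell_radius = 8))
  ps <- peak_sites(g, sigma_threshold = 6)
  expect_equal(nrow(ps), 1)
  expect_lt(sqrt(sum((unlist(ps[1, c("x", "y", "z")]) - colMeans(obs))^2)),
            0.1)
  expect_equal(ps$support[1], 50)
})

test_that("mass is conserved on trajectory maps", {
  ann <- consensus_annotation(2)
  m <- build_helix(ann)
  g <- generate_trajectory(m, n_frames = 10, n_bulk_waters = 200, seed = 9)
  traj <- superimpose_frames(g$trajectory)
  grid <- accumulate_density(traj)
  expect_lt(abs(sum(grid$values) * grid$spacing^3 - grid$n_observations) /
              grid$n_observations, 0.005)
})

test_that("peak count is non-increasing in the sigma threshold", {
  m <- consensus_model(2)
  sites <- generate_ordered_waters(m, "TQTA")
  g <- generate_trajectory(m, n_frames = 20, planted_sites = sites,
                           n_bulk_waters = 300, seed = 4)
  grid <- accumulate_density(superimpose_frames(g$trajectory))
  counts <- vapply(c(2, 4, 6, 10), function(s) {
    nrow(peak_sites(grid, sigma_threshold = s))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("close maxima merge keeping the higher peak", {
  dims <- c(21L, 21L, 21L)
  vals <- array(0, dims)
  vals[10, 10, 10] <- 5
  vals[12, 10, 10] <- 4        # 0.66 A away at 0.33 A spacing
  vals[18, 10, 10] <- 3
  grid <- structure(list(origin = c(0, 0, 0), spacing = 0.33, values = vals,
                         map_mean = 0.01, map_sd = 0.1,
                         mask = array(TRUE, dims),
                         n_observations = 3L,
                         observations = matrix(numeric(0), 0, 3),
                         obs_frame = integer(0), n_frames = 1L,
                         params = density_params()),
                    class = "density_grid")
  ps <- peak_sites(grid, sigma_threshold = 6)
  expect_equal(nrow(ps), 2)
  expect_gt(ps$sigma[1], ps$sigma[2])
})

test_that("degenerate maps are rejected", {
  dims <- c(5L, 5L, 5L)
  grid <- structure(list(origin = c(0, 0, 0), spacing = 0.33,
                         values = array(1, dims), map_mean = 1, map_sd = 0,
                         mask = array(TRUE, dims), n_observations = 0L,
                         observations = matrix(numeric(0), 0, 3),
                         obs_frame = integer(0), n_frames = 1L,
                         params = density_params()),
                    class = "density_grid")
  expect_error(peak_sites(grid), "degenerate")
})

test_that("bulk-only water yields no ordered sites at the default contour", {
  # at the reference sampling depth (100 frames, ~2000 bulk waters) the
  # bulk background never reaches the 6-sigma contour
  m <- consensus_model(8)
  g <- generate_trajectory(m, n_frames = 100, planted_sites = NULL,
                           n_bulk_waters = 2000, seed = 12)
  grid <- accumulate_density(superimpose_frames(g$trajectory))
  expect_equal(nrow(peak_sites(grid, sigma_threshold = 6)), 0)
})
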