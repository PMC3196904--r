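test_that("lattice constants follow the closed forms and the printed spacings", {
  lat <- build_ice_lattice(ice_lattice_params(d_oo = 2.76))
  expect_lt(abs(lat$a - sqrt(8 / 3) * 2.76), 1e-9)
  expect_lt(abs(lat$c - (8 / 3) * 2.76), 1e-9)
  net <- plane_slice(lat, "primary_prism")
  expect_lt(abs(net$spacings["short"] - 4.5) / 4.5, 0.01)
  expect_lt(abs(net$spacings["long"] - 7.35) / 7.35, 0.01)
})

test_that("scaling the O-O distance scales every coordinate exactly", {
  l1 <- build_ice_lattice(ice_lattice_params(d_oo = 2.76, extents = c(2, 2, 2)))
  l2 <- build_ice_lattice(ice_lattice_params(d_oo = 2.76 * 1.3,
                                             extents = c(2, 2, 2)))
  expect_equal(as.matrix(l2$oxygens), as.matrix(l1$oxygens) * 1.3,
               tolerance = 1e-12)
})

test_that("interior oxygens are tetrahedrally coordinated (brute force)", {
  lat <- build_ice_lattice(ice_lattice_params(extents = c(4, 4, 3)))
  ox <- as.matrix(lat$oxygens)
  d <- as.matrix(dist(ox))
  diag(d) <- Inf
  nn <- rowSums(abs(d - lat$d_oo) < 1e-6)
  # interior = at least half a cell away from the lattice boundary, in
  # fractional coordinates (the generated region is a parallelepiped)
  frac <- ox %*% solve(lat$basis)
  ext <- c(4, 4, 3)
  interior <- apply(frac, 1, function(f) {
    all(f > 0.51) && all(ext - f > 0.51)
  })
  expect_true(any(interior))
  expect_true(all(nn[interior] == 4))
})

test_that("plane slices select the right atoms and report net repeats", {
  lat <- build_ice_lattice(ice_lattice_params(extents = c(3, 4, 3)))
  pp <- plane_slice(lat, "primary_prism", thickness = 1.0)
  expect_true(all(pp$waters$x >= max(lat$oxygens$x) - 1.0))
  expect_gt(nrow(pp$waters), 0)
  # shorter-than-any-distance slab is empty
  tiny <- plane_slice(lat, "primary_prism", thickness = 1e-6)
  expect_lte(nrow(tiny$waters), nrow(lat$oxygens[
    abs(lat$oxygens$x - max(lat$oxygens$x)) < 1e-6, ]))
  # in-plane neighbours of the single-layer prism net: d_oo along c, a along y
  w <- as.matrix(pp$waters)
  dmat <- as.matrix(dist(w)); diag(dmat) <- Inf
  expect_lt(abs(min(dmat) - lat$d_oo), 1e-6)
  # basal slab spanning both sublattices: distinct projected columns are
  # separated by the hexagon edge a/sqrt(3)
  bas <- plane_slice(lat, "basal", thickness = 3.8)
  proj <- unique(round(as.matrix(bas$waters[, c("x", "y")]), 6))
  dp <- as.matrix(dist(proj)); diag(dp) <- Inf
  expect_lt(abs(min(dp) - lat$a / sqrt(3)), 1e-5)
  expect_error(plane_slice(lat, "prism_secondary"), "arg")
})

test_that("an exact subset of the net registers with zero RMSD", {
  lat <- build_ice_lattice(ice_lattice_params(extents = c(2, 6, 4)))
  net <- plane_slice(lat, "primary_prism")
  sub <- as.matrix(net$waters[seq(1, nrow(net$waters), by = 2), ])
  fit <- register_sites(sub, net)
  expect_true(fit$converged)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$matched_fraction, 1)
  # transform is proper rigid
  R <- fit$rotation
  expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
})

test_that("registration is invariant to rigid pre-transforms of the sites", {
  lat <- build_ice_lattice(ice_lattice_params(extents = c(2, 6, 4)))
  net <- plane_slice(lat, "primary_prism")
  sub <- as.matrix(net$waters[seq(1, nrow(net$waters), by = 3), ])
  set.seed(5)
  sub <- sub + matrix(rnorm(length(sub), 0, 0.1), ncol = 3)
  f0 <- register_sites(sub, net)
  R <- inphelix:::rotation_about(c(1, -1, 2), 1.1)
  moved <- sub %*% t(R) + matrix(c(4, -7, 2), nrow(sub), 3, byrow = TRUE)
  f1 <- register_sites(moved, net)
  expect_lt(abs(f0$rmsd - f1$rmsd), 1e-6)
  expect_equal(nrow(f0$matched_pairs), nrow(f1$matched_pairs))
})

test_that("noisy-subset registration matches the Monte-Carlo noise oracle", {
  lat <- build_ice_lattice(ice_lattice_params(extents = c(2, 6, 4)))
  net <- plane_slice(lat, "primary_prism")
  truth <- as.matrix(net$waters[seq(1, min(44 * 2, nrow(net$waters)), by = 2), ])
  sigma <- 0.17
  # oracle: E[RMSD] of a Kabsch fit of noisy points onto their true
  # positions (no correspondence search involved)
  set.seed(99)
  oracle <- mean(replicate(200, {
    noisy <- truth + matrix(rnorm(length(truth), 0, sigma), ncol = 3)
    kabsch(noisy, truth)$rmsd
  }))
  rmsds <- vapply(1:25, function(s) {
    set.seed(s)
    noisy <- truth + matrix(rnorm(length(truth), 0, sigma), ncol = 3)
    register_sites(noisy, net)$rmsd
  }, numeric(1))
  expect_gt(mean(rmsds), 0.24)
  expect_lt(mean(rmsds), 0.36)
  expect_lt(abs(mean(rmsds) - oracle), 0.05)
})

test_that("registration RMSD grows with the noise amplitude", {
  lat <- build_ice_lattice(ice_lattice_params(extents = c(2, 6, 4)))
  net <- plane_slice(lat, "primary_prism")
  truth <- as.matrix(net$waters[seq(1, nrow(net$waters), by = 2), ])
  mean_rmsd <- vapply(c(0.05, 0.15, 0.3), function(sigma) {
    mean(vapply(1:5, function(s) {
      set.seed(s * 100)
      noisy <- truth + matrix(rnorm(length(truth), 0, sigma), ncol = 3)
      register_sites(noisy, net)$rmsd
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rmsd) > 0))
})

test_that("registration failure is reported when sites cannot pair", {
  net <- plane_slice(build_ice_lattice(ice_lattice_params(extents = c(2, 4, 3))),
                     "primary_prism")
  # three nearly coincident sites can share at most one mutual nearest
  # neighbour, so no start can maintain 3 correspondences
  far <- matrix(c(0, 0, 0, 0.1, 0, 0, 0, 0.1, 0), 3, 3, byrow = TRUE)
  fit <- register_sites(far, net, max_pair_distance = 0.5)
  expect_false(fit$converged)
  expect_equal(fit$matched_fraction, 0)
  expect_error(register_sites(far[1:2, ], net), "at least 3")
})
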