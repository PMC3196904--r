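test_that("zero substitution reproduces the exact consensus tiling", {
  g <- generate_inp_sequence(8, substitution_rate = 0,
                             anchor_substitution_rate = 0, seed = 1)
  expect_equal(g$sequence, strrep(CONSENSUS_FILL, 8))
  ann <- detect_repeats(g$sequence)
  expect_equal(sum(!ann$partial), 8)
  expect_equal(ann$identity, rep(1, 8))
})

test_that("generators are pure functions of parameters and seed", {
  g1 <- generate_inp_sequence(16, seed = 5)
  g2 <- generate_inp_sequence(16, seed = 5)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$truth$events, g2$truth$events)
  m <- consensus_model(2)
  t1 <- generate_trajectory(m, n_frames = 3, n_bulk_waters = 50, seed = 8)
  t2 <- generate_trajectory(m, n_frames = 3, n_bulk_waters = 50, seed = 8)
  for (f in 1:3) {
    expect_identical(t1$trajectory$protein[[f]], t2$trajectory$protein[[f]])
    expect_identical(t1$trajectory$waters[[f]], t2$trajectory$waters[[f]])
  }
})

test_that("extending the frame count never reshuffles earlier frames", {
  m <- consensus_model(2)
  short <- generate_trajectory(m, n_frames = 4, n_bulk_waters = 50, seed = 13)
  long <- generate_trajectory(m, n_frames = 8, n_bulk_waters = 50, seed = 13)
  for (f in 1:4) {
    expect_identical(short$trajectory$waters[[f]], long$trajectory$waters[[f]])
  }
})

test_that("planted profiles are recovered across seeds within binomial bounds", {
  prof <- tibble::tibble(position = 5L, residue = "T", frequency = 0.90)
  hits <- vapply(1:50, function(s) {
    g <- generate_inp_sequence(64, profile = prof, seed = s)
    pft <- position_frequencies(detect_repeats(g$sequence, min_identity = 0.3))
    ci <- stats::binom.test(pft$counts[5, "T"], 64)$conf.int
    ci[1] <= 0.90 && 0.90 <= ci[2]
  }, logical(1))
  # the exact 95% interval may miss in ~5% of draws
  expect_gte(mean(hits), 0.85)
})

test_that("invalid generator arguments are rejected", {
  expect_error(generate_inp_sequence(4, substitution_rate = 1), "rate")
  m <- consensus_model(2)
  expect_error(generate_trajectory(m, occupancy = 0), "occupancy")
  expect_error(generate_trajectory(m, n_frames = 2, n_bulk_waters = 5000,
                                   box_padding = 1), "box too small")
})

test_that("full occupancy with zero jitter gives identical frames peaking on sites", {
  m <- consensus_model(2)
  sites <- generate_ordered_waters(m, "TQTA")
  g <- generate_trajectory(m, n_frames = 5, protein_jitter = 0,
                           planted_sites = sites, occupancy = 1,
                           site_jitter = 0, n_bulk_waters = 0, seed = 2)
  np <- nrow(sites)
  for (f in 1:5) {
    expect_identical(g$trajectory$protein[[f]], g$trajectory$protein[[1]])
    expect_equal(g$trajectory$waters[[f]][seq_len(np), ],
                 unname(as.matrix(sites)), ignore_attr = TRUE)
  }
  grid <- accumulate_density(superimpose_frames(g$trajectory))
  ps <- peak_sites(grid)
  dd <- inphelix:::cpp_min_dist(as.matrix(sites),
                                as.matrix(ps[, c("x", "y", "z")]))
  expect_true(all(dd < 0.1))
})

test_that("bulk waters respect the hard-core exclusion", {
  m <- consensus_model(2)
  sites <- generate_ordered_waters(m, "TQTA")
  g <- generate_trajectory(m, n_frames = 3, planted_sites = sites,
                           n_bulk_waters = 400, seed = 6)
  np <- sum(g$truth$site_present[1, ])
  w <- g$trajectory$waters[[1]]
  bulk <- w[-seq_len(np), , drop = FALSE]
  dmin <- min(inphelix:::cpp_min_dist(bulk, g$trajectory$protein[[1]]))
  expect_gte(dmin, 2.4)
})

test_that("the planted water net carries the prism-plane spacings at the standoff", {
  m <- consensus_model(8)
  for (face in c("TQTA", "SLTA")) {
    sites <- generate_ordered_waters(m, face, standoff = 2.8)
    sp <- attr(sites, "spacings")
    expect_lt(abs(sp["short"] - 4.5) / 4.5, 0.01)
    expect_lt(abs(sp["long"] - 7.35) / 7.35, 0.01)
    # standoff from the face's outermost strand atoms
    regs <- if (face == "TQTA") 5:8 else 13:16
    fa <- m[m$register %in% regs, ]
    xs <- if (face == "TQTA") max(fa$x) else min(fa$x)
    expect_equal(unique(round(abs(sites$x - xs), 6)), 2.8)
    # clipped to the face footprint
    expect_true(all(sites$y >= min(fa$y) - 1 & sites$y <= max(fa$y) + 1))
    expect_true(all(sites$z >= min(fa$z) - 1 & sites$z <= max(fa$z) + 1))
    # brute-force clipping oracle: count net nodes inside the footprint
    lat <- build_ice_lattice(ice_lattice_params(extents = c(1, 30, 30)))
    net <- plane_slice(lat, "primary_prism", 1.0)$waters
    ny <- net$y - min(net$y) + min(fa$y) - 1
    nz <- net$z - min(net$z) + min(fa$z) - 1
    inside <- sum(ny <= max(fa$y) + 1 & nz <= max(fa$z) + 1)
    expect_equal(nrow(sites), inside)
  }
})

test_that("sites planted outside the shell are never recovered", {
  m <- consensus_model(2)
  sites <- generate_ordered_waters(m, "TQTA", standoff = 14)
  g <- generate_trajectory(m, n_frames = 20, planted_sites = sites,
                           occupancy = 1, n_bulk_waters = 200,
                           box_padding = 16, seed = 3)
  grid <- accumulate_density(superimpose_frames(g$trajectory),
                             density_params(shell_radius = 10))
  ps <- peak_sites(grid)
  if (nrow(ps) > 0) {
    dd <- inphelix:::cpp_min_dist(as.matrix(sites),
                                  as.matrix(ps[, c("x", "y", "z")]))
    expect_true(all(dd > 1))
  } else {
    expect_equal(nrow(ps), 0)
  }
})

test_that("truth records round-trip through JSON serialization", {
  g <- generate_inp_sequence(8, seed = 44)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(spans = g$truth$spans, events = g$truth$events),
                       path, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(tibble::as_tibble(back$spans), g$truth$spans)
  if (nrow(g$truth$events)) {
    expect_equal(tibble::as_tibble(back$events), g$truth$events)
  }
})
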