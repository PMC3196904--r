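dimer8 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_dimer(consensus_model(8))
    cache
  }
})

test_that("dimer chains are congruent rigid copies", {
  d <- dimer8()
  a <- atom_xyz(d, d$chain == "A")
  b <- atom_xyz(d, d$chain == "B")
  expect_lt(kabsch(b, a)$rmsd, 1e-6)
})

test_that("parallel mode keeps the N termini at the same end", {
  d <- dimer8()
  z1a <- d$z[d$chain == "A" & d$resno == min(d$resno) & d$atom == "CA"]
  z1b <- d$z[d$chain == "B" & d$resno == min(d$resno) & d$atom == "CA"]
  expect_lt(abs(z1a - z1b), 4.8)
  # antiparallel flips the axis
  anti <- build_dimer(consensus_model(8), dimer_spec(mode = "antiparallel"))
  z1b_anti <- anti$z[anti$chain == "B" & anti$resno == min(anti$resno) &
                       anti$atom == "CA"]
  expect_gt(abs(z1a - z1b_anti), 4.8 * 5)
})

test_that("the interface gap is realized within 0.1 A by exhaustive scan", {
  for (gap in c(3.2, 3.5, 4.0)) {
    d <- build_dimer(consensus_model(4), dimer_spec(interface_gap = gap))
    lad <- model_ladders(d)
    tyr <- lad[lad$ladder == "tyrosine_ladder", ]
    mins <- c()
    for (ch in c("A", "B")) {
      sel <- d$chain == ch &
        d$resno %in% tyr$resno[tyr$chain == ch]
      other <- atom_xyz(d, d$chain != ch)
      tt <- atom_xyz(d, sel)
      dd <- sqrt(outer(rowSums(tt^2), rowSums(other^2), "+") -
                   2 * tt %*% t(other))
      mins <- c(mins, min(dd))
    }
    expect_lt(abs(min(mins) - gap), 0.1)
  }
})

test_that("each composite face pairs TQTA of one chain with SLTA of the other", {
  d <- dimer8()
  ca <- d[d$atom == "CA", ]
  mean_x <- function(ch, regs) mean(ca$x[ca$chain == ch & ca$register %in% regs])
  # +x face: chain A TQTA strand and chain B SLTA strand
  expect_gt(mean_x("A", c(5, 7)), 0)
  expect_gt(mean_x("B", c(13, 15)), 0)
  expect_lt(mean_x("A", c(13, 15)), 0)
  expect_lt(mean_x("B", c(5, 7)), 0)
})

test_that("a single chain reports zero interface metrics with a warning", {
  expect_warning(rep <- interface_metrics(consensus_model(4)), "single")
  expect_equal(rep$cross_chain_hbonds, 0)
})

test_that("planted Tyr-OH / Ser-OG contacts are counted as intercalation pairs", {
  # synthetic two-chain arrangement with k hydroxyl pairs at 3.2 A and
  # proper donor geometry, verified against a brute-force pair count
  k <- 5
  mk_res <- function(chain, resno, resname, atoms, base) {
    tibble::tibble(
      chain = chain, resno = resno, resname = resname,
      atom = names(atoms),
      element = substr(names(atoms), 1, 1),
      x = base[1] + vapply(atoms, function(a) a[1], numeric(1)),
      y = base[2] + vapply(atoms, function(a) a[2], numeric(1)),
      z = base[3] + vapply(atoms, function(a) a[3], numeric(1)),
      register = NA_integer_, coil = NA_integer_
    )
  }
  rows <- list()
  for (i in seq_len(k)) {
    zb <- i * 4.8
    rows[[2 * i - 1]] <- mk_res("A", i, "TYR",
      list(CZ = c(0, -1.37, 0), OH = c(0, 0, 0)), c(0, 0, zb))
    rows[[2 * i]] <- mk_res("B", i, "SER",
      list(CB = c(0, 4.61, 0), OG = c(0, 3.2, 0)), c(0, 0, zb))
  }
  toy <- inphelix:::new_inp_model(dplyr::bind_rows(rows))
  rep <- interface_metrics(toy)
  # brute force: all cross-chain O-O pairs within 3.5 A
  oa <- atom_xyz(toy, toy$chain == "A" & toy$atom == "OH")
  ob <- atom_xyz(toy, toy$chain == "B" & toy$atom == "OG")
  dd <- sqrt(outer(rowSums(oa^2), rowSums(ob^2), "+") - 2 * oa %*% t(ob))
  expect_equal(sum(dd <= 3.5), k)
  expect_equal(rep$tyr_ser_pairs, k)
  expect_equal(rep$cross_chain_hbonds, k)
})

test_that("interface metrics are symmetric under chain relabeling", {
  d <- build_dimer(consensus_model(4, mode = "idealized_rotamers"),
                   dimer_spec(interface_gap = 3.2))
  swapped <- d
  swapped$chain <- ifelse(d$chain == "A", "B", "A")
  attr(swapped, "ladders") <- dplyr::mutate(
    model_ladders(d), chain = ifelse(.data$chain == "A", "B", "A"))
  r1 <- interface_metrics(d)
  r2 <- interface_metrics(swapped)
  expect_equal(r1$cross_chain_hbonds, r2$cross_chain_hbonds)
  expect_equal(r1$min_interchain_distance, r2$min_interchain_distance)
  expect_equal(r1$tyr_buried, r2$tyr_buried)
})

test_that("twist is zero for the ideal dimer and recovers an applied twist", {
  d <- dimer8()
  ft <- flatness_twist(d)
  expect_lt(abs(ft$twist_per_coil), 0.1)
  m <- consensus_model(8)
  for (applied in c(1, 2, 5)) {
    tw <- m
    xyz <- atom_xyz(m)
    for (k in unique(m$coil)) {
      idx <- which(m$coil == k)
      a <- (k - 1) * applied * pi / 180
      R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      xyz[idx, ] <- xyz[idx, ] %*% t(R)
    }
    tw$x <- xyz[, 1]; tw$y <- xyz[, 2]; tw$z <- xyz[, 3]
    expect_equal(flatness_twist(tw)$twist_per_coil, applied, tolerance = 0.05)
  }
})

test_that("face planarity degrades monotonically with applied twist", {
  m <- consensus_model(8)
  rms <- vapply(c(0, 1, 2, 3, 5), function(applied) {
    xyz <- atom_xyz(m)
    for (k in unique(m$coil)) {
      idx <- which(m$coil == k)
      a <- (k - 1) * applied * pi / 180
      R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      xyz[idx, ] <- xyz[idx, ] %*% t(R)
    }
    tw <- m; tw$x <- xyz[, 1]; tw$y <- xyz[, 2]; tw$z <- xyz[, 3]
    flatness_twist(tw)$face_planarity_rmsd
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("flatness_twist requires at least 3 coils", {
  expect_error(flatness_twist(consensus_model(2)), "3 coils")
})

test_that("a two-chain zero-offset multimer reduces to the parallel dimer", {
  mm <- build_multimer(consensus_model(4), n_chains = 2, offset_coils = 0)
  d <- build_dimer(consensus_model(4))
  expect_equal(atom_xyz(mm), atom_xyz(d), tolerance = 1e-9)
})

test_that("multimer extent is affine in chain count and offset", {
  rise <- 4.8
  for (cfg in list(c(3, 4), c(2, 4), c(4, 4))) {
    mm <- build_multimer(consensus_model(8), n_chains = cfg[1],
                         offset_coils = cfg[2])
    ca <- mm[mm$atom == "CA", ]
    extent <- diff(range(ca$z))
    predicted <- (8 + (cfg[1] - 1) * cfg[2]) * rise
    expect_lt(abs(extent - predicted) / predicted, 0.1)
  }
})

test_that("impossible offsets are rejected", {
  expect_error(build_multimer(consensus_model(4), n_chains = 3,
                              offset_coils = 4), "offset")
  # same-column chains overlapping in z cannot be tiled
  expect_error(build_multimer(consensus_model(8), n_chains = 3,
                              offset_coils = 2), "impossible")
})
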