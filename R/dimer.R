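#' Dimer assembly specification
#'
#' @param mode `"parallel"` (duplicate rotated 180 degrees about the long
#'   axis; N termini at the same end) or `"antiparallel"` (rotated 180
#'   degrees about the face normal, N termini at opposite ends).
#' @param interface_gap Target minimum heavy-atom distance between the
#'   tyrosine ladder and the opposite chain, Angstroms (in `[3.0, 5.0]`).
#' @param offset_coils Coil offset used when tiling multimers.
#' @return A `dimer_spec` list.
#' @export
dimer_spec <- function(mode = c("parallel", "antiparallel"),
                       interface_gap = 3.5, offset_coils = 0L) {
  mode <- match.arg(mode)
  if (interface_gap < 3.0 || interface_gap > 5.0) {
    stop("interface_gap must be in [3.0, 5.0] A")
  }
  structure(list(mode = mode, interface_gap = interface_gap,
                 offset_coils = as.integer(offset_coils)),
            class = "dimer_spec")
}

# heavy atoms of the tyrosine-ladder residues of one chain
tyr_ladder_xyz <- function(model, chain) {
  lad <- model_ladders(model)
  lad <- lad[lad$ladder == "tyrosine_ladder" & lad$chain == chain, ]
  if (nrow(lad) == 0) return(NULL)
  sel <- model$chain == chain &
    paste(model$chain, model$resno) %in% paste(lad$chain, lad$resno)
  model_xyz(model[sel, ])
}

# rigid transform of the duplicated chain for a given mode, before the
# interface translation
dimer_partner_xyz <- function(xyz, mode, z_center) {
  if (mode == "parallel") {
    # 180 degrees about the helix (z) axis
    cbind(-xyz[, 1], -xyz[, 2], xyz[, 3])
  } else {
    # 180 degrees about the face normal (x): flips y and z
    cbind(xyz[, 1], -xyz[, 2], 2 * z_center - xyz[, 3])
  }
}

#' Build a tyrosine-ladder dimer of a helix model
#'
#' Chain B is a rigid copy of chain A rotated 180 degrees about the long
#' axis (parallel mode, N termini at the same end) or about the face
#' normal (antiparallel). B is then translated along the interface normal
#' (the y axis of the built frame) by a 1D line search until the minimum
#' heavy-atom distance between either chain's tyrosine ladder and the
#' opposite chain equals `interface_gap` (within 0.1 A). In the parallel
#' dimer each composite face pairs the SLTA surface of one chain with the
#' TQTA surface of the other.
#'
#' @param model A single-chain `inp_model` with a tyrosine-ladder
#'   annotation (see [annotate_ladders()]).
#' @param spec A [dimer_spec()].
#' @return A two-chain `inp_model` (chains A and B).
#' @export
build_dimer <- function(model, spec = dimer_spec()) {
  stopifnot(inherits(model, "inp_model"), inherits(spec, "dimer_spec"))
  lad <- model_ladders(model)
  if (!any(lad$ladder == "tyrosine_ladder")) {
    stop("model has no tyrosine_ladder annotation; run annotate_ladders()")
  }
  chain_a <- model[model$chain == model$chain[1], ]
  xyz_a <- model_xyz(chain_a)
  z_center <- mean(range(xyz_a[, 3]))
  xyz_b0 <- dimer_partner_xyz(xyz_a, spec$mode, z_center)

  tyr_a <- tyr_ladder_xyz(model, model$chain[1])
  lad_rows <- paste(chain_a$chain, chain_a$resno) %in%
    paste(lad$chain[lad$ladder == "tyrosine_ladder"],
          lad$resno[lad$ladder == "tyrosine_ladder"])

  mind_at <- function(s) {
    xb <- xyz_b0
    xb[, 2] <- xb[, 2] + s
    tyr_b <- xb[lad_rows, , drop = FALSE]
    min(cpp_min_dist(tyr_a, xb), cpp_min_dist(tyr_b, xyz_a))
  }
  # bracket: at small separation the ladders interpenetrate, at large they
  # are far apart; the minimum distance is monotone in s on the far side
  s_hi <- diff(range(c(xyz_a[, 2], xyz_b0[, 2]))) + 30
  f <- function(s) mind_at(s) - spec$interface_gap
  if (f(s_hi) < 0) stop("could not separate chains to the requested gap")
  s_lo <- 0
  if (f(s_lo) > 0) {
    # already separated at zero shift; search downward
    while (f(s_lo) > 0 && s_lo > -s_hi) s_lo <- s_lo - 2
  }
  sol <- stats::uniroot(f, c(s_lo, s_hi), tol = 1e-3)
  s <- sol$root

  chain_b <- chain_a
  xb <- xyz_b0
  xb[, 2] <- xb[, 2] + s
  chain_b <- set_model_xyz(chain_b, xb)
  chain_b$chain <- "B"
  out <- dplyr::bind_rows(tibble::as_tibble(chain_a),
                          tibble::as_tibble(chain_b))
  ladders <- dplyr::bind_rows(
    lad,
    dplyr::mutate(lad, chain = "B")
  )
  dimer <- new_inp_model(out, ladders = ladders,
                         helix_axis = attr(model, "helix_axis"),
                         params = attr(model, "params"))
  clash <- model_clashes(dimer, cutoff = 2.5)
  cross <- clash[dimer$chain[clash$i] != dimer$chain[clash$j], ]
  if (nrow(cross) > 0) {
    stop("unresolvable inter-chain clash (", nrow(cross),
         " contacts below 2.5 A) at the requested interface gap")
  }
  attr(dimer, "dimer_spec") <- spec
  dimer
}

# donor and acceptor heavy atoms (hydrogens are absent from the models; a
# heavy-atom angle at the donor serves as the geometry proxy)
HB_DONORS <- list(
  N = "CA", OG = "CB", OG1 = "CB", OH = "CZ", NE2 = "CD", ND2 = "CG",
  NZ = "CE", NE1 = "CD1", SG = "CB"
)
HB_ACCEPTORS <- c("O", "OG", "OG1", "OH", "OE1", "OD1", "OE2", "OD2",
                  "ND1", "SG")

#' Interface metrics of a dimer
#'
#' Counts cross-chain hydrogen bonds (donor-acceptor heavy-atom pairs
#' within `hbond_dist` whose donor-antecedent/donor/acceptor angle is at
#' least `hbond_angle`), the tyrosine-serine hydroxyl intercalation pairs,
#' the minimum inter-chain heavy-atom distance, buried tyrosine-ladder
#' residues, and the twist/flatness measures of the assembly.
#'
#' @param dimer A two-chain `inp_model`.
#' @param hbond_dist Donor-acceptor distance cutoff, Angstroms.
#' @param hbond_angle Minimum angle (degrees) at the donor.
#' @return An `interface_report` list.
#' @export
interface_metrics <- function(dimer, hbond_dist = 3.5, hbond_angle = 120) {
  stopifnot(inherits(dimer, "inp_model"))
  chains <- unique(dimer$chain)
  if (length(chains) == 1) {
    warning("single-chain model: no interface")
    return(structure(
      list(cross_chain_hbonds = 0L,
           hbond_pairs = tibble::tibble(), tyr_ser_pairs = 0L,
           min_interchain_distance = NA_real_, tyr_buried = 0L,
           twist_per_coil = NA_real_, face_planarity_rmsd = NA_real_,
           single_chain = TRUE),
      class = "interface_report"
    ))
  }
  if (length(chains) != 2) stop("interface_metrics expects exactly two chains")
  don <- dimer[dimer$atom %in% names(HB_DONORS), ]
  acc <- dimer[dimer$atom %in% HB_ACCEPTORS, ]
  get_xyz <- function(tbl) unname(as.matrix(tbl[, c("x", "y", "z")]))
  pairs <- list()
  for (i in seq_len(nrow(don))) {
    d_at <- don[i, ]
    ante_name <- HB_DONORS[[d_at$atom]]
    ante <- dimer[dimer$chain == d_at$chain & dimer$resno == d_at$resno &
                    dimer$atom == ante_name, ]
    cand <- acc[acc$chain != d_at$chain, ]
    if (nrow(cand) == 0) next
    dd <- sqrt((cand$x - d_at$x)^2 + (cand$y - d_at$y)^2 +
                 (cand$z - d_at$z)^2)
    close <- which(dd <= hbond_dist)
    for (j in close) {
      a_at <- cand[j, ]
      ang <- if (nrow(ante) == 1) {
        v1 <- c(ante$x[1], ante$y[1], ante$z[1]) - c(d_at$x, d_at$y, d_at$z)
        v2 <- c(a_at$x, a_at$y, a_at$z) - c(d_at$x, d_at$y, d_at$z)
        acos(max(-1, min(1, sum(vec_unit(v1) * vec_unit(v2))))) * 180 / pi
      } else 180
      if (ang >= hbond_angle) {
        pairs[[length(pairs) + 1]] <- tibble::tibble(
          donor_chain = d_at$chain, donor_resno = d_at$resno,
          donor_resname = d_at$resname, donor_atom = d_at$atom,
          acceptor_chain = a_at$chain, acceptor_resno = a_at$resno,
          acceptor_resname = a_at$resname, acceptor_atom = a_at$atom,
          distance = dd[j], angle = ang
        )
      }
    }
  }
  hb <- if (length(pairs)) dplyr::bind_rows(pairs) else tibble::tibble()
  n_hb <- 0L
  tyr_ser <- 0L
  if (nrow(hb)) {
    # a hydroxyl pair can qualify in both donor directions; count each
    # physical contact once
    id_a <- paste(hb$donor_chain, hb$donor_resno, hb$donor_atom)
    id_b <- paste(hb$acceptor_chain, hb$acceptor_resno, hb$acceptor_atom)
    key <- paste(pmin(id_a, id_b), pmax(id_a, id_b))
    n_hb <- length(unique(key))
    is_ts <- (hb$donor_resname == "TYR" & hb$donor_atom == "OH" &
                hb$acceptor_resname == "SER" & hb$acceptor_atom == "OG") |
      (hb$donor_resname == "SER" & hb$donor_atom == "OG" &
         hb$acceptor_resname == "TYR" & hb$acceptor_atom == "OH")
    tyr_ser <- length(unique(key[is_ts]))
  }

  a_xyz <- get_xyz(dimer[dimer$chain == chains[1], ])
  b_xyz <- get_xyz(dimer[dimer$chain == chains[2], ])
  min_inter <- min(cpp_min_dist(a_xyz, b_xyz))

  lad <- model_ladders(dimer)
  tyr <- lad[lad$ladder == "tyrosine_ladder", ]
  buried <- 0L
  for (i in seq_len(nrow(tyr))) {
    sel <- dimer$chain == tyr$chain[i] & dimer$resno == tyr$resno[i]
    other <- get_xyz(dimer[dimer$chain != tyr$chain[i], ])
    if (min(cpp_min_dist(get_xyz(dimer[sel, ]), other)) < 4.5) {
      buried <- buried + 1L
    }
  }
  ft <- tryCatch(flatness_twist(dimer), error = function(e) {
    list(twist_per_coil = NA_real_, face_planarity_rmsd = NA_real_)
  })
  structure(
    list(cross_chain_hbonds = n_hb, hbond_pairs = hb,
         tyr_ser_pairs = as.integer(tyr_ser),
         min_interchain_distance = min_inter, tyr_buried = buried,
         twist_per_coil = ft$twist_per_coil,
         face_planarity_rmsd = ft$face_planarity_rmsd,
         single_chain = FALSE),
    class = "interface_report"
  )
}

#' @export
print.interface_report <- function(x, ...) {
  cat("<interface_report> ", x$cross_chain_hbonds, " cross-chain H-bonds (",
      x$tyr_ser_pairs, " Tyr-OH...Ser-OG), min inter-chain distance ",
      round(x$min_interchain_distance, 2), " A, ", x$tyr_buried,
      " buried Tyr\n", sep = "")
  invisible(x)
}

#' @export
glance.interface_report <- function(x, ...) {
  tibble::tibble(
    cross_chain_hbonds = x$cross_chain_hbonds,
    tyr_ser_pairs = x$tyr_ser_pairs,
    min_interchain_distance = x$min_interchain_distance,
    tyr_buried = x$tyr_buried,
    twist_per_coil = x$twist_per_coil,
    face_planarity_rmsd = x$face_planarity_rmsd
  )
}

#' Twist per coil and face planarity of a model
#'
#' Twist is the mean signed rotation, about the helix axis, of the
#' cross-section reference direction (coil centroid to the register-2
#' corner) between successive coils, averaged over chains. Planarity is
#' the RMSD of the outward strand C-alpha atoms (the pleat peaks, registers
#' 5/7 and 13/15) of each composite face from that face's best-fit plane.
#'
#' @param model An `inp_model` with at least 3 coils.
#' @return List with `twist_per_coil` (degrees), `face_planarity_rmsd`
#'   (mean over faces, Angstroms) and `faces` (per-face tibble).
#' @export
flatness_twist <- function(model) {
  stopifnot(inherits(model, "inp_model"))
  axis <- (attr(model, "helix_axis") %||% list(direction = c(0, 0, 1)))$direction
  chains <- unique(model$chain)
  twists <- c()
  for (ch in chains) {
    m <- model[model$chain == ch & model$atom == "CA" & !is.na(model$coil), ]
    coils <- sort(unique(m$coil))
    if (length(coils) < 3) stop("need at least 3 coils to measure twist")
    refdir <- vapply(coils, function(k) {
      sub <- m[m$coil == k, ]
      cen <- colMeans(as.matrix(sub[, c("x", "y", "z")]))
      corner <- sub[sub$register == 2L, ]
      v <- c(corner$x[1], corner$y[1], corner$z[1]) - cen
      v <- v - sum(v * axis) * axis
      vec_unit(v)
    }, numeric(3))
    ang <- vapply(seq_len(ncol(refdir) - 1), function(k) {
      v1 <- refdir[, k]; v2 <- refdir[, k + 1]
      atan2(sum(vec_cross(v1, v2) * axis), sum(v1 * v2)) * 180 / pi
    }, numeric(1))
    twists <- c(twists, ang)
  }
  # faces: outward pleat peaks, split by side of the axis plane
  peaks <- model[model$atom == "CA" & model$register %in% c(5L, 7L, 13L, 15L), ]
  xyz <- model_xyz(peaks)
  side <- sign(xyz[, 1] - mean(xyz[, 1]))
  faces <- lapply(c(-1, 1), function(sg) {
    pts <- xyz[side == sg, , drop = FALSE]
    if (nrow(pts) < 3) return(NA_real_)
    cen <- colMeans(pts)
    sv <- svd(sweep(pts, 2, cen))
    nrm <- sv$v[, 3]
    sqrt(mean((sweep(pts, 2, cen) %*% nrm)^2))
  })
  faces_tbl <- tibble::tibble(face = c("minus_x", "plus_x"),
                              planarity_rmsd = unlist(faces))
  list(twist_per_coil = mean(twists),
       face_planarity_rmsd = mean(unlist(faces), na.rm = TRUE),
       faces = faces_tbl)
}

#' Tile an offset multimer from a helix model
#'
#' Chains alternate between the two dimer orientations so each new chain
#' pairs its tyrosine ladder with the exposed ladder of the previous chain,
#' shifted along the helix axis by `offset_coils` coils. `n_chains = 2`
#' with zero offset reduces to the parallel dimer.
#'
#' @param model A single-chain `inp_model` with ladder annotations.
#' @param n_chains Number of chains (>= 2).
#' @param offset_coils Axial offset between successive chains, in coils
#'   (must be smaller than the coil count).
#' @param spec A [dimer_spec()] providing the interface gap.
#' @return An `inp_model` with chains A, B, C, ...
#' @export
build_multimer <- function(model, n_chains, offset_coils = 0L,
                           spec = dimer_spec(offset_coils = offset_coils)) {
  stopifnot(inherits(model, "inp_model"), n_chains >= 2)
  n_coils <- length(unique(stats::na.omit(model$coil)))
  if (offset_coils >= n_coils) {
    stop("offset_coils must be smaller than the coil count (", n_coils, ")")
  }
  dimer <- build_dimer(model, dimer_spec(mode = "parallel",
                                         interface_gap = spec$interface_gap,
                                         offset_coils = offset_coils))
  rise <- (attr(model, "params") %||% helix_params())$rise_per_coil
  chain_a <- dimer[dimer$chain == "A", ]
  chain_b <- dimer[dimer$chain == "B", ]
  lad <- model_ladders(model)
  out <- list()
  ladders <- list()
  for (k in seq_len(n_chains)) {
    base <- if (k %% 2 == 1) chain_a else chain_b
    piece <- tibble::as_tibble(base)
    # one extra coil of clearance each time a chain starts past the end of
    # the previous chain in its own column, so abutting termini do not
    # interpenetrate
    wraps <- if (n_coils > 0) ((k - 1) * offset_coils) %/% n_coils else 0
    piece$z <- piece$z + ((k - 1) * offset_coils + wraps) * rise
    piece$chain <- LETTERS[k]
    out[[k]] <- piece
    ladders[[k]] <- dplyr::mutate(lad, chain = LETTERS[k])
  }
  multi <- new_inp_model(dplyr::bind_rows(out),
                         ladders = dplyr::bind_rows(ladders),
                         helix_axis = attr(model, "helix_axis"),
                         params = attr(model, "params"))
  clash <- model_clashes(multi, cutoff = 2.5)
  cross <- clash[multi$chain[clash$i] != multi$chain[clash$j], ]
  if (nrow(cross) > 0) {
    stop("geometrically impossible offset: ", nrow(cross),
         " inter-chain contacts below 2.5 A")
  }
  attr(multi, "dimer_spec") <- spec
  multi
}
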