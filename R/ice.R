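#' Parameters for the ideal hexagonal ice (Ih) oxygen lattice
#'
#' The oxygen sublattice of ice Ih is the hexagonal-diamond (lonsdaleite)
#' arrangement: every oxygen is tetrahedrally coordinated by four others at
#' the nearest-neighbour distance `d_oo`. The hexagonal cell constants
#' follow in closed form: `a = sqrt(8/3) * d_oo` and `c = (8/3) * d_oo`.
#'
#' @param d_oo Nearest-neighbour O-O distance in Angstroms (2.76 is the
#'   standard value for ice at ambient pressure).
#' @param extents Integer vector of cell repeats along the a, b and c axes.
#' @return An `ice_lattice_params` list.
#' @export
ice_lattice_params <- function(d_oo = 2.76, extents = c(4L, 4L, 3L)) {
  stopifnot(is.numeric(d_oo), d_oo > 0)
  extents <- rep_len(as.integer(extents), 3L)
  if (any(extents < 1)) stop("extents must all be >= 1")
  structure(list(d_oo = d_oo, extents = extents),
            class = "ice_lattice_params")
}

#' Build an ideal ice Ih oxygen lattice
#'
#' Generates oxygen positions on the hexagonal-diamond lattice. The frame
#' is chosen so that the normal of the primary prism plane (the 10-10
#' face) lies along +x and the crystallographic c axis along +z; the
#' in-plane short repeat (length `a`) then runs along +y.
#'
#' @param params An [ice_lattice_params()] object.
#' @return An `ice_lattice`: list with `oxygens` (tibble x, y, z), lattice
#'   constants `a` and `c`, `d_oo` and the 3 x 3 `basis` matrix (cell
#'   vectors as rows).
#' @export
#' @examples
#' lat <- build_ice_lattice(ice_lattice_params(d_oo = 2.76))
#' lat$a  # ~4.51 A
#' lat$c  # ~7.36 A
build_ice_lattice <- function(params = ice_lattice_params()) {
  stopifnot(inherits(params, "ice_lattice_params"))
  d <- params$d_oo
  a <- sqrt(8 / 3) * d
  cc <- (8 / 3) * d
  # hexagonal basis oriented so the {10-10} normal is +x:
  # a1 has the only off-plane (x) component; a2 along +y; c along +z.
  a1 <- c(a * sqrt(3) / 2, -a / 2, 0)
  a2 <- c(0, a, 0)
  a3 <- c(0, 0, cc)
  basis <- rbind(a1, a2, a3)
  # lonsdaleite oxygen sites (fractional): 4 per cell
  frac <- rbind(
    c(1 / 3, 2 / 3, 1 / 16),
    c(2 / 3, 1 / 3, 9 / 16),
    c(2 / 3, 1 / 3, 15 / 16),
    c(1 / 3, 2 / 3, 7 / 16)
  )
  ext <- params$extents
  cells <- expand.grid(i = 0:(ext[1] - 1), j = 0:(ext[2] - 1),
                       k = 0:(ext[3] - 1))
  xyz <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    shift <- as.numeric(cells[r, ])
    (frac + matrix(shift, 4, 3, byrow = TRUE)) %*% basis
  }))
  structure(
    list(oxygens = tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
         a = a, c = cc, d_oo = d, basis = basis),
    class = "ice_lattice"
  )
}

#' @export
print.ice_lattice <- function(x, ...) {
  cat("<ice_lattice> ", nrow(x$oxygens), " oxygens, d_OO = ", x$d_oo,
      " A, a = ", round(x$a, 3), " A, c = ", round(x$c, 3), " A\n", sep = "")
  invisible(x)
}

#' Slice a crystal plane out of an ice lattice
#'
#' Extracts the oxygens lying within `thickness` of the outermost named
#' plane and reports the two orthogonal in-plane repeat spacings of the
#' resulting water net. For the primary prism plane these are `a` (~4.5 A)
#' and `c` (~7.35 A) at the standard O-O distance; for the basal plane both
#' repeats equal `a`.
#'
#' @param lattice An `ice_lattice`.
#' @param plane `"primary_prism"` (the 10-10 face, normal +x) or
#'   `"basal"` (the 0001 face, normal +z).
#' @param thickness Slab thickness in Angstroms measured from the outermost
#'   atom layer.
#' @return A `plane_net`: list with `waters` (tibble x, y, z), `plane`,
#'   `normal`, and `spacings` (named numeric, sorted ascending).
#' @export
plane_slice <- function(lattice, plane = c("primary_prism", "basal"),
                        thickness = 1.0) {
  stopifnot(inherits(lattice, "ice_lattice"))
  plane <- match.arg(plane)
  if (!is.numeric(thickness) || thickness <= 0) stop("thickness must be > 0")
  ox <- lattice$oxygens
  if (plane == "primary_prism") {
    coord <- ox$x
    normal <- c(1, 0, 0)
    spacings <- c(short = lattice$a, long = lattice$c)
  } else {
    coord <- ox$z
    normal <- c(0, 0, 1)
    # basal net: puckered hexagonal rings, edge projecting to a/sqrt(3)
    spacings <- c(short = lattice$a / sqrt(3), long = lattice$a)
  }
  top <- max(coord)
  keep <- coord >= top - thickness
  structure(
    list(waters = ox[keep, , drop = FALSE], plane = plane, normal = normal,
         spacings = spacings, lattice = lattice),
    class = "plane_net"
  )
}

#' @export
print.plane_net <- function(x, ...) {
  cat("<plane_net> ", x$plane, ": ", nrow(x$waters), " waters, repeats ",
      round(x$spacings[1], 3), " x ", round(x$spacings[2], 3), " A\n", sep = "")
  invisible(x)
}

# mutual nearest neighbours between two point sets within a cutoff
mutual_nn <- function(p, q, cutoff) {
  if (nrow(p) == 0 || nrow(q) == 0) {
    return(cbind(site = integer(), lattice = integer()))
  }
  d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * p %*% t(q)
  d2[d2 < 0] <- 0
  nn_pq <- max.col(-d2, ties.method = "first")
  nn_qp <- max.col(-t(d2), ties.method = "first")
  i <- seq_len(nrow(p))
  keep <- nn_qp[nn_pq[i]] == i & sqrt(d2[cbind(i, nn_pq[i])]) <= cutoff
  cbind(site = i[keep], lattice = nn_pq[i][keep])
}

#' Register ordered-water sites against an ice plane net
#'
#' Finds the rigid transform placing the observed sites onto the lattice
#' net by iterative closest point: mutual-nearest-neighbour correspondences
#' within `max_pair_distance` alternate with closed-form Kabsch
#' superposition until the RMSD changes by less than 1e-6 A (at most 50
#' iterations). The sites' best-fit plane is first aligned with the net
#' plane; a deterministic multi-start over both plane flips, 12 in-plane
#' rotations and a 3 x 3 grid of lattice translations within one unit cell
#' guards against local minima. The best result is the one with the most
#' matched pairs, ties broken by lower RMSD.
#'
#' @param sites Water sites: a tibble/data frame with `x`, `y`, `z`
#'   columns (for example from [peak_sites()]), or a numeric matrix.
#' @param net A `plane_net` from [plane_slice()].
#' @param max_pair_distance Correspondence cutoff in Angstroms.
#' @return A `registration_result`: list with `rotation`, `translation`,
#'   `rmsd`, `matched_pairs` (tibble site/lattice indices), and
#'   `matched_fraction`; `converged` is `FALSE` with a `reason` when fewer
#'   than 3 pairs survive.
#' @export
register_sites <- function(sites, net, max_pair_distance = 1.5) {
  stopifnot(inherits(net, "plane_net"))
  p <- site_matrix(sites)
  if (nrow(p) < 3) stop("need at least 3 sites to register")
  q <- as.matrix(net$waters[, c("x", "y", "z")])

  cen_p <- colMeans(p); cen_q <- colMeans(q)
  axis <- net$normal
  # pre-align the sites' best-fit plane normal with the net normal (both
  # signs), making the fit invariant to arbitrary rigid pre-transforms;
  # the multi-start grid then only needs in-plane rotations
  sv <- svd(sweep(p, 2, cen_p))
  n3 <- sv$v[, 3]
  pre_rotations <- lapply(c(1, -1), function(sgn) {
    v <- sgn * n3
    cs <- sum(v * axis)
    ax <- vec_cross(v, axis)
    if (sqrt(sum(ax^2)) < 1e-9) {
      if (cs > 0) diag(3) else rotation_about(
        if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0), pi)
    } else {
      rotation_about(ax, acos(max(-1, min(1, cs))))
    }
  })
  angles <- seq(0, 2 * pi, length.out = 13)[1:12]
  # translation offsets spanning one unit cell of the net
  sp <- net$spacings
  in1 <- if (net$plane == "primary_prism") c(0, 1, 0) else c(1, 0, 0)
  in2 <- if (net$plane == "primary_prism") c(0, 0, 1) else c(0, 1, 0)
  offs <- expand.grid(u = c(0, 1 / 3, 2 / 3), v = c(0, 1 / 3, 2 / 3))

  best <- NULL
  for (pre in pre_rotations) {
  for (ang in angles) {
    R0 <- rotation_about(axis, ang) %*% pre
    for (r in seq_len(nrow(offs))) {
      shift <- offs$u[r] * sp[1] * in1 + offs$v[r] * sp[2] * in2
      # initial guess: rotate about site centroid, then move centroid onto
      # net centroid plus the lattice offset
      cur <- sweep(p, 2, cen_p) %*% t(R0) +
        matrix(cen_q + shift, nrow(p), 3, byrow = TRUE)
      res <- icp_refine(cur, q, max_pair_distance)
      if (is.null(res)) next
      # best = largest mutual correspondence set, then lowest RMSD (a
      # smaller subset can always fit tighter, so pair count dominates)
      if (is.null(best) || nrow(res$pairs) > nrow(best$pairs) ||
          (nrow(res$pairs) == nrow(best$pairs) &&
           res$rmsd < best$rmsd - 1e-12)) {
        res$R0 <- R0; res$shift0 <- cen_q + shift - as.vector(R0 %*% cen_p)
        best <- res
      }
    }
  }
  }
  if (is.null(best)) {
    return(structure(
      list(rotation = diag(3), translation = c(0, 0, 0), rmsd = NA_real_,
           matched_pairs = tibble::tibble(site = integer(), lattice = integer()),
           matched_fraction = 0, converged = FALSE,
           reason = "fewer than 3 matched pairs at convergence"),
      class = "registration_result"
    ))
  }
  # compose overall transform: x -> Rfit (R0 x + shift0) + tfit
  R_tot <- best$rotation %*% best$R0
  t_tot <- as.vector(best$rotation %*% best$shift0) + best$translation
  fitted <- apply_rigid(p, R_tot, t_tot)
  structure(
    list(rotation = R_tot, translation = t_tot, rmsd = best$rmsd,
         matched_pairs = tibble::tibble(site = best$pairs[, 1],
                                        lattice = best$pairs[, 2]),
         matched_fraction = nrow(best$pairs) / nrow(p),
         sites_fitted = tibble::tibble(x = fitted[, 1], y = fitted[, 2],
                                       z = fitted[, 3]),
         net = net, converged = TRUE, reason = NULL),
    class = "registration_result"
  )
}

# core ICP loop; returns NULL when fewer than 3 pairs can be maintained
icp_refine <- function(p0, q, cutoff, max_iter = 50, tol = 1e-6) {
  cur <- p0
  R_acc <- diag(3); t_acc <- c(0, 0, 0)
  prev_rmsd <- Inf
  for (it in seq_len(max_iter)) {
    pairs <- mutual_nn(cur, q, cutoff)
    if (nrow(pairs) < 3) return(NULL)
    fit <- kabsch(cur[pairs[, 1], , drop = FALSE],
                  q[pairs[, 2], , drop = FALSE])
    cur <- apply_rigid(cur, fit$rotation, fit$translation)
    R_acc <- fit$rotation %*% R_acc
    t_acc <- as.vector(fit$rotation %*% t_acc) + fit$translation
    if (abs(prev_rmsd - fit$rmsd) < tol) {
      return(list(rotation = R_acc, translation = t_acc, rmsd = fit$rmsd,
                  pairs = pairs))
    }
    prev_rmsd <- fit$rmsd
  }
  pairs <- mutual_nn(cur, q, cutoff)
  if (nrow(pairs) < 3) return(NULL)
  list(rotation = R_acc, translation = t_acc, rmsd = prev_rmsd, pairs = pairs)
}

site_matrix <- function(sites) {
  if (is.matrix(sites)) {
    stopifnot(ncol(sites) == 3)
    return(unname(sites))
  }
  stopifnot(all(c("x", "y", "z") %in% names(sites)))
  unname(as.matrix(sites[, c("x", "y", "z")]))
}

#' @export
print.registration_result <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat("<registration_result> RMSD ", round(x$rmsd, 3), " A over ",
        nrow(x$matched_pairs), " pairs (matched fraction ",
        round(x$matched_fraction, 2), ")\n", sep = "")
  } else {
    cat("<registration_result> FAILED: ", x$reason, "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.registration_result <- function(x, ...) {
  x$matched_pairs
}

#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(
    rmsd = x$rmsd,
    n_matched = nrow(x$matched_pairs),
    matched_fraction = x$matched_fraction,
    converged = isTRUE(x$converged)
  )
}
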