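# Shared 3D geometry helpers. Coordinates are plain numeric matrices with
# one row per point, in Angstroms.

vec_unit <- function(v) v / sqrt(sum(v^2))

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation matrix about unit axis by angle (radians), Rodrigues form
rotation_about <- function(axis, theta) {
  a <- vec_unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors.
#' @return Angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vec_cross(b1, b2); n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, vec_unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum || R x_i + t - y_i ||^2` over paired points.
#'
#' @param x,y Numeric matrices (n x 3) of paired coordinates; `x` is moved
#'   onto `y`.
#' @param weights Optional per-pair weights.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   and `rmsd` after superposition.
#' @export
kabsch <- function(x, y, weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y), nrow(x) >= 3)
  w <- if (is.null(weights)) rep(1, nrow(x)) else weights / sum(weights) * nrow(x)
  cx <- colSums(x * w) / sum(w)
  cy <- colSums(y * w) / sum(w)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  H <- t(x0 * w) %*% y0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cy - as.vector(R %*% cx)
  moved <- x %*% t(R) + matrix(t_vec, nrow(x), 3, byrow = TRUE)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((moved - y)^2))))
}

apply_rigid <- function(xyz, rotation, translation) {
  as.matrix(xyz) %*% t(rotation) +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
}

# RMSD between two paired coordinate sets without fitting
rmsd_plain <- function(x, y) sqrt(mean(rowSums((as.matrix(x) - as.matrix(y))^2)))
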