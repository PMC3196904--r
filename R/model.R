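# Structure models are tibbles with one row per atom:
#   chain, resno, resname, atom, element, x, y, z, register, coil
# plus attributes: ladders (tibble ladder/chain/resno), helix_axis
# (list(origin, direction)), params (helix_params).

new_inp_model <- function(atoms, ladders = NULL, helix_axis = NULL,
                          params = NULL) {
  structure(
    atoms,
    class = c("inp_model", class(tibble::tibble())),
    ladders = ladders,
    helix_axis = helix_axis,
    params = params
  )
}

#' @export
print.inp_model <- function(x, ...) {
  nch <- length(unique(x$chain))
  nres <- nrow(unique(x[, c("chain", "resno")]))
  cat("<inp_model> ", nch, " chain(s), ", nres, " residues, ", nrow(x),
      " atoms\n", sep = "")
  lad <- attr(x, "ladders")
  if (!is.null(lad) && nrow(lad)) {
    cat("  ladders:", paste(sprintf("%s(%d)", unique(lad$ladder),
                                    table(lad$ladder)[unique(lad$ladder)]),
                            collapse = " "), "\n")
  }
  NextMethod()
}

model_xyz <- function(model) {
  unname(as.matrix(model[, c("x", "y", "z")]))
}

set_model_xyz <- function(model, xyz) {
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' Ladder annotation table of a model
#'
#' @param model An `inp_model`.
#' @return Tibble with columns `ladder`, `chain`, `resno`.
#' @export
model_ladders <- function(model) {
  attr(model, "ladders") %||%
    tibble::tibble(ladder = character(), chain = character(),
                   resno = integer())
}

#' Axial extent and cross-section dimensions of a model
#'
#' Measures the maximum C-alpha extent along the helix axis (length), the
#' in-plane extent along the face width direction (width) and across the
#' two beta-sheets (thickness).
#'
#' @param model An `inp_model` with a helix axis attribute (built models
#'   have one; otherwise the principal axis of the C-alpha cloud is used).
#' @return One-row tibble with `length`, `width`, `thickness` in Angstroms.
#' @export
model_dimensions <- function(model) {
  ca <- model[model$atom == "CA", ]
  xyz <- model_xyz(ca)
  ax <- attr(model, "helix_axis")
  if (is.null(ax)) {
    cen <- colMeans(xyz)
    pc <- prcomp(xyz)
    u <- pc$rotation[, 1]
    w <- pc$rotation[, 2]; tdir <- pc$rotation[, 3]
    origin <- cen
  } else {
    u <- ax$direction; origin <- ax$origin
    w <- c(0, 1, 0); tdir <- c(1, 0, 0)
    if (abs(sum(u * w)) > 0.9) w <- c(1, 0, 0)
    w <- vec_unit(w - sum(w * u) * u)
    tdir <- vec_cross(u, w)
  }
  rel <- sweep(xyz, 2, origin)
  proj <- rel %*% cbind(u, w, tdir)
  tibble::tibble(
    length = diff(range(proj[, 1])),
    width = diff(range(proj[, 2])),
    thickness = diff(range(proj[, 3]))
  )
}

# all heavy-atom clashes below `cutoff`; pairs separated by >= 2 residues
# within a chain, or any pair across chains
model_clashes <- function(model, cutoff = 2.5) {
  xyz <- model_xyz(model)
  n <- nrow(xyz)
  if (n < 2) {
    return(tibble::tibble(i = integer(), j = integer(), distance = numeric()))
  }
  d <- as.matrix(stats::dist(xyz))
  same_chain <- outer(model$chain, model$chain, "==")
  dres <- abs(outer(model$resno, model$resno, "-"))
  eligible <- (!same_chain) | (dres >= 2)
  hit <- which(d < cutoff & eligible & upper.tri(d), arr.ind = TRUE)
  tibble::tibble(i = hit[, 1], j = hit[, 2],
                 distance = d[hit])
}
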