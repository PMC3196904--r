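#' Ice-active surface area models
#'
#' Describes the flat rectangular footprint of the ice-ordering faces of an
#' INP monomer, dimer or multimer. The area follows the simple arithmetic
#' `face_length x face_width x n_faces`; a parallel dimer presents two
#' composite faces, each spanning the full width of both chains. The
#' `extrapolated` constructor converts a repeat count into a face length at
#' a nominal rise of 5 A per coil, so that the full 64-repeat central
#' domain gives a 320 A long face.
#'
#' @param face_length,face_width Face dimensions in Angstroms.
#' @param n_faces Number of ice-active faces (1 for a single exposed face,
#'   2 for a dimer presenting both sides).
#' @param source How the dimensions were obtained
#'   (`"measured-from-model"` or `"extrapolated-from-repeats"`).
#' @return An `area_model` list.
#' @export
#' @examples
#' active_area(area_model(320, 40, n_faces = 2))  # 25600
area_model <- function(face_length, face_width, n_faces = 2,
                       source = "measured-from-model") {
  stopifnot(is.numeric(face_length), face_length > 0,
            is.numeric(face_width), face_width > 0,
            n_faces %in% c(1, 2))
  structure(list(face_length = face_length, face_width = face_width,
                 n_faces = as.integer(n_faces), source = source),
            class = "area_model")
}

#' @param n_repeats Number of 16-aa repeats (coils).
#' @param rise_per_coil Extrapolation rise per coil in Angstroms. The
#'   default 5.0 reproduces the published arithmetic (64 coils -> 320 A);
#'   the coordinate builder's 4.8 A default is an independent parameter.
#' @rdname area_model
#' @export
area_model_from_repeats <- function(n_repeats, face_width = 40,
                                    n_faces = 2, rise_per_coil = 5.0) {
  stopifnot(is.numeric(n_repeats), n_repeats >= 1)
  area_model(n_repeats * rise_per_coil, face_width, n_faces,
             source = "extrapolated-from-repeats")
}

#' @export
print.area_model <- function(x, ...) {
  cat("<area_model> ", x$face_length, " x ", x$face_width, " A, ",
      x$n_faces, " face(s) [", x$source, "]: ",
      format(active_area(x), big.mark = ","), " A^2\n", sep = "")
  invisible(x)
}

#' Ice-active surface area of a model
#'
#' @param model An [area_model()].
#' @return Area in square Angstroms: `face_length * face_width * n_faces`.
#' @export
active_area <- function(model) {
  stopifnot(inherits(model, "area_model"))
  model$face_length * model$face_width * model$n_faces
}

#' Critical ice-embryo area threshold
#'
#' Literature value for the minimum flat template area an ice embryo needs
#' to keep growing at a given temperature; the default 20,100 square
#' Angstroms applies at -12 degrees C, the temperature at which single INP
#' molecules are active.
#'
#' @param area Threshold area in square Angstroms.
#' @param temperature Temperature in degrees Celsius at which the threshold
#'   applies.
#' @param note Free-text provenance note.
#' @return A `critical_area_threshold` list.
#' @export
critical_area_threshold <- function(area = 20100, temperature = -12,
                                    note = "literature value for ice-embryo growth") {
  stopifnot(is.numeric(area), area > 0)
  structure(list(area = area, temperature = temperature, note = note),
            class = "critical_area_threshold")
}

#' Compare an active surface area against the critical embryo threshold
#'
#' @param area Active area in square Angstroms (a number or an
#'   [area_model()]).
#' @param threshold A [critical_area_threshold()].
#' @return A one-row tibble with `area`, `threshold`, `passes` and `margin`
#'   (area minus threshold, square Angstroms).
#' @export
#' @examples
#' critical_area_check(25600)
critical_area_check <- function(area, threshold = critical_area_threshold()) {
  if (inherits(area, "area_model")) area <- active_area(area)
  stopifnot(is.numeric(area), area >= 0,
            inherits(threshold, "critical_area_threshold"))
  tibble::tibble(
    area = area,
    threshold_area = threshold$area,
    temperature = threshold$temperature,
    passes = area >= threshold$area,
    margin = area - threshold$area
  )
}

#' Active surface area of an offset multimer
#'
#' Computes the two composite-face area of `n_chains` chains tiled with a
#' coil offset: the assembly length is
#' `(n_coils + (n_chains - 1) * offset_coils) * per_coil_rise`, so overlap
#' between successive chains is counted once.
#'
#' @param n_chains Number of chains in the assembly.
#' @param offset_coils Coil offset between successive chains (0 =
#'   in-register dimer stacking).
#' @param n_coils Coils per chain.
#' @param per_coil_rise Rise per coil in Angstroms.
#' @param width Composite face width in Angstroms.
#' @param n_faces Number of ice-active faces.
#' @return Area in square Angstroms.
#' @export
#' @examples
#' multimer_area(n_chains = 2, offset_coils = 0, n_coils = 64) # = dimer area
multimer_area <- function(n_chains, offset_coils = 0, n_coils = 64,
                          per_coil_rise = 5.0, width = 40, n_faces = 2) {
  stopifnot(n_chains >= 1, offset_coils >= 0)
  if (n_chains > 1 && offset_coils >= n_coils) {
    stop("offset_coils must be smaller than the coils per chain (",
         n_coils, ")")
  }
  len <- (n_coils + (n_chains - 1) * offset_coils) * per_coil_rise
  len * width * n_faces
}
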