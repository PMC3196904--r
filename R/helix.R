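#' Parameters of the parametric beta-helix builder
#'
#' @param handedness `"right"` (default) or `"left"`. The left-handed build
#'   is the exact mirror image (x -> -x) of the right-handed build; either
#'   hand is plausible for an ice-nucleation protein and the choice does
#'   not affect any face geometry.
#' @param rise_per_coil Axial rise per 16-residue coil, Angstroms (stacked
#'   parallel beta-sheet spacing; must lie in `[4.5, 5.2]`).
#' @param strand_ca_step Axial advance of consecutive C-alpha along a
#'   strand, Angstroms (must lie in `[3.2, 3.6]`). The coil cross-section
#'   template realizes ~3.37 A; the value is validated and recorded.
#' @param sidechain_mode `"cbeta_only"` (default) places only C-beta;
#'   `"idealized_rotamers"` additionally places full side chains with
#'   standard bond geometry in a fixed extended convention — sufficient for
#'   ladder hydrogen-bond distance checks, not for packing energetics.
#' @return A `helix_params` list.
#' @export
helix_params <- function(handedness = c("right", "left"),
                         rise_per_coil = 4.8,
                         strand_ca_step = 3.37,
                         sidechain_mode = c("cbeta_only", "idealized_rotamers")) {
  handedness <- match.arg(handedness)
  sidechain_mode <- match.arg(sidechain_mode)
  if (rise_per_coil < 4.5 || rise_per_coil > 5.2) {
    stop("rise_per_coil must be in [4.5, 5.2] A")
  }
  if (strand_ca_step < 3.2 || strand_ca_step > 3.6) {
    stop("strand_ca_step must be in [3.2, 3.6] A")
  }
  structure(list(handedness = handedness, rise_per_coil = rise_per_coil,
                 strand_ca_step = strand_ca_step,
                 sidechain_mode = sidechain_mode),
            class = "helix_params")
}

# 16 x 2 in-plane coil template from the frozen constants
coil_template_xy <- function() {
  s <- sqrt(COIL_CHORD^2 - COIL_DZ^2)
  adv <- sqrt(COIL_CHORD^2 - COIL_DZ^2 - 4 * STRAND_DELTA^2)
  y0 <- 1.5 * adv
  strandA <- rbind(c(STRAND_XA + STRAND_DELTA, y0),
                   c(STRAND_XA - STRAND_DELTA, y0 - adv),
                   c(STRAND_XA + STRAND_DELTA, adv - y0),
                   c(STRAND_XA - STRAND_DELTA, -y0))
  p <- strandA[4, ]
  turn <- matrix(0, 4, 2)
  for (i in 1:4) {
    p <- p + s * c(cos(TURN_DIRS[i]), sin(TURN_DIRS[i]))
    turn[i, ] <- p
  }
  rbind(-turn, strandA, turn, -strandA)
}

# intrinsic frame of the CA trace at an interior residue
trace_frame <- function(prev, cur, nxt) {
  t <- vec_unit(nxt - prev)
  m <- (prev + nxt) / 2 - cur
  p <- vec_unit(m - sum(m * t) * t)
  rbind(t, p, vec_cross(t, p))
}

AA_321 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
            G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
            M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
            S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

# standard L construction of C-beta from backbone atoms
place_cb <- function(N, CA, C) {
  v1 <- vec_unit(N - CA); v2 <- vec_unit(C - CA)
  bis <- -vec_unit(v1 + v2)
  nrm <- vec_unit(vec_cross(v2, v1))
  CA + BOND_CA_CB * vec_unit(bis * cos(0.9128) + nrm * sin(0.9128))
}

#' Build an idealized parallel beta-helix model from a repeat annotation
#'
#' One solenoid coil is built per complete 16-residue repeat: the TxTA and
#' xLxA strand motifs run as extended beta-conformations on the +x and -x
#' faces, the GYGS and xxxS turns form the connecting corners, and
#' successive coils stack in register along the +z helix axis at
#' `rise_per_coil`. Backbone N, C, O atoms are placed from the frozen
#' per-register frame offsets (see `R/helix-constants.R`); side chains
#' follow `sidechain_mode`. Residue numbering follows the annotation spans.
#'
#' @param annotation A `repeat_annotation` with at least one complete
#'   repeat (see [detect_repeats()]).
#' @param params A [helix_params()] object.
#' @return An `inp_model` atom tibble with ladder annotations attached (see
#'   [annotate_ladders()]).
#' @export
#' @examples
#' ann <- detect_repeats(strrep("GYGSTQTAGEGSSLTA", 8))
#' model <- build_helix(ann)
build_helix <- function(annotation, params = helix_params()) {
  stopifnot(inherits(annotation, "repeat_annotation"),
            inherits(params, "helix_params"))
  complete <- annotation[!annotation$partial, , drop = FALSE]
  n_coils <- nrow(complete)
  if (n_coils == 0) stop("annotation has no complete repeat to build from")
  seqs <- repeat_strings(annotation)[!annotation$partial]
  aa1 <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  bad <- setdiff(unique(aa1), names(AA_321))
  if (length(bad)) stop("unknown residue name(s): ", paste(bad, collapse = ", "))
  resnames <- unname(AA_321[aa1])
  resnos <- unlist(lapply(seq_len(n_coils), function(k) {
    complete$start[k]:complete$end[k]
  }))
  n <- 16L * n_coils
  dz <- params$rise_per_coil / 16
  xy <- coil_template_xy()
  ca <- do.call(rbind, lapply(seq_len(n_coils) - 1L, function(k) {
    cbind(xy, dz * (0:15) + params$rise_per_coil * k)
  }))
  register <- rep(1:16, n_coils)
  coil <- rep(seq_len(n_coils), each = 16L)

  # backbone via per-register frame offsets; periodic ghosts at the ends
  Npos <- matrix(NA_real_, n, 3)
  Cpos <- matrix(NA_real_, n, 3)
  rise_vec <- c(0, 0, params$rise_per_coil)
  for (i in seq_len(n)) {
    prev <- if (i == 1) ca[16, ] - rise_vec else ca[i - 1, ]
    nxt <- if (i == n) ca[n - 15, ] + rise_vec else ca[i + 1, ]
    F <- trace_frame(prev, ca[i, ], nxt)
    rr <- ((register[i] - 1L) %% 8L) + 1L
    if (rr <= 4) {
      oN <- BB_OFF_TURN_N[rr, ]; oC <- BB_OFF_TURN_C[rr, ]
    } else {
      oN <- BB_OFF_STRAND_N; oC <- BB_OFF_STRAND_C
    }
    Npos[i, ] <- ca[i, ] + as.vector(t(F) %*% oN)
    Cpos[i, ] <- ca[i, ] + as.vector(t(F) %*% oC)
  }
  Opos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n - 1)) {
    Opos[i, ] <- Cpos[i, ] + BOND_C_O *
      (-vec_unit(vec_unit(Npos[i + 1, ] - Cpos[i, ]) +
                   vec_unit(ca[i, ] - Cpos[i, ])))
  }
  Opos[n, ] <- Cpos[n, ] + BOND_C_O *
    vec_unit(vec_unit(Cpos[n, ] - ca[n, ]) + c(0, 0, 1))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    atoms <- rbind(N = Npos[i, ], CA = ca[i, ], C = Cpos[i, ], O = Opos[i, ])
    if (resnames[i] != "GLY") {
      cb <- place_cb(Npos[i, ], ca[i, ], Cpos[i, ])
      atoms <- rbind(atoms, CB = cb)
      if (params$sidechain_mode == "idealized_rotamers") {
        sc <- place_sidechain(resnames[i], ca[i, ], cb)
        if (!is.null(sc)) atoms <- rbind(atoms, sc)
      }
    }
    rows[[i]] <- tibble::tibble(
      chain = "A", resno = resnos[i], resname = resnames[i],
      atom = rownames(atoms),
      element = ELEMENT_FROM_ATOM(rownames(atoms)),
      x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
      register = register[i], coil = coil[i]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (params$handedness == "left") out$x <- -out$x
  model <- new_inp_model(out,
                         helix_axis = list(origin = c(0, 0, 0),
                                           direction = c(0, 0, 1)),
                         params = params)
  annotate_ladders(model, annotation)
}

# Extended side-chain templates. Atoms are placed in a frame anchored at
# C-beta: e1 = the CA->CB direction projected perpendicular to the helix
# axis (so chains extend across, not along, the solenoid), ez = the helix
# axis, eb = e1 x ez (in the coil plane, pointing toward the turn the
# residue's polar tip leans to). Geometry is schematic-but-bonded:
# standard bond lengths and a fixed extended chi convention. Long inward
# chains (Gln, Glu, Leu, Ile) bend toward `eb` so they run along the core
# toward the turns instead of piercing the opposite sheet; aromatic rings
# are tilted 45 degrees from the coil axis so stacked ladder rings clear
# each other. The mode serves ladder hydrogen-bond distance checks, not
# packing energetics.
place_sidechain <- function(resname, CA, CB, axis = c(0, 0, 1)) {
  e1 <- vec_unit(CB - CA)
  e1h <- e1 - sum(e1 * axis) * axis
  if (sqrt(sum(e1h^2)) < 1e-6) e1h <- vec_cross(axis, c(1, 0, 0))
  e1 <- vec_unit(e1h)
  ez <- axis
  eb <- vec_cross(e1, ez)
  at <- function(d, a_deg, axis2 = eb) {
    a <- a_deg * pi / 180
    d * (cos(a) * e1 + sin(a) * axis2)
  }
  sc <- switch(resname,
    SER = rbind(OG = CB + at(1.41, 15, ez)),
    THR = rbind(OG1 = CB + at(1.43, 30, ez),
                CG2 = CB + at(1.52, -30, ez)),
    CYS = rbind(SG = CB + at(1.81, 15, ez)),
    VAL = rbind(CG1 = CB + at(1.52, 30, ez),
                CG2 = CB + at(1.52, -30, ez)),
    ALA = NULL,
    GLY = NULL,
    LEU = {
      cg <- CB + at(1.53, 40)
      rbind(CG = cg,
            CD1 = cg + at(1.53, 65, ez),
            CD2 = cg + at(1.53, -45))
    },
    ILE = {
      cg1 <- CB + at(1.53, 40)
      rbind(CG1 = cg1, CG2 = CB + at(1.53, -30),
            CD1 = cg1 + at(1.53, 40, ez))
    },
    GLN = {
      # climbs the inter-coil gap so the amide tip sits between coils
      cg <- CB + at(1.52, 60, ez)
      cd <- cg + at(1.52, 60, ez)
      rbind(CG = cg, CD = cd,
            OE1 = cd + at(1.23, 50, ez),
            NE2 = cd + at(1.32, -70, ez))
    },
    ASN = {
      cg <- CB + at(1.52, 60, ez)
      rbind(CG = cg,
            OD1 = cg + at(1.23, 50, ez),
            ND2 = cg + at(1.32, -70, ez))
    },
    GLU = {
      cg <- CB + at(1.52, 60, ez)
      cd <- cg + at(1.52, 60, ez)
      rbind(CG = cg, CD = cd,
            OE1 = cd + at(1.25, 50, ez),
            OE2 = cd + at(1.25, -70, ez))
    },
    ASP = {
      cg <- CB + at(1.52, 60, ez)
      rbind(CG = cg,
            OD1 = cg + at(1.25, 50, ez),
            OD2 = cg + at(1.25, -70, ez))
    },
    TYR = {
      em <- vec_unit(cos(pi / 4) * ez + sin(pi / 4) * eb)  # 45 deg ring tilt
      cg <- CB + at(1.51, 0)
      ring <- function(dpar, dperp) cg + dpar * e1 + dperp * em
      rbind(CG = cg,
            CD1 = ring(0.70, 1.20), CD2 = ring(0.70, -1.20),
            CE1 = ring(2.09, 1.20), CE2 = ring(2.09, -1.20),
            CZ = ring(2.79, 0),
            OH = ring(4.16, 0))
    },
    PHE = {
      em <- vec_unit(cos(pi / 4) * ez + sin(pi / 4) * eb)
      cg <- CB + at(1.51, 0)
      ring <- function(dpar, dperp) cg + dpar * e1 + dperp * em
      rbind(CG = cg,
            CD1 = ring(0.70, 1.20), CD2 = ring(0.70, -1.20),
            CE1 = ring(2.09, 1.20), CE2 = ring(2.09, -1.20),
            CZ = ring(2.79, 0))
    },
    # generic stub for remaining types: a single gamma carbon
    rbind(CG = CB + at(1.52, 15, ez))
  )
  sc
}

#' Annotate the serine, glutamine and tyrosine ladders of a model
#'
#' The serine ladder is the inward-pointing residue at register 12 (final
#' position of the xxxS turn); the glutamine ladder is the inward-pointing
#' residue at register 6 (second position of TxTA), counted only when that
#' residue actually is glutamine (glycine substitutions are excluded); the
#' tyrosine ladder is the outward-pointing residue at register 2 (second
#' position of GYGS).
#'
#' @param model An `inp_model` whose coils correspond 1:1 to the complete
#'   repeats of `annotation`.
#' @param annotation The `repeat_annotation` the model was built from; when
#'   `NULL`, register columns already present in the model are used.
#' @return The model with a `ladders` attribute (tibble ladder, chain,
#'   resno).
#' @export
annotate_ladders <- function(model, annotation = NULL) {
  stopifnot(inherits(model, "inp_model"))
  if (!is.null(annotation)) {
    n_coils_model <- length(unique(stats::na.omit(model$coil)))
    n_complete <- sum(!annotation$partial)
    if (n_coils_model != n_complete) {
      stop("model coils (", n_coils_model,
           ") do not match annotation complete repeats (", n_complete, ")")
    }
  }
  res <- dplyr::distinct(tibble::as_tibble(model[, c("chain", "resno",
                                                     "resname", "register")]))
  lad <- dplyr::bind_rows(
    dplyr::filter(res, .data$register == 12L, .data$resname == "SER") |>
      dplyr::mutate(ladder = "serine_ladder"),
    dplyr::filter(res, .data$register == 6L, .data$resname == "GLN") |>
      dplyr::mutate(ladder = "glutamine_ladder"),
    dplyr::filter(res, .data$register == 2L, .data$resname == "TYR") |>
      dplyr::mutate(ladder = "tyrosine_ladder")
  )
  attr(model, "ladders") <- lad[, c("ladder", "chain", "resno")]
  model
}

# torsion classification boxes (degrees)
classify_region <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return(NA_character_)
  if (phi >= -95 && phi <= -50 && psi >= 120 && psi <= 180) return("ppii")
  if (phi >= -175 && phi <= -50 && (psi >= 60 || psi <= -150)) return("beta")
  if (phi >= -160 && phi <= -40 && psi >= -80 && psi <= 30) return("alpha")
  if (phi >= 25 && phi <= 110 && psi >= -30 && psi <= 80) return("alpha")
  "other"
}

#' Validate the geometry of a built model
#'
#' Computes backbone phi/psi/omega torsions and classifies each residue
#' into torsion regions (beta, polyproline II, alpha, other), lists steric
#' clashes (non-bonded heavy atoms closer than 2.5 A, pairs at least two
#' residues apart or on different chains), and measures the model
#' dimensions and realized rise per coil. The report passes when there are
#' no clashes and every strand-register residue (registers 5-8 and 13-16)
#' classifies as beta (or its polyproline II sub-region).
#'
#' @param model An `inp_model` with backbone atoms.
#' @param clash_cutoff Heavy-atom clash distance, Angstroms.
#' @return A `geometry_report`: list with `torsions` (tibble), `clashes`
#'   (tibble), `dimensions`, `rise_per_coil`, and `passes`.
#' @export
validate_geometry <- function(model, clash_cutoff = 2.5) {
  stopifnot(inherits(model, "inp_model"))
  res_tbl <- dplyr::distinct(tibble::as_tibble(
    model[, c("chain", "resno", "resname", "register", "coil")]
  ))
  if (nrow(res_tbl) < 2) stop("model must have at least 2 residues")
  get_atom <- function(chain, resno, name) {
    hit <- model[model$chain == chain & model$resno == resno &
                   model$atom == name, ]
    if (nrow(hit) == 0) return(NULL)
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  tors <- vector("list", nrow(res_tbl))
  for (r in seq_len(nrow(res_tbl))) {
    ch <- res_tbl$chain[r]; rn <- res_tbl$resno[r]
    N <- get_atom(ch, rn, "N"); CA <- get_atom(ch, rn, "CA")
    C <- get_atom(ch, rn, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) {
      stop("missing backbone atom in residue ", ch, " ", rn)
    }
    prev_c <- get_atom(ch, rn - 1, "C")
    next_n <- get_atom(ch, rn + 1, "N")
    next_ca <- get_atom(ch, rn + 1, "CA")
    phi <- if (!is.null(prev_c)) dihedral_angle(prev_c, N, CA, C) else NA_real_
    psi <- if (!is.null(next_n)) dihedral_angle(N, CA, C, next_n) else NA_real_
    ome <- if (!is.null(next_n) && !is.null(next_ca)) {
      dihedral_angle(CA, C, next_n, next_ca)
    } else NA_real_
    tors[[r]] <- tibble::tibble(
      chain = ch, resno = rn, resname = res_tbl$resname[r],
      register = res_tbl$register[r], phi = phi, psi = psi, omega = ome
    )
  }
  tors <- dplyr::bind_rows(tors)
  tors$region <- vapply(seq_len(nrow(tors)), function(i) {
    classify_region(tors$phi[i], tors$psi[i])
  }, character(1))
  tors$allowed <- is.na(tors$region) | tors$region != "other" |
    tors$resname == "GLY"

  clashes <- model_clashes(model, cutoff = clash_cutoff)
  dims <- model_dimensions(model)
  coils <- sort(unique(stats::na.omit(model$coil)))
  rise <- if (length(coils) >= 2) {
    zc <- vapply(coils, function(k) {
      mean(model$z[model$atom == "CA" & model$coil == k &
                     model$chain == model$chain[1]])
    }, numeric(1))
    mean(diff(zc))
  } else NA_real_
  strand <- tors[!is.na(tors$register) &
                   tors$register %in% c(5:8, 13:16), ]
  strand_beta <- strand$region %in% c("beta", "ppii") | is.na(strand$phi) |
    is.na(strand$psi)
  structure(
    list(torsions = tors, clashes = clashes, dimensions = dims,
         rise_per_coil = rise,
         passes = nrow(clashes) == 0 && all(strand_beta)),
    class = "geometry_report"
  )
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("<geometry_report> ", nrow(x$torsions), " residues, ",
      nrow(x$clashes), " clash(es); dimensions ",
      paste(round(as.numeric(x$dimensions), 1), collapse = " x "),
      " A; rise/coil ", round(x$rise_per_coil, 2), " A; ",
      if (x$passes) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' @export
glance.geometry_report <- function(x, ...) {
  tibble::tibble(
    n_residues = nrow(x$torsions),
    n_clashes = nrow(x$clashes),
    frac_allowed = mean(x$torsions$allowed),
    length = x$dimensions$length,
    width = x$dimensions$width,
    thickness = x$dimensions$thickness,
    rise_per_coil = x$rise_per_coil,
    passes = x$passes
  )
}
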