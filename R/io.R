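#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file (single or multi-record).
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  ss <- Biostrings::readAAStringSet(path)
  tibble::tibble(id = sub("\\s.*$", "", names(ss)),
                 sequence = unname(as.character(ss)))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Tibble with `id` and `sequence` columns (or a named
#'   character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("writing FASTA requires the Biostrings package")
  }
  if (is.character(sequences)) {
    sequences <- tibble::tibble(
      id = names(sequences) %||% paste0("seq", seq_along(sequences)),
      sequence = unname(sequences)
    )
  }
  ss <- Biostrings::AAStringSet(sequences$sequence)
  names(ss) <- sequences$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

ELEMENT_FROM_ATOM <- function(atom) {
  substr(gsub("[0-9']", "", atom), 1, 1)
}

#' Read a PDB file as a structure model or water trajectory
#'
#' Single-model files become an `inp_model` atom tibble (waters included as
#' HOH rows); files with MODEL/ENDMDL records become a `water_trajectory`
#' with HOH oxygens split out as the water set of each frame.
#'
#' @param path Path to a PDB file.
#' @return An `inp_model` or a `water_trajectory`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms in ", path)
  n_models <- nrow(pdb$xyz)
  is_water <- at$resid %in% c("HOH", "WAT", "SOL")
  if (is.na(n_models) || n_models <= 1) {
    out <- tibble::tibble(
      chain = ifelse(is.na(at$chain), "A", at$chain),
      resno = at$resno,
      resname = at$resid,
      atom = at$elety,
      element = ELEMENT_FROM_ATOM(at$elety),
      x = at$x, y = at$y, z = at$z,
      register = NA_integer_, coil = NA_integer_
    )
    if (!any(!is_water)) {
      warning("file contains only waters; returning a model with no protein")
    }
    return(new_inp_model(out))
  }
  prot_idx <- which(!is_water)
  wat_idx <- which(is_water & at$elety == "O")
  if (length(prot_idx) == 0) {
    warning("trajectory contains only waters")
  }
  roster <- tibble::tibble(
    chain = ifelse(is.na(at$chain[prot_idx]), "A", at$chain[prot_idx]),
    resno = at$resno[prot_idx],
    resname = at$resid[prot_idx],
    atom = at$elety[prot_idx]
  )
  protein <- vector("list", n_models)
  waters <- vector("list", n_models)
  for (f in seq_len(n_models)) {
    m <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    protein[[f]] <- m[prot_idx, , drop = FALSE]
    waters[[f]] <- m[wat_idx, , drop = FALSE]
  }
  new_water_trajectory(roster, protein, waters)
}

#' Write a structure model or trajectory to a PDB file
#'
#' @param x An `inp_model` atom tibble or a `water_trajectory` (written as
#'   a multi-model PDB with waters as HOH oxygens).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "water_trajectory")) {
    return(write_trajectory_pdb(x, path))
  }
  stopifnot(is.data.frame(x), all(c("chain", "resno", "resname", "atom",
                                    "x", "y", "z") %in% names(x)))
  xyz <- as.vector(t(model_xyz(x)))
  n <- nrow(x)
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = x$resno, resid = x$resname, chain = x$chain,
                   eleno = seq_len(n), elety = x$atom,
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  roster <- traj$roster
  fmt <- function(serial, name, resn, chain, resno, xyz) {
    # fixed PDB columns: serial 7-11, name 13-16, resName 18-20, chain 22,
    # resSeq 23-26, coordinates 31-54
    sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, substr(name, 1, 3), resn, chain, resno,
            xyz[1], xyz[2], xyz[3])
  }
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    prot <- traj$protein[[f]]
    for (i in seq_len(nrow(roster))) {
      serial <- serial + 1L
      writeLines(fmt(serial, roster$atom[i], roster$resname[i],
                     roster$chain[i], roster$resno[i], prot[i, ]), con)
    }
    w <- traj$waters[[f]]
    if (nrow(w) > 0) {
      for (i in seq_len(nrow(w))) {
        serial <- serial + 1L
        writeLines(fmt(serial, "O", "HOH", "W", i, w[i, ]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a density map in CCP4/MRC format
#'
#' Writes an MRC2014 (mode 2, 32-bit float) volume with the voxel spacing
#' in the cell parameters and the world origin in the MRC origin fields, so
#' standard viewers superpose the map on PDB coordinates written from the
#' same frames.
#'
#' @param grid A `density_grid`.
#' @param path Output path (conventionally `.mrc` or `.map`).
#' @return `path`, invisibly.
#' @export
write_density_map <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- dim(grid$values)
  if (any(d > 4000)) stop("grid too large for the MRC header limits")
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- grid$values
  wi(d)                      # NX NY NZ   (columns, rows, sections)
  wi(2)                      # MODE 2 = float32
  wi(c(0, 0, 0))             # NXSTART..
  wi(d)                      # MX MY MZ
  wf(d * grid$spacing)       # CELLA
  wf(c(90, 90, 90))          # CELLB
  wi(c(1, 2, 3))             # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(1)                      # ISPG
  wi(0)                      # NSYMBT
  wi(rep(0, 25))             # EXTRA (words 25-49)
  wf(grid$origin)            # ORIGIN (words 50-52, MRC2014 convention)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.vector(v)))                       # RMS
  wi(1)                      # NLABL
  lab <- sprintf("water probability map, spacing %.3f A", grid$spacing)
  writeChar(formatC(lab, width = 80, flag = "-"), con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 720), collapse = ""), con, nchars = 720, eos = NULL)
  stopifnot(seek(con, where = NA) == 1024)
  writeBin(as.numeric(as.vector(v)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a CCP4/MRC density map written by [write_density_map()]
#'
#' @param path Path to an MRC file.
#' @return A `density_grid` with `origin`, `spacing` and `values` (map
#'   statistics are recomputed over the whole box; no mask is available).
#' @export
read_density_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode: ", mode)
  ri(3)              # NXSTART
  m <- ri(3)         # MX MY MZ
  cella <- rf(3)
  rf(3); ri(3); rf(3); ri(1)
  nsymbt <- ri(1)
  ri(25)
  origin <- rf(3)
  seek(con, 1024 + nsymbt)
  v <- rf(prod(d))
  dim(v) <- d
  spacing <- cella[1] / m[1]
  structure(
    list(origin = origin, spacing = spacing, values = v,
         map_mean = mean(v), map_sd = stats::sd(as.vector(v)),
         mask = NULL, n_observations = NA_integer_,
         observations = matrix(numeric(0), 0, 3), obs_frame = integer(0),
         n_frames = NA_integer_, params = NULL),
    class = "density_grid"
  )
}

#' Write a repeat report as CSV
#'
#' One row per repeat with its span, identity and the four tetra-peptide
#' motifs (motifs are filled in if absent).
#'
#' @param annotation A `repeat_annotation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_repeat_report <- function(annotation, path) {
  if (!"turn_gygs" %in% names(annotation)) {
    annotation <- segment_motifs(annotation)
  }
  readr::write_csv(tibble::as_tibble(annotation), path)
  invisible(path)
}

#' Write water sites as CSV and/or PDB
#'
#' @param sites A `water_sites` tibble.
#' @param csv,pdb Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_sites <- function(sites, csv = NULL, pdb = NULL) {
  out <- character(0)
  if (!is.null(csv)) {
    readr::write_csv(tibble::as_tibble(sites), csv)
    out <- c(out, csv)
  }
  if (!is.null(pdb)) {
    n <- nrow(sites)
    xyz <- as.vector(t(as.matrix(sites[, c("x", "y", "z")])))
    bio3d::write.pdb(file = pdb, xyz = xyz, type = rep("HETATM", n),
                     resno = seq_len(n), resid = rep("HOH", n),
                     chain = rep("W", n), eleno = seq_len(n),
                     elety = rep("O", n), o = rep(1, n),
                     b = sites$sigma %||% rep(0, n))
    out <- c(out, pdb)
  }
  invisible(out)
}
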