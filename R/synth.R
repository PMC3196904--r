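#' Generate an INP-like tandem repeat sequence with known ground truth
#'
#' Tiles the 16-residue consensus `n_repeats` times and applies independent
#' per-position substitutions. Ladder anchor positions (the tyrosine,
#' glutamine and serine ladder registers 2, 6 and 12) are substituted at
#' their own, typically much lower, rate — these residues are the most
#' conserved positions of natural INP arrays. Alternatively a per-position
#' residue frequency profile can be planted (for example threonine present
#' 87% of the time at TxTA position 1).
#'
#' @param n_repeats Number of complete repeats to generate.
#' @param consensus A [consensus_repeat()] giving the repeat pattern.
#' @param substitution_rate Per-position substitution probability at
#'   non-anchor positions, in `[0, 1)`.
#' @param anchor_substitution_rate Substitution probability at the three
#'   ladder anchor registers (2, 6, 12).
#' @param profile Optional tibble/data frame with columns `position`
#'   (1-16), `residue`, `frequency`: at each listed position the residue is
#'   drawn as `residue` with the given probability and uniformly from the
#'   other 19 amino acids otherwise (overrides the rate model there).
#' @param fill Concrete 16-residue template used for wildcard positions;
#'   the default expands `GYGSTxTAxxxSxLxA` to the canonical
#'   `GYGSTQTAGEGSSLTA` block.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List with `sequence` (string) and `truth`, a `sequence_truth`
#'   list holding the true repeat `spans`, the substitution `events`, the
#'   planted `profile` and all parameters.
#' @export
#' @examples
#' g <- generate_inp_sequence(8, substitution_rate = 0, seed = 1)
#' g$sequence
generate_inp_sequence <- function(n_repeats,
                                  consensus = consensus_repeat(),
                                  substitution_rate = 0.15,
                                  anchor_substitution_rate = 0.05,
                                  profile = NULL,
                                  fill = "GYGSTQTAGEGSSLTA",
                                  seed = 1L) {
  stopifnot(n_repeats >= 1)
  if (substitution_rate < 0 || substitution_rate >= 1) {
    stop("substitution_rate must be in [0, 1)")
  }
  if (anchor_substitution_rate < 0 || anchor_substitution_rate >= 1) {
    stop("anchor_substitution_rate must be in [0, 1)")
  }
  if (nchar(fill) != 16) stop("fill template must have 16 residues")
  cons <- strsplit(consensus$pattern, "")[[1]]
  fill_chars <- strsplit(toupper(fill), "")[[1]]
  base <- ifelse(cons == "x", fill_chars, cons)
  anchors <- c(2L, 6L, 12L)

  prof <- NULL
  if (!is.null(profile)) {
    profile <- tibble::as_tibble(profile)
    stopifnot(all(c("position", "residue", "frequency") %in% names(profile)))
    prof <- profile
  }

  withr_seed(seed, {
    events <- list()
    rows <- character(n_repeats)
    for (k in seq_len(n_repeats)) {
      chars <- base
      for (p in 1:16) {
        if (!is.null(prof) && p %in% prof$position) {
          row <- prof[prof$position == p, ][1, ]
          if (stats::runif(1) <= row$frequency) {
            chars[p] <- row$residue
          } else {
            chars[p] <- sample(setdiff(AA_ALPHABET, row$residue), 1)
          }
          if (chars[p] != base[p]) {
            events[[length(events) + 1]] <- c(k, p, base[p], chars[p])
          }
          next
        }
        rate <- if (p %in% anchors) anchor_substitution_rate else substitution_rate
        if (rate > 0 && stats::runif(1) < rate) {
          chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
          events[[length(events) + 1]] <- c(k, p, base[p], chars[p])
        }
      }
      rows[k] <- paste(chars, collapse = "")
    }
    sequence <- paste(rows, collapse = "")
    ev <- if (length(events)) {
      m <- do.call(rbind, events)
      tibble::tibble(repeat_index = as.integer(m[, 1]),
                     position = as.integer(m[, 2]),
                     from = m[, 3], to = m[, 4])
    } else {
      tibble::tibble(repeat_index = integer(), position = integer(),
                     from = character(), to = character())
    }
    truth <- structure(
      list(
        spans = tibble::tibble(repeat_index = seq_len(n_repeats),
                               start = (seq_len(n_repeats) - 1L) * 16L + 1L,
                               end = seq_len(n_repeats) * 16L),
        events = ev,
        profile = prof,
        params = list(n_repeats = n_repeats, consensus = consensus$pattern,
                      substitution_rate = substitution_rate,
                      anchor_substitution_rate = anchor_substitution_rate,
                      fill = fill, seed = as.integer(seed))
      ),
      class = "sequence_truth"
    )
    list(sequence = sequence, truth = truth)
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Plant a prism-plane water net along an ice-nucleating face
#'
#' Places the oxygen net of the ice Ih primary prism plane parallel to the
#' named face of a built model at a fixed standoff, clipped to the face
#' footprint. These positions serve as ground-truth ordered-water sites for
#' synthetic trajectories.
#'
#' @param model A built structure model (see [build_helix()]).
#' @param face `"TQTA"` (the +x face) or `"SLTA"` (the -x face).
#' @param lattice_params Ice lattice parameters.
#' @param standoff Distance from the outermost face heavy atom to the water
#'   layer, in Angstroms.
#' @param margin Extra clip margin around the face footprint (Angstroms).
#' @return Tibble of site coordinates with attributes `spacings` and
#'   `face`.
#' @export
generate_ordered_waters <- function(model, face = c("TQTA", "SLTA"),
                                    lattice_params = ice_lattice_params(),
                                    standoff = 2.8, margin = 1.0) {
  face <- match.arg(face)
  stopifnot(inherits(model, "inp_model"))
  strand_regs <- if (face == "TQTA") 5:8 else 13:16
  fa <- model[model$register %in% strand_regs & model$chain == model$chain[1], ]
  if (nrow(fa) == 0) stop("model carries no register annotation for face ", face)
  sgn <- if (face == "TQTA") 1 else -1
  face_x <- if (sgn > 0) max(fa$x) else min(fa$x)

  # net from the prism-plane slice, one atom layer
  span_y <- range(fa$y) + c(-margin, margin)
  span_z <- range(fa$z) + c(-margin, margin)
  lat <- build_ice_lattice(ice_lattice_params(
    d_oo = lattice_params$d_oo,
    extents = c(1L,
                max(2L, ceiling(diff(span_y) / (sqrt(8 / 3) * lattice_params$d_oo)) + 2L),
                max(2L, ceiling(diff(span_z) / ((8 / 3) * lattice_params$d_oo)) + 2L))
  ))
  net <- plane_slice(lat, "primary_prism", thickness = 1.0)$waters
  # flatten to a single plane and anchor to the face
  net$x <- face_x + sgn * standoff
  net$y <- net$y - min(net$y) + span_y[1]
  net$z <- net$z - min(net$z) + span_z[1]
  keep <- net$y >= span_y[1] & net$y <= span_y[2] &
    net$z >= span_z[1] & net$z <= span_z[2]
  out <- tibble::as_tibble(net[keep, c("x", "y", "z")])
  attr(out, "spacings") <- c(short = lat$a, long = lat$c)
  attr(out, "face") <- face
  out
}

#' Generate a synthetic hydrated trajectory around a model
#'
#' Emulates the statistical structure of a solvated MD trajectory: every
#' frame holds the protein atoms under isotropic Gaussian jitter, the
#' planted ordered-water sites each present with a per-frame Bernoulli
#' occupancy and their own positional jitter, and bulk waters drawn
#' uniformly over the box with a hard-core exclusion (2.4 A) against
#' protein and planted waters. Frames are seeded from per-frame substreams
#' drawn once from the master seed, so extending `n_frames` never reshuffles
#' earlier frames.
#'
#' @param model A built structure model.
#' @param n_frames Number of frames (the reference protocol extracts 100
#'   coordinate sets per simulation).
#' @param protein_jitter Per-atom isotropic Gaussian sd, Angstroms.
#' @param planted_sites Tibble/matrix of ordered-water site coordinates
#'   (e.g. from [generate_ordered_waters()]); may be `NULL` for bulk-only.
#' @param occupancy Per-frame Bernoulli occupancy of each planted site.
#' @param site_jitter Positional jitter sd of planted waters, Angstroms.
#' @param n_bulk_waters Bulk (disordered) waters per frame.
#' @param box_padding Padding of the rectangular box around the protein,
#'   Angstroms.
#' @param frame_interval Metadata: time between frames in ps.
#' @param seed Master seed.
#' @return List with `trajectory` (a `water_trajectory`) and `truth` (a
#'   `trajectory_truth` list).
#' @export
generate_trajectory <- function(model, n_frames = 100, protein_jitter = 0.3,
                                planted_sites = NULL, occupancy = 0.8,
                                site_jitter = 0.25, n_bulk_waters = 2000,
                                box_padding = 10, frame_interval = 20,
                                seed = 1L) {
  stopifnot(inherits(model, "inp_model"), n_frames >= 1)
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  if (protein_jitter < 0 || site_jitter < 0) stop("jitters must be >= 0")
  pxyz <- as.matrix(model[, c("x", "y", "z")])
  sites <- if (is.null(planted_sites)) {
    matrix(numeric(0), 0, 3)
  } else {
    site_matrix(planted_sites)
  }
  lo <- apply(pxyz, 2, min) - box_padding
  hi <- apply(pxyz, 2, max) + box_padding
  box_vol <- prod(hi - lo)
  # crude capacity check for the hard-core constraint
  excluded <- (nrow(pxyz) + nrow(sites)) * (4 / 3) * pi * 2.4^3
  if (n_bulk_waters * 8 > box_vol - excluded) {
    stop("box too small to place ", n_bulk_waters,
         " bulk waters at the 2.4 A hard-core constraint")
  }
  frame_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, n_frames))
  frames_protein <- vector("list", n_frames)
  frames_water <- vector("list", n_frames)
  site_present <- matrix(FALSE, n_frames, nrow(sites))
  for (f in seq_len(n_frames)) {
    withr_seed(frame_seeds[f], {
      prot <- pxyz + matrix(stats::rnorm(length(pxyz), 0, protein_jitter),
                            nrow(pxyz), 3)
      planted <- matrix(numeric(0), 0, 3)
      if (nrow(sites) > 0) {
        present <- stats::runif(nrow(sites)) <= occupancy
        site_present[f, ] <- present
        if (any(present)) {
          planted <- sites[present, , drop = FALSE] +
            matrix(stats::rnorm(3 * sum(present), 0, site_jitter),
                   sum(present), 3)
        }
      }
      hard <- rbind(prot, planted)
      bulk <- matrix(numeric(0), 0, 3)
      tries <- 0L
      while (nrow(bulk) < n_bulk_waters) {
        tries <- tries + 1L
        if (tries > 200L) {
          stop("could not place bulk waters at the hard-core constraint")
        }
        need <- n_bulk_waters - nrow(bulk)
        cand <- cbind(stats::runif(2 * need, lo[1], hi[1]),
                      stats::runif(2 * need, lo[2], hi[2]),
                      stats::runif(2 * need, lo[3], hi[3]))
        ok <- cpp_min_dist(cand, hard) >= 2.4
        cand <- cand[ok, , drop = FALSE]
        if (nrow(cand) > need) cand <- cand[seq_len(need), , drop = FALSE]
        bulk <- rbind(bulk, cand)
      }
      frames_protein[[f]] <- prot
      frames_water[[f]] <- rbind(planted, bulk)
    })
  }
  traj <- new_water_trajectory(
    roster = tibble::as_tibble(model[, c("chain", "resno", "resname", "atom")]),
    protein = frames_protein, waters = frames_water,
    frame_interval = frame_interval
  )
  truth <- structure(
    list(sites = tibble::tibble(x = sites[, 1], y = sites[, 2], z = sites[, 3]),
         site_present = site_present,
         occupancy = occupancy, site_jitter = site_jitter,
         protein_jitter = protein_jitter, n_bulk_waters = n_bulk_waters,
         box = rbind(lo = lo, hi = hi), seed = as.integer(seed),
         frame_seeds = frame_seeds),
    class = "trajectory_truth"
  )
  list(trajectory = traj, truth = truth)
}
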