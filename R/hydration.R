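#' Water trajectory container
#'
#' Ordered frames of protein coordinates plus water oxygen positions sharing
#' a fixed protein atom roster.
#'
#' @param roster Tibble describing the protein atoms (chain, resno,
#'   resname, atom), one row per atom, shared by all frames.
#' @param protein List of n_atoms x 3 coordinate matrices, one per frame.
#' @param waters List of k_f x 3 water-oxygen coordinate matrices.
#' @param frame_interval Time between frames in ps (metadata only).
#' @return A `water_trajectory` object.
#' @export
new_water_trajectory <- function(roster, protein, waters, frame_interval = 20) {
  stopifnot(length(protein) == length(waters), length(protein) >= 1)
  n_atoms <- nrow(roster)
  ok <- vapply(protein, function(m) nrow(m) == n_atoms, logical(1))
  if (!all(ok)) stop("all frames must share the protein atom roster")
  structure(
    list(roster = roster, protein = protein, waters = waters,
         frame_interval = frame_interval, n_frames = length(protein)),
    class = "water_trajectory"
  )
}

#' @export
print.water_trajectory <- function(x, ...) {
  nw <- vapply(x$waters, nrow, integer(1))
  cat("<water_trajectory> ", x$n_frames, " frames, ", nrow(x$roster),
      " protein atoms, ", round(mean(nw)), " waters/frame (",
      x$frame_interval, " ps interval)\n", sep = "")
  invisible(x)
}

#' Superimpose trajectory frames on a reference by their C-alpha atoms
#'
#' Each frame is rigidly transformed to minimise the C-alpha RMSD against
#' the reference frame (least-squares Kabsch fit); waters move with their
#' frame. Already-aligned trajectories are unchanged (the fit is the
#' identity).
#'
#' @param traj A `water_trajectory`.
#' @param reference_frame Index of the frame used as the reference.
#' @return The superimposed `water_trajectory`, with a `ca_rmsd` attribute
#'   giving the per-frame C-alpha RMSD after fitting.
#' @export
superimpose_frames <- function(traj, reference_frame = 1L) {
  stopifnot(inherits(traj, "water_trajectory"))
  ca_idx <- which(traj$roster$atom == "CA")
  if (length(ca_idx) < 3) {
    stop("need at least 3 C-alpha atoms for a rigid superposition")
  }
  ref <- traj$protein[[reference_frame]][ca_idx, , drop = FALSE]
  rmsds <- numeric(traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    fit <- kabsch(traj$protein[[f]][ca_idx, , drop = FALSE], ref)
    traj$protein[[f]] <- apply_rigid(traj$protein[[f]], fit$rotation,
                                     fit$translation)
    if (nrow(traj$waters[[f]]) > 0) {
      traj$waters[[f]] <- apply_rigid(traj$waters[[f]], fit$rotation,
                                      fit$translation)
    }
    rmsds[f] <- fit$rmsd
  }
  attr(traj, "ca_rmsd") <- rmsds
  attr(traj, "superimposed") <- TRUE
  traj
}

#' Parameters for water-density accumulation
#'
#' @param shell_radius Only waters within this distance (Angstroms) of any
#'   protein atom contribute to, and define, the map region.
#' @param grid_spacing Voxel edge, Angstroms.
#' @param resolution Full width at half maximum of the Gaussian smearing
#'   kernel, Angstroms; stands in for the crystallographic map resolution.
#' @param sigma_threshold Default contour level, in standard deviations
#'   above the map mean, used for site picking.
#' @param sigma_domain Where the map mean/sd are computed: over the shell
#'   mask (`"shell"`, default) or the whole box (`"box"`).
#' @return A `density_params` list.
#' @export
density_params <- function(shell_radius = 10, grid_spacing = 0.33,
                           resolution = 1.0, sigma_threshold = 6,
                           sigma_domain = c("shell", "box")) {
  sigma_domain <- match.arg(sigma_domain)
  stopifnot(shell_radius > 0, grid_spacing > 0, resolution > 0)
  if (grid_spacing >= resolution) {
    stop("grid_spacing must be smaller than the resolution")
  }
  structure(list(shell_radius = shell_radius, grid_spacing = grid_spacing,
                 resolution = resolution, sigma_threshold = sigma_threshold,
                 sigma_domain = sigma_domain),
            class = "density_params")
}

#' Accumulate a water-probability density map from a trajectory
#'
#' For every frame, water oxygens within `shell_radius` of any protein atom
#' deposit a normalized 3D Gaussian of FWHM `resolution` onto a regular
#' grid. The grid covers the shell with at least one resolution width of
#' padding. Map mean and standard deviation are computed over the shell
#' mask (or the whole box, per `sigma_domain`); the total integral of the
#' map equals the number of contributing water observations up to kernel
#' truncation (<0.5%).
#'
#' @param traj A superimposed `water_trajectory` (see
#'   [superimpose_frames()]).
#' @param params A [density_params()] object.
#' @return A `density_grid`: list with `origin`, `spacing`, `values` (3D
#'   array), `map_mean`, `map_sd`, `mask` (logical 3D array),
#'   `n_observations`, plus the shell water observations used
#'   (`observations`, `obs_frame`) for site support counting.
#' @export
accumulate_density <- function(traj, params = density_params()) {
  stopifnot(inherits(traj, "water_trajectory"),
            inherits(params, "density_params"))
  if (!isTRUE(attr(traj, "superimposed"))) {
    warning("trajectory does not appear to be superimposed; ",
            "call superimpose_frames() first")
  }
  prot_all <- do.call(rbind, traj$protein)
  sigma <- params$resolution / (2 * sqrt(2 * log(2)))
  pad <- params$shell_radius + max(params$resolution, 4 * sigma)
  lo <- apply(prot_all, 2, min) - pad
  hi <- apply(prot_all, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / params$grid_spacing)) + 1L
  origin <- lo

  obs <- list()
  obs_frame <- list()
  for (f in seq_len(traj$n_frames)) {
    w <- traj$waters[[f]]
    if (nrow(w) == 0) next
    keep <- cpp_min_dist(w, traj$protein[[f]]) <= params$shell_radius
    if (!any(keep)) next
    obs[[length(obs) + 1]] <- w[keep, , drop = FALSE]
    obs_frame[[length(obs_frame) + 1]] <- rep.int(f, sum(keep))
  }
  observations <- if (length(obs)) do.call(rbind, obs) else matrix(numeric(0), 0, 3)
  if (nrow(observations) == 0) {
    warning("no waters found inside the shell in any frame")
  }
  values <- cpp_accumulate_gaussian(dims, origin, params$grid_spacing,
                                    observations, sigma, cutoff = 4)
  dim(values) <- dims
  mask <- cpp_shell_mask(dims, origin, params$grid_spacing,
                         traj$protein[[1]], params$shell_radius)
  dim(mask) <- dims
  dom <- if (params$sigma_domain == "shell") values[mask] else as.vector(values)
  structure(
    list(origin = origin, spacing = params$grid_spacing, values = values,
         map_mean = mean(dom), map_sd = stats::sd(dom), mask = mask,
         n_observations = nrow(observations),
         observations = observations,
         obs_frame = if (length(obs_frame)) unlist(obs_frame) else integer(0),
         n_frames = traj$n_frames,
         params = params),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", x$spacing, " A, ", x$n_observations,
      " water observations; map mean ", signif(x$map_mean, 3), ", sd ",
      signif(x$map_sd, 3), "\n", sep = "")
  invisible(x)
}

#' Pick ordered-water sites from a density map
#'
#' Finds local maxima over the 26-voxel neighbourhood with peak height at
#' least `sigma_threshold` standard deviations above the map mean, merges
#' maxima closer than 1.2 A (keeping the higher peak), and refines each
#' position by per-axis parabolic interpolation. Sites are returned sorted
#' by decreasing peak sigma.
#'
#' @param grid A `density_grid` from [accumulate_density()].
#' @param sigma_threshold Contour level in map standard deviations.
#' @param merge_radius Minimum separation between reported sites (A).
#' @return A `water_sites` tibble: `x`, `y`, `z`, `sigma`, `support`
#'   (number of frames with a shell water within 1.2 A of the site).
#' @export
peak_sites <- function(grid, sigma_threshold = NULL, merge_radius = 1.2) {
  stopifnot(inherits(grid, "density_grid"))
  sigma_threshold <- sigma_threshold %||% grid$params$sigma_threshold
  if (!is.finite(grid$map_sd) || grid$map_sd <= 0) {
    stop("degenerate density map: standard deviation is zero")
  }
  v <- grid$values
  d <- dim(v)
  thr <- grid$map_mean + sigma_threshold * grid$map_sd
  cand <- which(v >= thr)
  if (length(cand) == 0) return(empty_sites())
  ijk <- arrayInd(cand, d)
  # drop candidates on the boundary (no full neighbourhood)
  inner <- ijk[, 1] > 1 & ijk[, 1] < d[1] & ijk[, 2] > 1 & ijk[, 2] < d[2] &
    ijk[, 3] > 1 & ijk[, 3] < d[3]
  ijk <- ijk[inner, , drop = FALSE]
  if (nrow(ijk) == 0) return(empty_sites())
  keep <- vapply(seq_len(nrow(ijk)), function(r) {
    i <- ijk[r, 1]; j <- ijk[r, 2]; k <- ijk[r, 3]
    nb <- v[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
    v[i, j, k] >= max(nb)
  }, logical(1))
  ijk <- ijk[keep, , drop = FALSE]
  if (nrow(ijk) == 0) return(empty_sites())

  # parabolic refinement along each axis
  refine <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (den >= 0) return(0)           # not a proper maximum along this axis
    max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
  }
  pos <- t(vapply(seq_len(nrow(ijk)), function(r) {
    i <- ijk[r, 1]; j <- ijk[r, 2]; k <- ijk[r, 3]
    dx <- refine(v[i - 1, j, k], v[i, j, k], v[i + 1, j, k])
    dy <- refine(v[i, j - 1, k], v[i, j, k], v[i, j + 1, k])
    dz <- refine(v[i, j, k - 1], v[i, j, k], v[i, j, k + 1])
    grid$origin + (c(i, j, k) - 1 + c(dx, dy, dz)) * grid$spacing
  }, numeric(3)))
  peak_sigma <- (v[ijk] - grid$map_mean) / grid$map_sd

  # merge close peaks, keeping the higher; ties by sigma then position
  ord <- order(-peak_sigma, pos[, 1], pos[, 2], pos[, 3])
  pos <- pos[ord, , drop = FALSE]; peak_sigma <- peak_sigma[ord]
  taken <- logical(nrow(pos))
  sel <- integer(0)
  for (r in seq_len(nrow(pos))) {
    if (taken[r]) next
    sel <- c(sel, r)
    if (r < nrow(pos)) {
      rest <- (r + 1):nrow(pos)
      dd <- sqrt(rowSums((pos[rest, , drop = FALSE] -
                            matrix(pos[r, ], length(rest), 3, byrow = TRUE))^2))
      taken[rest[dd < merge_radius]] <- TRUE
    }
  }
  pos <- pos[sel, , drop = FALSE]; peak_sigma <- peak_sigma[sel]
  support <- if (nrow(grid$observations) > 0) {
    as.integer(cpp_site_support(pos, grid$observations, grid$obs_frame,
                                grid$n_frames, 1.2))
  } else {
    rep.int(0L, nrow(pos))
  }
  out <- tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        sigma = peak_sigma, support = support)
  class(out) <- c("water_sites", class(out))
  out
}

empty_sites <- function() {
  out <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                        sigma = numeric(), support = integer())
  class(out) <- c("water_sites", class(out))
  out
}
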