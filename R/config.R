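#' Default pipeline configuration
#'
#' A single validated document collecting the defaults of every stage:
#' repeat detection, helix building, dimer assembly, synthetic trajectory
#' generation, density mapping, lattice registration and the surface-area
#' model. Unknown keys are rejected on validation.
#'
#' @return A named list of sections (`pipeline_config`).
#' @export
default_config <- function() {
  structure(list(
    repeats = list(consensus = "GYGSTxTAxxxSxLxA", min_identity = 0.5,
                   superperiod = 3L),
    builder = list(handedness = "right", rise_per_coil = 4.8,
                   strand_ca_step = 3.37, sidechain_mode = "cbeta_only"),
    dimer = list(mode = "parallel", interface_gap = 3.5, offset_coils = 0L),
    synthesis = list(n_repeats = 8L, substitution_rate = 0.15,
                     anchor_substitution_rate = 0.05,
                     n_frames = 100L, protein_jitter = 0.3,
                     occupancy = 0.8, site_jitter = 0.25,
                     n_bulk_waters = 2000L, box_padding = 10,
                     standoff = 2.8, face = "TQTA"),
    density = list(shell_radius = 10, grid_spacing = 0.33, resolution = 1.0,
                   sigma_threshold = 6, sigma_domain = "shell"),
    lattice = list(d_oo = 2.76, plane = "primary_prism", thickness = 1.0,
                   max_pair_distance = 1.5),
    area = list(n_repeats_full = 64L, per_coil_rise = 5.0, width = 40,
                n_faces = 2L, threshold = 20100, temperature = -12),
    seed = 1L
  ), class = "pipeline_config")
}

RANGE_CHECKS <- list(
  c("repeats", "min_identity", 0, 1),
  c("builder", "rise_per_coil", 4.5, 5.2),
  c("builder", "strand_ca_step", 3.2, 3.6),
  c("dimer", "interface_gap", 3.0, 5.0),
  c("synthesis", "occupancy", 1e-9, 1),
  c("synthesis", "substitution_rate", 0, 0.999),
  c("density", "shell_radius", 1e-9, Inf),
  c("density", "grid_spacing", 1e-9, Inf),
  c("lattice", "d_oo", 1e-9, Inf),
  c("area", "threshold", 1e-9, Inf)
)

#' Validate a pipeline configuration
#'
#' @param config A list as produced by [default_config()] or
#'   [read_config()].
#' @return The validated `pipeline_config` (invisibly on success); errors
#'   on unknown keys or out-of-range values.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in names(config)) {
    if (sec == "seed") next
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  merged <- ref
  for (sec in names(config)) {
    if (sec == "seed") { merged$seed <- config$seed; next }
    merged[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  for (chk in RANGE_CHECKS) {
    val <- merged[[chk[1]]][[chk[2]]]
    if (val < as.numeric(chk[3]) || val > as.numeric(chk[4])) {
      stop(chk[1], "$", chk[2], " = ", val, " outside [", chk[3], ", ",
           chk[4], "]")
    }
  }
  class(merged) <- "pipeline_config"
  invisible(merged)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @param config A `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full desk-scale pipeline
#'
#' Sequence generation, repeat detection, helix building, dimer assembly,
#' planted-water trajectory synthesis, frame superposition, density
#' mapping, site picking, ice-lattice registration and the surface-area
#' report, driven by one configuration. Outputs are written to `outdir`
#' (model.pdb, dimer.pdb, density.mrc, sites.csv, fit.json, area.json).
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param seed Master seed overriding `config$seed`.
#' @param outdir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param quiet Suppress progress messages.
#' @return A list with every intermediate product (annotation, model,
#'   dimer, trajectory truth, density grid, sites, registration, area
#'   report, file paths).
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         outdir = NULL, quiet = FALSE) {
  config <- validate_config(unclass(config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(...)
  say("pipeline seed: ", config$seed)

  cons <- consensus_repeat(config$repeats$consensus,
                           superperiod = config$repeats$superperiod)
  gen <- generate_inp_sequence(
    n_repeats = config$synthesis$n_repeats, consensus = cons,
    substitution_rate = config$synthesis$substitution_rate,
    anchor_substitution_rate = config$synthesis$anchor_substitution_rate,
    seed = config$seed
  )
  ann <- detect_repeats(gen$sequence, cons,
                        min_identity = config$repeats$min_identity)
  say("detected ", sum(!ann$partial), " complete repeats")
  hp <- helix_params(handedness = config$builder$handedness,
                     rise_per_coil = config$builder$rise_per_coil,
                     strand_ca_step = config$builder$strand_ca_step,
                     sidechain_mode = config$builder$sidechain_mode)
  model <- build_helix(ann, hp)
  dimer <- build_dimer(model, dimer_spec(mode = config$dimer$mode,
                                         interface_gap = config$dimer$interface_gap,
                                         offset_coils = config$dimer$offset_coils))
  sites_true <- generate_ordered_waters(
    model, face = config$synthesis$face,
    lattice_params = ice_lattice_params(d_oo = config$lattice$d_oo),
    standoff = config$synthesis$standoff
  )
  traj_gen <- generate_trajectory(
    model, n_frames = config$synthesis$n_frames,
    protein_jitter = config$synthesis$protein_jitter,
    planted_sites = sites_true, occupancy = config$synthesis$occupancy,
    site_jitter = config$synthesis$site_jitter,
    n_bulk_waters = config$synthesis$n_bulk_waters,
    box_padding = config$synthesis$box_padding, seed = config$seed
  )
  traj <- superimpose_frames(traj_gen$trajectory)
  dp <- density_params(shell_radius = config$density$shell_radius,
                       grid_spacing = config$density$grid_spacing,
                       resolution = config$density$resolution,
                       sigma_threshold = config$density$sigma_threshold,
                       sigma_domain = config$density$sigma_domain)
  grid <- accumulate_density(traj, dp)
  sites <- peak_sites(grid)
  say(nrow(sites), " ordered-water sites at sigma >= ",
      config$density$sigma_threshold)
  lat <- build_ice_lattice(ice_lattice_params(d_oo = config$lattice$d_oo,
                                              extents = c(2L, 8L, 8L)))
  net <- plane_slice(lat, config$lattice$plane, config$lattice$thickness)
  fit <- if (nrow(sites) >= 3) {
    register_sites(sites, net, config$lattice$max_pair_distance)
  } else NULL
  area_rep <- critical_area_check(
    multimer_area(n_chains = 2, offset_coils = 0,
                  n_coils = config$area$n_repeats_full,
                  per_coil_rise = config$area$per_coil_rise,
                  width = config$area$width, n_faces = config$area$n_faces),
    critical_area_threshold(config$area$threshold, config$area$temperature)
  )

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      model = file.path(outdir, "model.pdb"),
      dimer = file.path(outdir, "dimer.pdb"),
      density = file.path(outdir, "density.mrc"),
      sites = file.path(outdir, "sites.csv"),
      fit = file.path(outdir, "fit.json"),
      area = file.path(outdir, "area.json")
    )
    write_structure(model, paths$model)
    write_structure(dimer, paths$dimer)
    write_density_map(grid, paths$density)
    write_sites(sites, csv = paths$sites)
    if (!is.null(fit)) {
      jsonlite::write_json(glance(fit), paths$fit, auto_unbox = TRUE,
                           digits = NA)
    }
    jsonlite::write_json(as.list(area_rep), paths$area, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(config = config, annotation = ann, model = model,
                 dimer = dimer, truth = traj_gen$truth, grid = grid,
                 sites = sites, fit = fit, area = area_rep, paths = paths))
}
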