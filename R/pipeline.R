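# Configuration-driven orchestration: contacts -> occupancy -> free ligand
# -> saturation fit -> ddG ranking; density; exposure; simulate.
#
# Configs are JSON with strict validation (unknown keys are rejected so a
# misspelt cutoff can never silently fall back to a default).  Every report
# embeds the exact parameter values used and the package version.

.known_keys <- list(
  top = c("mode", "temperature", "seed", "outdir", "stride", "contact",
          "free_ligand_exclusion", "exposure_cutoff", "sites", "manifest",
          "species_map", "synthetic", "density", "nonspecific_band"),
  contact = c("lower", "upper"),
  synthetic = c("kind", "k_on_per_conc", "k_off", "n_residues",
                "residue_emission_prob", "concentrations", "replicates",
                "frames", "well_depths", "site_centers", "site_radii",
                "n_chol", "n_popc", "box"),
  density = c("bin_size", "site_center", "site_radius", "bulk_z_slab",
              "min_protein_distance", "selection"))

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
  }
}

#' Read and validate a run configuration
#'
#' @param path JSON config file.  Recognised top-level keys: `mode`,
#'   `temperature`, `seed`, `outdir`, `stride`, `contact` (lower/upper, nm),
#'   `free_ligand_exclusion` (nm), `exposure_cutoff` (nm), `sites`,
#'   `manifest`, `species_map`, `synthetic`, `density`, `nonspecific_band`.
#'   Unknown keys anywhere are an error.
#' @return validated config list with defaults filled in (class
#'   `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as parsed from JSON).
#' @export
validate_run_config <- function(cfg) {
  .check_keys(cfg, .known_keys$top, "config")
  cfg$temperature <- cfg$temperature %||% 310
  if (cfg$temperature <= 0) stop("temperature must be > 0")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$stride <- as.integer(cfg$stride %||% 1L)
  cfg$contact <- as.list(cfg$contact %||% list())
  .check_keys(cfg$contact, .known_keys$contact, "contact")
  cfg$contact$lower <- cfg$contact$lower %||% 0.55
  cfg$contact$upper <- cfg$contact$upper %||% 1.0
  if (cfg$contact$lower <= 0 || cfg$contact$lower > cfg$contact$upper) {
    stop("contact cutoffs must satisfy 0 < lower <= upper")
  }
  cfg$free_ligand_exclusion <- cfg$free_ligand_exclusion %||% 0.8
  cfg$exposure_cutoff <- cfg$exposure_cutoff %||% 0.6
  if (cfg$free_ligand_exclusion <= 0 || cfg$exposure_cutoff <= 0) {
    stop("cutoffs must be positive")
  }
  cfg$nonspecific_band <- cfg$nonspecific_band %||% c(30, 50)
  if (!is.null(cfg$synthetic)) {
    .check_keys(as.list(cfg$synthetic), .known_keys$synthetic, "synthetic")
  }
  if (!is.null(cfg$density)) {
    .check_keys(as.list(cfg$density), .known_keys$density, "density")
  }
  if (!is.null(cfg$manifest)) {
    mf <- cfg$manifest
    for (f in c(mf$coordinates, mf$trajectory)) {
      if (!is.null(f) && !file.exists(f)) stop("manifest file not found: ", f)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_sites <- function(cfg) {
  out <- list()
  for (s in cfg$sites) {
    s <- as.list(s)
    out[[s$site_id]] <- site_definition(s$site_id,
                                        chain = unlist(s$chain),
                                        resid = unlist(s$resid))
  }
  out
}

.run_log <- function(outdir, lines) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outdir, "run.log")
  stamp <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ")
  cat(paste0(stamp, lines, "\n"), sep = "", file = path, append = TRUE)
  message(paste(lines, collapse = "\n"))
  invisible(path)
}

#' Run the binding-saturation workflow end to end
#'
#' Either from a manifest of trajectory files or from a synthetic kinetic
#' model.  Per site the report contains the saturation points (CSV), the
#' pooled + per-replicate fits (JSON) and the all-pairs ddG table.
#'
#' @param config a `run_config` (or path to one).
#' @return invisible list with `points`, `fits`, `ddg` and output paths.
#' @export
run_saturation <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir %||% "."
  if (!is.null(config$synthetic)) {
    syn <- as.list(config$synthetic)
    concentrations <- unlist(syn$concentrations) %||% c(1, 2.5, 5, 10, 15, 30, 40)
    if (length(concentrations) < 3) stop("need >= 3 conditions (concentrations)")
    kds <- unlist(syn$k_off) / unlist(syn$k_on_per_conc)
    n_sites <- length(kds)
    site_ids <- paste0("S", seq_len(n_sites))
    points <- list(); fits <- list()
    for (i in seq_len(n_sites)) {
      model <- kinetic_site_model(
        k_on_per_conc = unlist(syn$k_on_per_conc)[i],
        k_off = unlist(syn$k_off)[i],
        n_residues = syn$n_residues %||% 6L,
        residue_emission_prob = syn$residue_emission_prob %||% 1.0)
      ds <- generate_saturation_dataset(
        model, concentrations = concentrations,
        replicates = syn$replicates %||% 5L,
        frames = syn$frames %||% 2e4L,
        base_seed = config$seed + (i - 1L) * 100000L)
      ds$points$site_id <- site_ids[i]
      points[[i]] <- ds$points
      fits[[site_ids[i]]] <- fit_saturation(ds$points)
    }
    points <- do.call(rbind, points)
  } else {
    if (is.null(config$manifest) || length(unique(config$manifest$cholesterol_percent)) < 3) {
      stop("need >= 3 conditions in the manifest")
    }
    sites <- .parse_sites(config)
    runs <- lapply(seq_len(nrow(config$manifest)), function(i) {
      row <- config$manifest[i, ]
      ld <- load_system(row$coordinates, row$trajectory,
                        species_map = config$species_map,
                        stride = config$stride)
      series <- lapply(sites, function(st) {
        residue_contact_series(ld$system, "CHOL", st$residues,
                               lower = config$contact$lower,
                               upper = config$contact$upper)
      })
      list(system = ld$system,
           condition = simulation_condition(row$cholesterol_percent,
                                            row$replicate,
                                            config$temperature),
           series_by_site = series)
    })
    tab <- occupancy_table(runs, sites, config$free_ligand_exclusion)
    points <- data.frame(x = tab$free_chol_percent, y = tab$occupancy_percent,
                         replicate = tab$replicate, condition = tab$condition,
                         site_id = tab$site_id)
    fits <- lapply(split(points, points$site_id), fit_saturation)
  }
  # ddG table over all site pairs, strong (small Kd) minus weak is negative
  ids <- names(fits)
  ddg <- NULL
  if (length(ids) >= 2) {
    pairs <- utils::combn(ids, 2)
    ddg <- data.frame(
      site_a = pairs[1, ], site_b = pairs[2, ],
      kd_a = vapply(pairs[1, ], function(i) fits[[i]]$kd_app, numeric(1)),
      kd_b = vapply(pairs[2, ], function(i) fits[[i]]$kd_app, numeric(1)))
    ddg$ddg_kj_mol <- delta_delta_g(ddg$kd_a, ddg$kd_b, config$temperature)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(points, file.path(outdir, "saturation_points.csv"),
                   row.names = FALSE, quote = FALSE)
  fit_report <- lapply(fits, function(f) {
    list(kd_app = f$kd_app, bmax_app = f$bmax_app, kd_sem = f$kd_sem,
         bmax_sem = f$bmax_sem,
         kd_per_replicate = unname(f$kd_per_replicate),
         pooled_stderrs = as.list(f$pooled$fit_stderrs),
         converged = f$pooled$converged)
  })
  report <- list(parameters = list(
    temperature = config$temperature, seed = config$seed,
    contact = config$contact,
    free_ligand_exclusion = config$free_ligand_exclusion,
    package_version = as.character(utils::packageVersion("satbind"))),
    fits = fit_report)
  jsonlite::write_json(report, file.path(outdir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(ddg)) {
    utils::write.csv(ddg, file.path(outdir, "ddg_table.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  unconv <- names(fit_report)[!vapply(fit_report, `[[`, TRUE, "converged")]
  .run_log(outdir, c(
    sprintf("run_saturation: %d site(s), %d points, seed %d",
            length(fits), nrow(points), config$seed),
    sprintf("  site %s: Kd_app = %.4g%% (SEM %.3g), Bmax_app = %.4g%%",
            names(fit_report),
            vapply(fit_report, `[[`, 0, "kd_app"),
            vapply(fit_report, function(x) x$kd_sem %||% NA_real_, 0),
            vapply(fit_report, `[[`, 0, "bmax_app")),
    if (length(unconv)) paste("WARNING: unconverged fits:",
                              paste(unconv, collapse = ", "))))
  invisible(list(points = points, fits = fits, ddg = ddg, outdir = outdir))
}

#' Run the density free-energy workflow
#'
#' Accumulates the 3D cholesterol density (after protein alignment), builds
#' site and bulk masks, reports dG per configuration and exports OpenDX
#' maps.
#'
#' @param config a `run_config` (or path); uses the `density` and either
#'   `synthetic` (spatial) or `manifest` sections.
#' @param system optional pre-built [bead_system()] (bypasses file I/O).
#' @return invisible list with `grid`, `dg_kj_mol`, paths.
#' @export
run_density <- function(config, system = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir %||% "."
  dct <- as.list(config$density %||% list())
  if (is.null(system)) {
    if (!is.null(config$synthetic)) {
      syn <- as.list(config$synthetic)
      model <- spatial_ensemble_model(
        box = unlist(syn$box) %||% c(10, 10, 10),
        site_centers = matrix(unlist(syn$site_centers), ncol = 3, byrow = TRUE),
        site_radii = unlist(syn$site_radii),
        well_depths = unlist(syn$well_depths),
        n_chol = syn$n_chol %||% 100L, n_popc = syn$n_popc %||% 100L,
        temperature = config$temperature)
      system <- simulate_snapshot_ensemble(model, frames = syn$frames %||% 500L,
                                           seed = config$seed)$system
      dct$site_center <- dct$site_center %||% model$site_centers[1, ]
      dct$site_radius <- dct$site_radius %||% (model$site_radii[1] - 0.1)
      zc <- model$box[3] / 2; h <- model$leaflet_half_thickness
      dct$bulk_z_slab <- dct$bulk_z_slab %||% c(zc - 2 * h, zc + 2 * h)
    } else {
      row <- config$manifest[1, ]
      system <- load_system(row$coordinates, row$trajectory,
                            config$species_map, config$stride)$system
      system <- align_to_protein(system)
    }
  }
  sel_species <- dct$selection %||% "CHOL"
  sel <- which(system$molecule_species[system$bead_molecule] == sel_species)
  spec <- grid_spec(c(0, 0, 0), system$box[1, ], dct$bin_size %||% 0.1)
  grid <- accumulate_density(system, sel, spec)
  site <- site_mask(grid, unlist(dct$site_center), dct$site_radius)
  bulk <- bulk_mask(grid, system, z_slab = unlist(dct$bulk_z_slab),
                    min_protein_distance = dct$min_protein_distance %||% 2.0,
                    exclude = list(site_mask(grid, unlist(dct$site_center),
                                             dct$site_radius + 0.2)))
  dg <- binding_free_energy(grid, site, bulk, config$temperature)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_opendx(grid, file.path(outdir, "density.dx"))
  jsonlite::write_json(
    list(dg_kj_mol = dg, temperature = config$temperature,
         bin_size = grid$spec$bin_size, samples = grid$samples,
         site_voxels = sum(site$mask), bulk_voxels = sum(bulk$mask)),
    file.path(outdir, "density_report.json"), auto_unbox = TRUE, digits = NA)
  .run_log(outdir, sprintf("run_density: dG = %.3f kJ/mol (%d samples)",
                           dg, grid$samples))
  invisible(list(grid = grid, dg_kj_mol = dg, outdir = outdir))
}

#' Run the membrane-exposure workflow
#'
#' @param config a `run_config` (or path).
#' @param system a [bead_system()]; when NULL, built from the config's
#'   synthetic spatial section.
#' @param site_lipid,bound_frames passed to [membrane_exposure()]; defaults
#'   track the first CHOL molecule across all frames.
#' @return invisible `exposure_result`.
#' @export
run_exposure <- function(config, system = NULL, site_lipid = NULL,
                         bound_frames = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir %||% "."
  if (is.null(system)) {
    syn <- as.list(config$synthetic)
    model <- spatial_ensemble_model(
      box = unlist(syn$box) %||% c(10, 10, 10),
      site_centers = matrix(unlist(syn$site_centers), ncol = 3, byrow = TRUE),
      site_radii = unlist(syn$site_radii),
      well_depths = unlist(syn$well_depths),
      n_chol = syn$n_chol %||% 100L, n_popc = syn$n_popc %||% 100L,
      temperature = config$temperature)
    system <- simulate_snapshot_ensemble(model, frames = syn$frames %||% 50L,
                                         seed = config$seed)$system
  }
  site_lipid <- site_lipid %||% molecules_of(system, "CHOL")[1]
  bound_frames <- bound_frames %||% seq_len(n_frames(system))
  res <- membrane_exposure(system, site_lipid, bound_frames,
                           cutoff = config$exposure_cutoff)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$per_frame, file.path(outdir, "exposure.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fraction = res$fraction,
                            frames_used = res$frames_used,
                            cutoff = config$exposure_cutoff),
                       file.path(outdir, "exposure_report.json"),
                       auto_unbox = TRUE, digits = NA)
  .run_log(outdir, sprintf("run_exposure: fraction = %.3f over %d frame(s)",
                           res$fraction, res$frames_used))
  invisible(res)
}

#' Generate and write a synthetic dataset from a config
#'
#' Spatial synthetic sections produce GRO + DCD + ground-truth JSON;
#' kinetic sections produce the saturation points CSV + ground truth.
#'
#' @param config a `run_config` (or path) with a `synthetic` section whose
#'   `kind` is "spatial" or "kinetic".
#' @return invisible list of output paths / dataset.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  syn <- as.list(config$synthetic)
  if (is.null(syn$kind)) stop("synthetic.kind must be 'spatial' or 'kinetic'")
  if (syn$kind == "spatial") {
    model <- spatial_ensemble_model(
      box = unlist(syn$box) %||% c(10, 10, 10),
      site_centers = matrix(unlist(syn$site_centers), ncol = 3, byrow = TRUE),
      site_radii = unlist(syn$site_radii),
      well_depths = unlist(syn$well_depths),
      n_chol = syn$n_chol %||% 100L, n_popc = syn$n_popc %||% 100L,
      temperature = config$temperature)
    ens <- simulate_snapshot_ensemble(model, frames = syn$frames %||% 100L,
                                      seed = config$seed)
    paths <- write_ensemble(ens, file.path(outdir, "synthetic"))
    .run_log(outdir, paste("run_simulate: wrote", paste(paths, collapse = ", ")))
    invisible(as.list(paths))
  } else if (syn$kind == "kinetic") {
    model <- kinetic_site_model(
      k_on_per_conc = syn$k_on_per_conc %||% 0.01,
      k_off = syn$k_off %||% 0.1,
      n_residues = syn$n_residues %||% 6L,
      residue_emission_prob = syn$residue_emission_prob %||% 1.0)
    ds <- generate_saturation_dataset(
      model,
      concentrations = unlist(syn$concentrations) %||% c(1, 2.5, 5, 10, 15, 30, 40),
      replicates = syn$replicates %||% 5L, frames = syn$frames %||% 2e4L,
      base_seed = config$seed)
    utils::write.csv(ds$points, file.path(outdir, "synthetic_points.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(ground_truth_kd = ds$ground_truth_kd,
                              ground_truth_bmax = ds$ground_truth_bmax),
                         file.path(outdir, "synthetic_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    .run_log(outdir, sprintf("run_simulate: kinetic dataset, Kd* = %g",
                             ds$ground_truth_kd))
    invisible(ds)
  } else {
    stop("unknown synthetic.kind: ", syn$kind)
  }
}
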