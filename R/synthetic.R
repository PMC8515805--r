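# Synthetic data with known ground truth.
#
# Two generators cover the two halves of the analysis:
#  * a two-state (empty <-> bound) Markov chain whose stationary occupancy
#    follows the Langmuir isotherm with a known Kd*, emitting per-residue
#    contact series -- validates the occupancy + saturation-fit path;
#  * an i.i.d. spatial snapshot ensemble with Boltzmann-weighted enrichment
#    of cholesterol in spherical site wells of known depth dG* around a
#    static protein proxy -- validates the density, free-ligand and
#    exposure paths.
# Time is discretised per frame (rates are per frame); snapshots carry no
# diffusion dynamics, only the equilibrium ensemble matters downstream.

#' Two-state Markov site-binding model with known Kd
#'
#' Transition probabilities per frame: empty -> bound with `k_on_per_conc *
#' L` (L = free-ligand percent), bound -> empty with `k_off`.  Stationary
#' occupancy is L / (Kd* + L) with Kd* = k_off / k_on_per_conc.  While
#' bound, each of the `n_residues` site residues independently registers a
#' contact with probability `residue_emission_prob`.
#'
#' @param k_on_per_conc association rate, 1/frame per percent free ligand.
#' @param k_off dissociation rate, 1/frame.
#' @param n_residues site size (default 6, the protocol's site size).
#' @param residue_emission_prob contact probability per residue per bound
#'   frame (default 1: every bound frame registers on every residue, so the
#'   site's ground-truth Bmax is 100%).
#' @return object of class `kinetic_site_model` with `ground_truth_kd`.
#' @export
kinetic_site_model <- function(k_on_per_conc = 0.01, k_off = 0.1,
                               n_residues = 6L,
                               residue_emission_prob = 1.0) {
  stopifnot(k_on_per_conc > 0, k_off >= 0,
            residue_emission_prob > 0, residue_emission_prob <= 1,
            n_residues >= 1)
  structure(list(k_on_per_conc = k_on_per_conc, k_off = k_off,
                 n_residues = as.integer(n_residues),
                 residue_emission_prob = residue_emission_prob,
                 ground_truth_kd = k_off / k_on_per_conc),
            class = "kinetic_site_model")
}

#' Simulate a contact series from the kinetic model
#'
#' The chain starts from its stationary distribution (bound with
#' probability L/(Kd*+L)), so finite-series occupancy is unbiased.
#'
#' @param model a [kinetic_site_model()].
#' @param free_ligand percent free ligand L.
#' @param frames series length (>= 1).
#' @param seed RNG seed (required for reproducibility).
#' @return a [contact_series()] with one lipid and `n_residues` residues
#'   labelled `"A:1" ... "A:n"`.
#' @export
simulate_contact_series <- function(model, free_ligand, frames, seed) {
  stopifnot(inherits(model, "kinetic_site_model"), frames >= 1)
  p_on <- model$k_on_per_conc * free_ligand
  p_off <- model$k_off
  if (p_on > 1 || p_off > 1) {
    stop("transition probability > 1: rates too large for the frame step")
  }
  set.seed(as.integer(seed))
  bound <- logical(frames)
  p_stat <- if (p_on + p_off > 0) p_on / (p_on + p_off) else 0
  bound[1] <- stats::runif(1) < p_stat
  u <- stats::runif(frames)
  for (f in seq_len(frames)[-1]) {
    bound[f] <- if (bound[f - 1]) u[f] >= p_off else u[f] < p_on
  }
  emit <- matrix(stats::runif(frames * model$n_residues) <
                   model$residue_emission_prob,
                 model$n_residues, frames)
  pair <- array(FALSE, c(1L, model$n_residues, frames))
  pair[1, , ] <- emit & rep(bound, each = model$n_residues)
  contact_series(pair, paste0("A:", seq_len(model$n_residues)),
                 lipid_ids = 1L)
}

#' Generate a full saturation dataset with known ground truth
#'
#' For each (concentration, replicate), a contact series is simulated under
#' a seed derived from `base_seed` by a simple counter (`base_seed +
#' counter`, counter enumerating condition x replicate in order), and the
#' site occupancy becomes the ordinate of one saturation point.  The
#' abscissa is the nominal free-ligand concentration (the kinetic model has
#' no explicit bilayer, so free = total by construction).
#'
#' @param model a [kinetic_site_model()].
#' @param concentrations percent free-ligand values (>= 3); default the
#'   seven-composition series 1, 2.5, 5, 10, 15, 30, 40 used by the
#'   protocol.
#' @param replicates number of replicates (protocol: 5).
#' @param frames frames per replicate.
#' @param base_seed integer.
#' @param keep_series store every contact series (needed for trajectory-
#'   truncation convergence scans; memory scales with frames).
#' @return list: `points` (data.frame x, y, replicate, condition),
#'   `ground_truth_kd`, `ground_truth_bmax`, `site` (a [site_definition()]),
#'   and `series` (when kept; parallel to `points` rows).
#' @export
generate_saturation_dataset <- function(model,
                                        concentrations = c(1, 2.5, 5, 10, 15, 30, 40),
                                        replicates = 5L, frames = 2e4L,
                                        base_seed = 1L,
                                        keep_series = FALSE) {
  if (length(concentrations) < 3) stop("need >= 3 concentrations")
  site <- site_definition("synthetic",
                          chain = rep("A", model$n_residues),
                          resid = seq_len(model$n_residues))
  rows <- list(); series <- list()
  counter <- 0L
  for (conc in concentrations) {
    for (r in seq_len(replicates)) {
      counter <- counter + 1L
      ser <- simulate_contact_series(model, conc, frames,
                                     seed = as.integer(base_seed) + counter)
      rows[[counter]] <- data.frame(
        x = conc, y = site_occupancy(ser, site),
        replicate = r, condition = conc)
      if (keep_series) series[[counter]] <- ser
    }
  }
  out <- list(points = do.call(rbind, rows),
              ground_truth_kd = model$ground_truth_kd,
              ground_truth_bmax = 100 * model$residue_emission_prob,
              site = site)
  if (keep_series) out$series <- series
  out
}

#' Static spatial ensemble model with Boltzmann site enrichment
#'
#' A static protein proxy (a vertical cylinder of beads spanning the
#' bilayer) sits at the box centre; cholesterol positions are drawn i.i.d.
#' per frame from the equilibrium weight exp(-U/RT), where U equals the
#' site `well_depths` (kJ/mol, <= 0 for attraction) inside spherical site
#' regions and 0 elsewhere in the leaflet slabs; POPC is uniform in the
#' slabs.  Lipids never overlap the protein cylinder.
#'
#' @param box length-3 box, nm (default 10 x 10 x 10).
#' @param protein_radius,protein_half_height cylinder geometry, nm.
#' @param site_centers matrix (n_sites x 3) of well centres, nm.
#' @param site_radii,well_depths per-site radius (nm) and depth (kJ/mol,
#'   <= 0).
#' @param n_chol,n_popc lipid counts per leaflet.
#' @param leaflet_half_thickness half-thickness of each leaflet slab, nm;
#'   slabs sit symmetrically about the box midplane.
#' @param temperature kelvin.
#' @return object of class `spatial_ensemble_model`.
#' @export
spatial_ensemble_model <- function(box = c(10, 10, 10),
                                   protein_radius = 1.0,
                                   protein_half_height = 2.0,
                                   site_centers = matrix(c(6.8, 5.0, 6.0), 1),
                                   site_radii = 0.8,
                                   well_depths = -10,
                                   n_chol = 100L, n_popc = 100L,
                                   leaflet_half_thickness = 1.0,
                                   temperature = 310) {
  site_centers <- rbind(site_centers)
  stopifnot(length(site_radii) == nrow(site_centers),
            length(well_depths) == nrow(site_centers),
            all(well_depths <= 0), n_chol > 0, n_popc > 0)
  ctr <- box / 2
  for (s in seq_len(nrow(site_centers))) {
    dxy <- sqrt(sum((site_centers[s, 1:2] - ctr[1:2])^2))
    if (dxy < protein_radius + site_radii[s] - 1e-9) {
      stop("site region ", s, " overlaps the protein proxy")
    }
    if (any(site_centers[s, ] - site_radii[s] < 0) ||
        any(site_centers[s, ] + site_radii[s] > box)) {
      stop("site region ", s, " extends outside the box")
    }
  }
  structure(list(box = box, protein_radius = protein_radius,
                 protein_half_height = protein_half_height,
                 site_centers = site_centers, site_radii = site_radii,
                 well_depths = well_depths,
                 n_chol = as.integer(n_chol), n_popc = as.integer(n_popc),
                 leaflet_half_thickness = leaflet_half_thickness,
                 temperature = temperature),
            class = "spatial_ensemble_model")
}

# Leaflet slab z-intervals (upper, lower), symmetric about the midplane.
.leaflet_slabs <- function(model) {
  zc <- model$box[3] / 2
  h <- model$leaflet_half_thickness
  rbind(c(zc, zc + 2 * h), c(zc - 2 * h, zc))
}

# Uniform point in the slabs, outside the protein cylinder and (optionally)
# outside all site spheres; vectorised rejection sampling.
.sample_bulk <- function(model, n, exclude_sites) {
  slabs <- .leaflet_slabs(model)
  ctr <- model$box / 2
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- 2L * (n - nrow(out)) + 16L
    x <- stats::runif(m, 0, model$box[1])
    y <- stats::runif(m, 0, model$box[2])
    leaf <- sample.int(2L, m, replace = TRUE)
    z <- stats::runif(m, slabs[leaf, 1], slabs[leaf, 2])
    ok <- (x - ctr[1])^2 + (y - ctr[2])^2 > model$protein_radius^2
    if (exclude_sites) {
      for (s in seq_len(nrow(model$site_centers))) {
        c_s <- model$site_centers[s, ]
        ok <- ok & ((x - c_s[1])^2 + (y - c_s[2])^2 + (z - c_s[3])^2 >
                      model$site_radii[s]^2)
      }
    }
    out <- rbind(out, cbind(x, y, z)[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Uniform point inside the part of site sphere s that lies within the slabs.
.sample_site <- function(model, s, n) {
  c_s <- model$site_centers[s, ]
  r <- model$site_radii[s]
  slabs <- .leaflet_slabs(model)
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- 3L * (n - nrow(out)) + 16L
    p <- matrix(stats::runif(3 * m, -r, r), m, 3)
    ok <- rowSums(p^2) <= r^2
    p <- sweep(p[ok, , drop = FALSE], 2, c_s, "+")
    inz <- (p[, 3] >= slabs[1, 1] & p[, 3] <= slabs[1, 2]) |
      (p[, 3] >= slabs[2, 1] & p[, 3] <= slabs[2, 2])
    out <- rbind(out, p[inz, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Volume of site sphere s clipped to the slabs (spherical-cap arithmetic
# would do; Monte Carlo at fixed internal seed is simpler and exact enough
# for the sampling weights -- it IS the sampling measure used above).
.site_volume <- function(model, s, n_mc = 2e4L) {
  r <- model$site_radii[s]
  c_s <- model$site_centers[s, ]
  slabs <- .leaflet_slabs(model)
  # analytic: sphere volume minus caps outside [zlo, zhi]
  zlo <- min(slabs); zhi <- max(slabs)
  cap <- function(h) if (h <= 0) 0 else pi * h^2 * (3 * r - h) / 3
  v <- 4 / 3 * pi * r^3
  v - cap(r - (zhi - c_s[3])) - cap(r - (c_s[3] - zlo))
}

.bulk_volume <- function(model) {
  slabs <- .leaflet_slabs(model)
  slab_h <- sum(slabs[, 2] - slabs[, 1])
  area <- model$box[1] * model$box[2] - pi * model$protein_radius^2
  v <- area * slab_h
  for (s in seq_len(nrow(model$site_centers))) v <- v - .site_volume(model, s)
  v
}

#' Draw an i.i.d. snapshot ensemble as a bead system
#'
#' Cholesterol is partitioned between bulk and site regions with
#' probabilities proportional to volume x exp(-well/RT); POPC is uniform.
#' Every lipid is a single bead (headgroup-proxy resolution); the protein
#' cylinder is a static shell of beads.
#'
#' @param model a [spatial_ensemble_model()].
#' @param frames number of snapshots.
#' @param seed RNG seed.
#' @return list: `system` (a [bead_system()]), `window`, `model`.
#' @export
simulate_snapshot_ensemble <- function(model, frames, seed) {
  stopifnot(inherits(model, "spatial_ensemble_model"), frames >= 1)
  set.seed(as.integer(seed))
  rt <- rt_kj(model$temperature)
  n_sites <- nrow(model$site_centers)
  w <- c(.bulk_volume(model),
         vapply(seq_len(n_sites), function(s) {
           .site_volume(model, s) * exp(-model$well_depths[s] / rt)
         }, numeric(1)))
  p_region <- w / sum(w)
  # static protein cylinder: rings of beads on the surface
  ctr <- model$box / 2
  ring_z <- seq(ctr[3] - model$protein_half_height,
                ctr[3] + model$protein_half_height, by = 0.25)
  ring_a <- seq(0, 2 * pi, length.out = 17L)[-17L]
  prot <- cbind(rep(ctr[1] + model$protein_radius * cos(ring_a), length(ring_z)),
                rep(ctr[2] + model$protein_radius * sin(ring_a), length(ring_z)),
                rep(ring_z, each = length(ring_a)))
  n_prot <- nrow(prot)
  n_lip <- model$n_chol + model$n_popc
  n_beads_tot <- n_prot + n_lip
  coords <- array(0, c(n_beads_tot, 3, frames))
  for (f in seq_len(frames)) {
    region <- sample.int(n_sites + 1L, model$n_chol, replace = TRUE,
                         prob = p_region) - 1L
    chol <- matrix(0, model$n_chol, 3)
    nb <- sum(region == 0L)
    if (nb) chol[region == 0L, ] <- .sample_bulk(model, nb, exclude_sites = TRUE)
    for (s in seq_len(n_sites)) {
      ns <- sum(region == s)
      if (ns) chol[region == s, ] <- .sample_site(model, s, ns)
    }
    popc <- .sample_bulk(model, model$n_popc, exclude_sites = FALSE)
    coords[, , f] <- rbind(prot, chol, popc)
  }
  bead_mol <- c(rep(1L, n_prot), seq_len(n_lip) + 1L)
  species <- c("protein", rep("CHOL", model$n_chol), rep("POPC", model$n_popc))
  chain <- c(rep("A", n_prot), rep(NA_character_, n_lip))
  resid <- c(rep(seq_along(ring_z), each = length(ring_a)),
             rep(NA_integer_, n_lip))
  resname <- c(rep("PROT", n_prot), rep("CHOL", model$n_chol),
               rep("POPC", model$n_popc))
  sys <- bead_system(coords, bead_mol, species, chain, resid, resname,
                     matrix(model$box, frames, 3, byrow = TRUE))
  list(system = sys, window = trajectory_window(seq_len(frames)),
       model = model)
}

#' Write a synthetic ensemble to disk as GRO + DCD (+ ground-truth JSON)
#'
#' Exercises the full file-reading path: the GRO carries frame 1 and the
#' topology, the DCD the trajectory, and the JSON the generator's ground
#' truth.
#'
#' @param ensemble result of [simulate_snapshot_ensemble()].
#' @param prefix output path prefix; writes `<prefix>.gro`, `<prefix>.dcd`,
#'   `<prefix>.truth.json`.
#' @return named character vector of paths.
#' @export
write_ensemble <- function(ensemble, prefix) {
  gro <- paste0(prefix, ".gro")
  dcd <- paste0(prefix, ".dcd")
  truth <- paste0(prefix, ".truth.json")
  write_gro(ensemble$system, gro, frame = 1L)
  write_dcd(ensemble$system, dcd)
  m <- ensemble$model
  jsonlite::write_json(
    list(well_depths_kj = m$well_depths,
         site_centers_nm = m$site_centers,
         site_radii_nm = m$site_radii,
         temperature_k = m$temperature,
         n_chol = m$n_chol, n_popc = m$n_popc),
    truth, auto_unbox = TRUE, digits = NA)
  c(gro = gro, dcd = dcd, truth = truth)
}
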