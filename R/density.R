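# 3D voxel density of lipid beads around a protein and the density-based
# binding free energy
#
#     dG = -RT * ln( rho_site / rho_bulk )
#
# where rho_site and rho_bulk are mean densities over masked voxel regions.
# Extending the classic 2D (xy-averaged) lipid density approach to three
# dimensions keeps sites above/below each other distinguishable.

#' Grid specification for density accumulation
#'
#' @param origin length-3 lower corner, nm.
#' @param lengths length-3 extents, nm.
#' @param bin_size voxel edge, nm (default 0.1, the analysis standard).
#' @return list with origin, lengths, bin_size, dims.
#' @export
grid_spec <- function(origin, lengths, bin_size = 0.1) {
  stopifnot(bin_size > 0, length(origin) == 3, length(lengths) == 3,
            all(lengths > 0))
  dims <- pmax(1L, as.integer(round(lengths / bin_size)))
  list(origin = as.numeric(origin), lengths = dims * bin_size,
       bin_size = bin_size, dims = dims)
}

#' Align frames onto the first frame's protein pose
#'
#' Rigid superposition of the protein beads of every frame onto frame 1
#' using a translation plus a rotation about z only (the bilayer normal
#' breaks full rotational symmetry; tilting frames out of the membrane
#' plane would smear leaflet structure).  The same transform is applied to
#' all beads.
#'
#' @param sys a [bead_system()].
#' @return a new `bead_system` with aligned coordinates.
#' @export
align_to_protein <- function(sys) {
  prot <- protein_beads(sys)
  if (!length(prot)) stop("no protein beads to align on")
  ref <- sys$coords[prot, , 1, drop = TRUE]
  ref_c <- colMeans(ref)
  out <- sys$coords
  for (f in seq_len(n_frames(sys))) {
    cur <- sys$coords[prot, , f, drop = TRUE]
    cur_c <- colMeans(cur)
    a <- sweep(cur[, 1:2, drop = FALSE], 2, cur_c[1:2])
    b <- sweep(ref[, 1:2, drop = FALSE], 2, ref_c[1:2])
    # optimal in-plane rotation angle (least-squares, closed form)
    num <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
    den <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
    th <- atan2(num, den)
    rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    xyz <- sweep(sys$coords[, , f], 2, cur_c) %*% rot
    out[, , f] <- sweep(xyz, 2, ref_c, "+")
  }
  sys$coords <- out
  sys
}

#' Accumulate a 3D voxel density of selected beads
#'
#' `counts[i, j, k]` is the number of selected bead-frames whose coordinate
#' falls in voxel (i, j, k); bead-frames outside the grid extents are
#' dropped (and counted in `n_outside`).  The density view is
#' `counts / (frames * voxel_volume)`, i.e. mean beads per nm^3 per frame,
#' so site/bulk ratios are dimensionless.
#'
#' @param sys a [bead_system()] (align first when the protein moves; see
#'   [align_to_protein()]).
#' @param selection integer bead indices to count.
#' @param spec a [grid_spec()].  Default: a grid covering frame 1's box,
#'   centred on the protein when present.
#' @return object of class `density_grid`: `counts` (3D array), `samples`,
#'   `n_frames`, `spec`, and `density`.
#' @export
accumulate_density <- function(sys, selection, spec = NULL) {
  if (!length(selection)) stop("empty bead selection")
  nf <- n_frames(sys)
  if (!nf) stop("zero frames")
  if (is.null(spec)) {
    spec <- grid_spec(c(0, 0, 0), sys$box[1, ])
  }
  dims <- spec$dims
  counts <- array(0L, dims)
  n_outside <- 0L
  for (f in seq_len(nf)) {
    xyz <- matrix(sys$coords[selection, , f], ncol = 3)
    ijk <- floor(sweep(xyz, 2, spec$origin) / spec$bin_size) + 1
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
    n_outside <- n_outside + sum(!ok)
    ijk <- ijk[ok, , drop = FALSE]
    lin <- (ijk[, 3] - 1) * dims[1] * dims[2] + (ijk[, 2] - 1) * dims[1] + ijk[, 1]
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- counts + array(tab, dims)
  }
  vol <- spec$bin_size^3
  structure(list(counts = counts, samples = sum(counts),
                 n_outside = n_outside, n_frames = nf, spec = spec,
                 density = counts / (nf * vol)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d x %d voxels (bin %.3g nm), %d samples (%d outside)\n",
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3],
              x$spec$bin_size, x$samples, x$n_outside))
  invisible(x)
}

.voxel_centers <- function(spec) {
  ax <- lapply(1:3, function(d) {
    spec$origin[d] + (seq_len(spec$dims[d]) - 0.5) * spec$bin_size
  })
  ax
}

#' Spherical site mask over a density grid
#'
#' Selects voxels whose centres lie within `radius` of `site_center`.  For
#' quantitative site densities choose a radius one bin smaller than the
#' physical site extent so no partially-covered voxel dilutes the mean.
#'
#' @param grid a [accumulate_density()] result.
#' @param site_center length-3 point, nm.
#' @param radius nm; must exceed the bin size.
#' @return object of class `region_mask` (logical array + kind).
#' @export
site_mask <- function(grid, site_center, radius) {
  spec <- grid$spec
  if (radius <= spec$bin_size) stop("radius must exceed the bin size")
  ax <- .voxel_centers(spec)
  dx2 <- outer(outer((ax[[1]] - site_center[1])^2,
                     (ax[[2]] - site_center[2])^2, "+"),
               (ax[[3]] - site_center[3])^2, "+")
  sel <- dx2 <= radius^2
  if (!any(sel)) stop("empty site mask")
  structure(list(mask = sel, kind = "site"), class = "region_mask")
}

#' Bulk-region mask: leaflet slab away from protein and sites
#'
#' Voxels whose centre z lies inside `z_slab`, farther than
#' `min_protein_distance` from every protein bead (frame 1 of an aligned
#' system), and outside any provided site masks.  The defaults (2.0 nm
#' protein clearance) are configurable stand-ins, not canonical values.
#'
#' @param grid a density grid.
#' @param sys the (aligned) [bead_system()] supplying protein beads; may be
#'   NULL for a protein-free system.
#' @param z_slab length-2 nm bounds of the bilayer/leaflet slab.
#' @param min_protein_distance nm.
#' @param exclude list of site `region_mask`s to subtract.
#' @return a `region_mask` of kind "bulk".
#' @export
bulk_mask <- function(grid, sys = NULL, z_slab,
                      min_protein_distance = 2.0, exclude = list()) {
  spec <- grid$spec
  ax <- .voxel_centers(spec)
  sel_z <- ax[[3]] >= z_slab[1] & ax[[3]] <= z_slab[2]
  sel <- array(TRUE, spec$dims)
  sel[, , !sel_z] <- FALSE
  if (!is.null(sys)) {
    prot <- protein_beads(sys)
    if (length(prot)) {
      pxyz <- sys$coords[prot, , 1, drop = TRUE]
      # distance of voxel centres to nearest protein bead, by xy then z
      cx <- rep(ax[[1]], times = spec$dims[2])
      cy <- rep(ax[[2]], each = spec$dims[1])
      min_xy2 <- matrix(Inf, spec$dims[1], spec$dims[2])
      for (p in seq_len(nrow(pxyz))) {
        d2 <- (cx - pxyz[p, 1])^2 + (cy - pxyz[p, 2])^2
        min_xy2 <- pmin(min_xy2, matrix(d2, spec$dims[1], spec$dims[2]))
      }
      # conservative: protein spans the slab (TMD), so xy distance governs
      near <- min_xy2 < min_protein_distance^2
      for (k in which(sel_z)) sel[, , k] <- sel[, , k] & !near
    }
  }
  for (m in exclude) sel <- sel & !m$mask
  if (!any(sel)) stop("empty bulk mask (slab/clearance exclude every voxel)")
  structure(list(mask = sel, kind = "bulk"), class = "region_mask")
}

#' Density-based binding free energy
#'
#' dG = -RT ln(mean site density / mean bulk density), kJ/mol.  Zero site
#' density returns +Inf with a warning (an unsampled site, not an error);
#' zero bulk density is an error.  Doubling every count leaves dG
#' unchanged (only the ratio matters).
#'
#' @param grid a density grid.
#' @param site,bulk `region_mask`s (disjoint).
#' @param temperature kelvin.
#' @return kJ/mol.
#' @export
binding_free_energy <- function(grid, site, bulk, temperature = 310) {
  stopifnot(inherits(site, "region_mask"), inherits(bulk, "region_mask"))
  if (any(site$mask & bulk$mask)) stop("site and bulk masks overlap")
  rho_site <- mean(grid$density[site$mask])
  rho_bulk <- mean(grid$density[bulk$mask])
  if (rho_bulk <= 0) stop("zero bulk density")
  if (rho_site <= 0) {
    warning("zero site density; returning +Inf")
    return(Inf)
  }
  -rt_kj(temperature) * log(rho_site / rho_bulk)
}

#' Export a density grid (or mask) as an OpenDX map
#'
#' Plain-text OpenDX, readable by VMD/PyMOL/gridData tooling.  Values are
#' written in x-fastest-last (z fastest) order as the format requires.
#'
#' @param grid a `density_grid`.
#' @param path output .dx file.
#' @param what `"density"` or `"counts"`, or a `region_mask` to export as
#'   0/1.
#' @export
write_opendx <- function(grid, path, what = "density") {
  spec <- grid$spec
  vals <- if (inherits(what, "region_mask")) {
    what$mask + 0
  } else {
    grid[[what]]
  }
  d <- spec$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f",
                     spec$origin[1] + spec$bin_size / 2,
                     spec$origin[2] + spec$bin_size / 2,
                     spec$origin[3] + spec$bin_size / 2), con)
  writeLines(sprintf("delta %.6f 0 0", spec$bin_size), con)
  writeLines(sprintf("delta 0 %.6f 0", spec$bin_size), con)
  writeLines(sprintf("delta 0 0 %.6f", spec$bin_size), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     d[1], d[2], d[3]), con)
  writeLines(sprintf("object 3 class array type double rank 0 items %d data follows",
                     prod(d)), con)
  # dx convention: x varies slowest, z fastest
  flat <- as.vector(aperm(vals, c(3, 2, 1)))
  chunks <- split(flat, ceiling(seq_along(flat) / 3))
  writeLines(vapply(chunks, function(v) paste(sprintf("%.6g", v), collapse = " "),
                    character(1)), con)
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "density" class field', con)
  invisible(path)
}
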