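# Occupancy metrics: the fraction of trajectory frames a residue (or a
# site, averaged over its residues) is in contact with the tracked lipid,
# in percent; the nonspecific-interaction baseline; and the free-ligand
# concentration used as the saturation-curve abscissa.

#' Site definition: a labelled list of residues
#'
#' Sites are user-supplied residue lists (typically six residues whose
#' contacts persist across bilayer compositions); automated site detection
#' is out of scope.
#'
#' @param site_id label.
#' @param chain,resid equal-length vectors of residue identifiers.
#' @return object of class `site_definition`.
#' @export
site_definition <- function(site_id, chain, resid) {
  stopifnot(length(chain) == length(resid), length(resid) >= 1L)
  key <- paste0(chain, ":", resid)
  if (anyDuplicated(key)) stop("site residues must be unique")
  structure(list(site_id = site_id,
                 residues = data.frame(chain = as.character(chain),
                                       resid = as.integer(resid),
                                       stringsAsFactors = FALSE)),
            class = "site_definition")
}

#' Per-residue occupancy, percent of frames
#'
#' occupancy = 100 * F_x / F_t, where F_x counts frames in which any tracked
#' lipid is in contact with the residue and F_t is the total frame count.
#'
#' @param series a [contact_series()].
#' @param residue residue key "chain:resid" (or chain and resid via `...`).
#' @return percent in [0, 100].
#' @export
residue_occupancy <- function(series, residue) {
  if (!residue %in% series$residue_labels) {
    stop("residue ", residue, " absent from contact series")
  }
  ft <- ncol(series$residue_states)
  if (!ft) stop("empty contact series (F_t = 0)")
  100 * sum(series$residue_states[residue, ]) / ft
}

#' Site occupancy: mean of the site residues' occupancies, percent
#'
#' @param series a [contact_series()].
#' @param site a [site_definition()].
#' @return percent in [0, 100].
#' @export
site_occupancy <- function(series, site) {
  keys <- paste0(site$residues$chain, ":", site$residues$resid)
  vals <- vapply(keys, function(k) residue_occupancy(series, k), numeric(1))
  mean(vals)
}

#' Residues with mid-range occupancy at the reference composition
#'
#' At the reference bilayer composition (40% cholesterol in the original
#' protocol) residues whose occupancy falls inside the closed band
#' (default [30, 50]%) define the nonspecific-interaction baseline: their
#' mean occupancy tracked across compositions gives the curve a specific
#' site must exceed.
#'
#' @param occupancies named numeric vector: residue key -> percent.
#' @param band closed interval, percent.
#' @return character vector of residue keys (possibly empty, with warning).
#' @export
nonspecific_residues <- function(occupancies, band = c(30, 50)) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  keep <- names(occupancies)[occupancies >= band[1] & occupancies <= band[2]]
  if (!length(keep)) {
    warning("no residues inside the nonspecific band [",
            band[1], ", ", band[2], "]%")
  }
  keep
}

#' Free-cholesterol concentration: unbound CHOL as percent of unbound lipids
#'
#' Per frame, a lipid molecule (CHOL or POPC alike) counts as unbound iff
#' the minimum distance from any of its beads to any protein bead exceeds
#' `exclusion_distance` (default 0.8 nm).  The free-ligand concentration is
#' 100 * mean over frames of unbound-CHOL / (unbound-CHOL + unbound-POPC).
#' This is the saturation-curve abscissa: it avoids the experimental
#' approximation of equating free and total ligand pools.
#'
#' @param sys a [bead_system()].
#' @param exclusion_distance nm; beyond this from the protein surface a
#'   lipid is unbound.
#' @param ligand_species counted in the numerator (default "CHOL").
#' @param other_species the competing lipid pool (default "POPC").
#' @return percent.
#' @export
free_ligand_fraction <- function(sys, exclusion_distance = 0.8,
                                 ligand_species = "CHOL",
                                 other_species = "POPC") {
  prot <- protein_beads(sys)
  if (!length(prot)) stop("system contains no protein beads")
  lig_mol <- molecules_of(sys, ligand_species)
  oth_mol <- molecules_of(sys, other_species)
  if (!length(lig_mol) && !length(oth_mol)) stop("system contains no lipids")
  lip_mol <- c(lig_mol, oth_mol)
  is_lig <- c(rep(TRUE, length(lig_mol)), rep(FALSE, length(oth_mol)))
  bead_idx <- which(sys$bead_molecule %in% lip_mol)
  mol_of_bead <- match(sys$bead_molecule[bead_idx], lip_mol)
  nf <- n_frames(sys)
  frac <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- sys$coords[, , f]
    d2 <- .min_image_dist2(xyz[bead_idx, , drop = FALSE],
                           xyz[prot, , drop = FALSE], sys$box[f, ])
    bead_min <- sqrt(apply(d2, 1, min))
    mol_min <- tapply(bead_min, mol_of_bead, min)
    unbound <- mol_min > exclusion_distance
    n_lig <- sum(unbound & is_lig[as.integer(names(mol_min))])
    n_tot <- sum(unbound)
    if (n_tot == 0) stop("frame ", f, " has zero unbound lipids")
    frac[f] <- n_lig / n_tot
  }
  100 * mean(frac)
}

#' Tabulate occupancies and free-ligand fractions per replicate
#'
#' Convenience used by the pipeline: one row per (condition, replicate,
#' site), pairing the saturation-curve ordinate (site occupancy) with its
#' abscissa (free cholesterol) computed from the same replicate.
#'
#' @param runs list of lists, each with `system`, `condition`
#'   (a [simulation_condition()]), and `series_by_site` (named list of
#'   [contact_series()] per site id).
#' @param sites named list of [site_definition()].
#' @param exclusion_distance nm, for [free_ligand_fraction()].
#' @return data.frame: condition, replicate, site_id, occupancy_percent,
#'   free_chol_percent.
#' @export
occupancy_table <- function(runs, sites, exclusion_distance = 0.8) {
  rows <- list()
  for (run in runs) {
    x <- free_ligand_fraction(run$system, exclusion_distance)
    for (sid in names(sites)) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = run$condition$total_cholesterol_percent,
        replicate = run$condition$replicate_id,
        site_id = sid,
        occupancy_percent = site_occupancy(run$series_by_site[[sid]], sites[[sid]]),
        free_chol_percent = x,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
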