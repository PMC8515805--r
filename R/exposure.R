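# Membrane exposure of a bound lipid: how buried is it?
#
# Among all beads within a cutoff (default 0.6 nm) of any bead of the bound
# lipid, the exposure fraction is lipid-bead contacts / (lipid + protein
# bead contacts).  0 = fully buried in the protein, 1 = fully membrane
# exposed.  Solvent beads are not counted (the measure contrasts protein
# against lipid environment only).

#' Membrane-exposure fraction of a bound site lipid
#'
#' @param sys a [bead_system()].
#' @param site_lipid molecule id of the bound lipid.
#' @param bound_frames frames over which the lipid is considered bound
#'   (supplied externally, e.g. frames where the site residues are in
#'   contact with this lipid).
#' @param cutoff nm (default 0.6).
#' @param per_molecule count touching molecules instead of beads.
#' @return object of class `exposure_result`: `fraction` (mean over usable
#'   bound frames), `frames_used`, `per_frame` (data.frame: frame,
#'   lipid_contacts, protein_contacts, fraction).
#' @export
membrane_exposure <- function(sys, site_lipid, bound_frames, cutoff = 0.6,
                              per_molecule = FALSE) {
  if (!length(bound_frames)) stop("bound_frames is empty")
  lip_beads <- which(sys$bead_molecule == site_lipid)
  if (!length(lip_beads)) stop("unknown site lipid molecule ", site_lipid)
  species_bead <- sys$molecule_species[sys$bead_molecule]
  other_lipid <- species_bead %in% c("CHOL", "POPC", "other") &
    sys$bead_molecule != site_lipid
  prot <- species_bead == "protein"
  cand <- which(other_lipid | prot)
  rows <- list()
  for (f in bound_frames) {
    xyz <- sys$coords[, , f]
    d2 <- .min_image_dist2(xyz[cand, , drop = FALSE],
                           xyz[lip_beads, , drop = FALSE], sys$box[f, ])
    touching <- apply(d2, 1, min) < cutoff^2
    idx <- cand[touching]
    if (per_molecule) {
      mols <- unique(sys$bead_molecule[idx])
      nl <- sum(sys$molecule_species[mols] != "protein")
      np <- sum(sys$molecule_species[mols] == "protein")
    } else {
      nl <- sum(other_lipid[idx])
      np <- sum(prot[idx])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f, lipid_contacts = nl, protein_contacts = np,
      fraction = if (nl + np > 0) nl / (nl + np) else NA_real_)
  }
  per_frame <- do.call(rbind, rows)
  usable <- is.finite(per_frame$fraction)
  if (!any(usable)) stop("all bound frames have zero contacts")
  if (any(!usable)) {
    message(sum(!usable), " bound frame(s) with zero contacts skipped")
  }
  structure(list(fraction = mean(per_frame$fraction[usable]),
                 frames_used = sum(usable),
                 per_frame = per_frame),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf("membrane exposure: %.3f over %d bound frame(s)\n",
              x$fraction, x$frames_used))
  invisible(x)
}

#' Replicate-averaged exposure with SEM
#'
#' @param results list of `exposure_result`s (one per replicate).
#' @return list: `fraction` (mean), `sem`, `n`.
#' @export
exposure_summary <- function(results) {
  fr <- vapply(results, `[[`, numeric(1), "fraction")
  list(fraction = mean(fr),
       sem = if (length(fr) >= 2) replicate_sem(fr) else NA_real_,
       n = length(fr))
}
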