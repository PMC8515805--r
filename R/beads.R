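#' Bead system: coarse-grained coordinates with molecule/species/residue maps
#'
#' The central container consumed by every analysis.  Coordinates are stored
#' in nanometres regardless of the source format (GRO is nm natively; PDB and
#' DCD inputs are converted from Angstrom on read).  Only orthorhombic boxes
#' are supported.
#'
#' @param coords numeric array `n_beads x 3 x n_frames`, nm.
#' @param bead_molecule integer vector (length `n_beads`): molecule id of
#'   each bead.  Molecule ids are `1..n_molecules`.
#' @param molecule_species character vector (length `n_molecules`), each one
#'   of `"protein"`, `"CHOL"`, `"POPC"`, `"other"`, `"solvent"`.
#' @param chain,resid,resname per-bead residue identifiers.  `chain` and
#'   `resid` must be non-NA for protein beads; matching of user-supplied site
#'   lists is by chain + resid.
#' @param box numeric matrix `n_frames x 3` of box edge lengths, nm.
#' @return object of class `bead_system`.
#' @export
bead_system <- function(coords, bead_molecule, molecule_species,
                        chain, resid, resname, box) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_beads <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3)
  if (!all(is.finite(box)) || any(box <= 0)) stop("box lengths must be finite and > 0")
  bead_molecule <- as.integer(bead_molecule)
  stopifnot(length(bead_molecule) == n_beads)
  if (anyNA(bead_molecule)) stop("every bead must map to exactly one molecule")
  n_mol <- max(bead_molecule)
  stopifnot(length(molecule_species) == n_mol)
  species_ok <- c("protein", "CHOL", "POPC", "other", "solvent")
  bad <- setdiff(unique(molecule_species), species_ok)
  if (length(bad)) {
    stop("unknown species: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(species_ok, collapse = ", "), ")")
  }
  stopifnot(length(chain) == n_beads, length(resid) == n_beads,
            length(resname) == n_beads)
  is_prot <- molecule_species[bead_molecule] == "protein"
  if (any(is_prot & (is.na(chain) | is.na(resid)))) {
    stop("every protein bead must map to exactly one (chain, resid) residue")
  }
  structure(
    list(coords = coords,
         bead_molecule = bead_molecule,
         molecule_species = as.character(molecule_species),
         chain = as.character(chain),
         resid = as.integer(resid),
         resname = as.character(resname),
         box = box),
    class = "bead_system")
}

#' @export
print.bead_system <- function(x, ...) {
  tab <- table(factor(x$molecule_species,
                      c("protein", "CHOL", "POPC", "other", "solvent")))
  cat(sprintf("bead_system: %d beads, %d molecules, %d frame(s)\n",
              n_beads(x), length(x$molecule_species), n_frames(x)))
  cat("  molecules:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  box (frame 1): %.3f x %.3f x %.3f nm\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' @rdname bead_system
#' @param x a `bead_system`.
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' @rdname bead_system
#' @export
n_beads <- function(x) dim(x$coords)[1]

#' Residue key "chain:resid" per bead (NA for non-protein beads)
#' @param sys a `bead_system`.
#' @keywords internal
residue_key <- function(sys) {
  k <- paste0(sys$chain, ":", sys$resid)
  k[is.na(sys$chain) | is.na(sys$resid)] <- NA_character_
  k
}

#' Bead indices of a protein residue
#' @param sys a `bead_system`
#' @param chain,resid residue identifier
#' @return integer bead indices
#' @export
residue_beads <- function(sys, chain, resid) {
  is_prot <- sys$molecule_species[sys$bead_molecule] == "protein"
  idx <- which(is_prot & sys$chain == chain & sys$resid == resid)
  if (!length(idx)) stop(sprintf("residue %s:%d not found in system", chain, resid))
  idx
}

#' Molecule ids of a given species
#' @param sys a `bead_system`
#' @param species one of the species labels
#' @export
molecules_of <- function(sys, species) {
  which(sys$molecule_species == species)
}

#' Bead indices of all protein beads
#' @param sys a `bead_system`
#' @export
protein_beads <- function(sys) {
  which(sys$molecule_species[sys$bead_molecule] == "protein")
}

#' Trajectory window: frame times and stride bookkeeping
#'
#' @param frame_times frame times in ps, strictly increasing.
#' @param stride frames skipped on load (1 = every frame kept).
#' @return object of class `trajectory_window` with fields `frame_count`,
#'   `frame_times`, `frame_stride`.
#' @export
trajectory_window <- function(frame_times, stride = 1L) {
  frame_times <- as.numeric(frame_times)
  if (!length(frame_times)) stop("zero frames")
  if (any(diff(frame_times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(frame_count = length(frame_times),
                 frame_times = frame_times,
                 frame_stride = as.integer(stride)),
            class = "trajectory_window")
}

#' Truncate a trajectory window to an analysis length
#'
#' Retains frames with time <= `max_time`; used for convergence analyses
#' that re-fit on shortened trajectories.
#'
#' @param window a `trajectory_window`.
#' @param max_time ps; must be >= the first frame time.
#' @return truncated `trajectory_window`.
#' @export
truncate_window <- function(window, max_time) {
  stopifnot(inherits(window, "trajectory_window"), max_time > 0)
  keep <- window$frame_times <= max_time
  if (!any(keep)) {
    stop(sprintf("max_time %.3f ps precedes first frame at %.3f ps",
                 max_time, window$frame_times[1]))
  }
  trajectory_window(window$frame_times[keep], window$frame_stride)
}

#' Simulation condition: bilayer composition + replicate label
#'
#' @param total_cholesterol_percent mol% cholesterol of lipids, in [0, 100].
#' @param replicate_id integer replicate label.
#' @param temperature kelvin; default 310 (the simulation temperature
#'   standard for physiological CG membranes).
#' @export
simulation_condition <- function(total_cholesterol_percent, replicate_id = 1L,
                                 temperature = 310) {
  stopifnot(total_cholesterol_percent >= 0, total_cholesterol_percent <= 100,
            temperature > 0)
  structure(list(total_cholesterol_percent = total_cholesterol_percent,
                 replicate_id = as.integer(replicate_id),
                 temperature = temperature),
            class = "simulation_condition")
}

#' Extract a single-frame coordinate matrix
#' @param sys a `bead_system`
#' @param frame frame index
#' @return `n_beads x 3` matrix (nm)
#' @export
frame_coords <- function(sys, frame = 1L) {
  stopifnot(frame >= 1L, frame <= n_frames(sys))
  sys$coords[, , frame, drop = TRUE]
}
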