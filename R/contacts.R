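# Dual-cutoff contact detection between lipid molecules and protein residues.
#
# A contact is bead-granular: a lipid touches a residue when ANY bead of the
# lipid is within the cutoff of ANY bead of the residue.  The dual-cutoff
# (hysteresis) rule suppresses flicker: a contact initiates below the lower
# cutoff (default 0.55 nm) and persists until the distance exceeds the upper
# cutoff (default 1.0 nm).

#' Minimum-image squared distances between two bead groups
#'
#' @param a,b coordinate matrices (`nA x 3`, `nB x 3`), nm.
#' @param box length-3 box edge lengths, nm.
#' @return `nA x nB` matrix of squared distances.
#' @keywords internal
.min_image_dist2 <- function(a, b, box) {
  d2 <- 0
  for (k in 1:3) {
    dk <- abs(outer(a[, k], b[, k], "-")) %% box[k]
    dk <- pmin(dk, box[k] - dk)
    d2 <- d2 + dk * dk
  }
  d2
}

#' Minimum bead-bead distance between two groups under minimum image
#'
#' Returns the minimum over all bead pairs of the minimum-image Euclidean
#' distance.  This is the distance the contact definitions use ("any bead
#' ... any bead"); no centre-of-mass shortcut is taken.
#'
#' @param group_a,group_b coordinate matrices (`n x 3`), nm.
#' @param box length-3 orthorhombic box lengths, nm.
#' @return distance in nm.
#' @export
min_bead_distance <- function(group_a, group_b, box) {
  group_a <- rbind(group_a); group_b <- rbind(group_b)
  if (!nrow(group_a) || !nrow(group_b)) stop("empty bead group")
  stopifnot(length(box) == 3, all(box > 0))
  sqrt(min(.min_image_dist2(group_a, group_b, box)))
}

#' Hysteresis (dual-cutoff) contact states from a distance series
#'
#' The state becomes TRUE when the distance drops below `lower`, stays TRUE
#' while the distance remains below `upper`, and becomes FALSE once the
#' distance reaches `upper`.  At frame 1 there is no history, so the state
#' is TRUE iff the distance is below `lower` (conservative: a contact is
#' never credited before it initiates).  With `lower == upper` the rule
#' collapses to plain thresholding.
#'
#' @param distances numeric vector of nm distances (one per frame).
#' @param lower,upper cutoffs in nm, `0 < lower <= upper`.
#' @return logical vector of contact states.
#' @export
dual_cutoff_states <- function(distances, lower = 0.55, upper = 1.0) {
  if (!length(distances)) stop("empty distance series")
  if (lower > upper) stop("lower cutoff exceeds upper cutoff")
  stopifnot(lower > 0)
  below_lo <- distances < lower
  below_hi <- distances < upper
  state <- logical(length(distances))
  state[1] <- below_lo[1]
  for (f in seq_along(distances)[-1]) {
    state[f] <- below_lo[f] || (state[f - 1] && below_hi[f])
  }
  state
}

# Vectorised form: rows = pairs, cols = frames.
.dual_cutoff_states_matrix <- function(dist_mat, lower, upper) {
  below_lo <- dist_mat < lower
  below_hi <- dist_mat < upper
  state <- matrix(FALSE, nrow(dist_mat), ncol(dist_mat))
  state[, 1] <- below_lo[, 1]
  for (f in seq_len(ncol(dist_mat))[-1]) {
    state[, f] <- below_lo[, f] | (state[, f - 1] & below_hi[, f])
  }
  state
}

#' Contact series container
#'
#' @param pair_states logical array `n_lipids x n_residues x n_frames`.
#' @param residue_labels character residue keys ("chain:resid").
#' @param lipid_ids molecule ids of the tracked lipids.
#' @param lower,upper the cutoffs used, nm.
#' @return object of class `contact_series`; `residue_states`
#'   (`n_residues x n_frames`) is the frame-wise OR over lipids.
#' @export
contact_series <- function(pair_states, residue_labels, lipid_ids,
                           lower = 0.55, upper = 1.0) {
  stopifnot(length(dim(pair_states)) == 3L, lower > 0, lower <= upper)
  dimnames(pair_states) <- list(NULL, residue_labels, NULL)
  residue_states <- apply(pair_states, c(2, 3), any)
  if (is.null(dim(residue_states))) {
    residue_states <- matrix(residue_states, nrow = dim(pair_states)[2])
  }
  rownames(residue_states) <- residue_labels
  structure(list(pair_states = pair_states,
                 residue_states = residue_states,
                 residue_labels = residue_labels,
                 lipid_ids = lipid_ids,
                 lower_cutoff = lower, upper_cutoff = upper),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("contact_series: %d lipid(s) x %d residue(s) x %d frame(s), cutoffs %.2f/%.2f nm\n",
              dim(x$pair_states)[1], dim(x$pair_states)[2], dim(x$pair_states)[3],
              x$lower_cutoff, x$upper_cutoff))
  invisible(x)
}

#' Per-residue lipid contact series for a bead system
#'
#' For every (lipid of `species`, residue) pair and every frame, the minimum
#' bead-bead minimum-image distance is thresholded through the dual-cutoff
#' state machine; the per-residue series is the OR over lipids.
#'
#' @param sys a [bead_system()].
#' @param species lipid species to track (default "CHOL").
#' @param residues data.frame with columns `chain`, `resid` (rows are the
#'   residues to monitor).
#' @param lower,upper dual cutoffs, nm.
#' @return a [contact_series()].
#' @export
residue_contact_series <- function(sys, species = "CHOL", residues,
                                   lower = 0.55, upper = 1.0) {
  if (lower > upper) stop("lower cutoff exceeds upper cutoff")
  lipids <- molecules_of(sys, species)
  if (!length(lipids)) stop("no lipids of species ", species)
  res_beads <- lapply(seq_len(nrow(residues)), function(r) {
    residue_beads(sys, residues$chain[r], residues$resid[r])
  })
  labels <- paste0(residues$chain, ":", residues$resid)
  lip_beads <- lapply(lipids, function(m) which(sys$bead_molecule == m))
  nf <- n_frames(sys)
  npair <- length(lipids) * nrow(residues)
  dmat <- matrix(0, npair, nf)
  for (f in seq_len(nf)) {
    xyz <- sys$coords[, , f]
    box <- sys$box[f, ]
    p <- 0L
    for (rb in res_beads) {
      rxyz <- xyz[rb, , drop = FALSE]
      for (lb in lip_beads) {
        p <- p + 1L
        dmat[p, f] <- sqrt(min(.min_image_dist2(xyz[lb, , drop = FALSE],
                                                rxyz, box)))
      }
    }
  }
  st <- .dual_cutoff_states_matrix(dmat, lower, upper)
  pair_states <- array(FALSE, c(length(lipids), nrow(residues), nf))
  p <- 0L
  for (r in seq_len(nrow(residues))) {
    for (l in seq_along(lipids)) {
      p <- p + 1L
      pair_states[l, r, ] <- st[p, ]
    }
  }
  contact_series(pair_states, labels, lipids, lower, upper)
}

#' Export per-residue contact states as tidy CSV
#'
#' @param series a [contact_series()].
#' @param path output CSV (frame, residue, state).
#' @export
write_contacts_csv <- function(series, path) {
  nf <- ncol(series$residue_states)
  df <- data.frame(
    frame = rep(seq_len(nf), each = length(series$residue_labels)),
    residue = rep(series$residue_labels, nf),
    state = as.integer(series$residue_states))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
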