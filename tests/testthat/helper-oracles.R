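# Independent oracles and toy-system builders shared across tests.
# These deliberately re-derive everything the slow, obvious way: exhaustive
# O(N^2) pair loops and a literal transcription of the hysteresis rule.

# Exhaustive minimum-image distance over all bead pairs (loop, no vectorisation)
oracle_min_dist <- function(a, b, box) {
  a <- rbind(a); b <- rbind(b)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d2 <- 0
      for (k in 1:3) {
        dk <- abs(a[i, k] - b[j, k]) %% box[k]
        dk <- min(dk, box[k] - dk)
        d2 <- d2 + dk^2
      }
      best <- min(best, d2)
    }
  }
  sqrt(best)
}

# Literal hysteresis state machine
oracle_hysteresis <- function(d, lower, upper) {
  s <- logical(length(d))
  prev <- FALSE
  for (f in seq_along(d)) {
    s[f] <- if (d[f] < lower) TRUE else if (d[f] >= upper) FALSE else prev
    if (f == 1 && d[f] >= lower) s[f] <- FALSE  # no history: only < lower starts
    prev <- s[f]
  }
  s
}

# Naive re-evaluation of residue_contact_series: per (lipid, residue) pair,
# build the distance series with oracle_min_dist, run oracle_hysteresis,
# OR over lipids.
oracle_contact_series <- function(sys, species, residues, lower, upper) {
  lipids <- which(sys$molecule_species == species)
  nf <- dim(sys$coords)[3]
  res_states <- matrix(FALSE, nrow(residues), nf)
  pair_states <- array(FALSE, c(length(lipids), nrow(residues), nf))
  for (r in seq_len(nrow(residues))) {
    rb <- which(sys$molecule_species[sys$bead_molecule] == "protein" &
                  sys$chain == residues$chain[r] &
                  sys$resid == residues$resid[r])
    for (li in seq_along(lipids)) {
      lb <- which(sys$bead_molecule == lipids[li])
      d <- vapply(seq_len(nf), function(f) {
        oracle_min_dist(matrix(sys$coords[lb, , f], ncol = 3),
                        matrix(sys$coords[rb, , f], ncol = 3),
                        sys$box[f, ])
      }, numeric(1))
      pair_states[li, r, ] <- oracle_hysteresis(d, lower, upper)
    }
    res_states[r, ] <- apply(pair_states[, r, , drop = FALSE], 3, any)
  }
  list(pair_states = pair_states, residue_states = res_states)
}

# Random toy system: small protein (few residues), a few CHOL/POPC lipids,
# random-walk coordinates so contacts flicker across frames.
make_toy_system <- function(n_res = 3L, n_chol = 2L, n_popc = 1L,
                            beads_per_res = 2L, beads_per_lipid = 2L,
                            frames = 10L, box = c(5, 5, 5), seed = 1L,
                            jitter = 0.35) {
  set.seed(seed)
  n_prot <- n_res * beads_per_res
  n_lip <- (n_chol + n_popc) * beads_per_lipid
  n <- n_prot + n_lip
  base <- matrix(runif(n * 3, 0, box[1]), n, 3)
  coords <- array(0, c(n, 3, frames))
  coords[, , 1] <- base
  for (f in seq_len(frames)[-1]) {
    coords[, , f] <- (coords[, , f - 1] +
                        matrix(rnorm(n * 3, 0, jitter), n, 3)) %% box[1]
  }
  bead_mol <- c(rep(1L, n_prot),
                rep(seq_len(n_chol + n_popc) + 1L, each = beads_per_lipid))
  species <- c("protein", rep("CHOL", n_chol), rep("POPC", n_popc))
  chain <- c(rep("A", n_prot), rep(NA, n_lip))
  resid <- c(rep(seq_len(n_res), each = beads_per_res), rep(NA, n_lip))
  resname <- c(rep("PROT", n_prot),
               rep(c("CHOL", "POPC"), c(n_chol, n_popc) * beads_per_lipid))
  bead_system(coords, bead_mol, species, chain, resid, resname,
              matrix(box, frames, 3, byrow = TRUE))
}

toy_residues <- function(n_res = 3L) {
  data.frame(chain = rep("A", n_res), resid = seq_len(n_res),
             stringsAsFactors = FALSE)
}

# Contact series built directly from a given residue-state matrix (for
# occupancy tests that need exact hand-written states).
series_from_states <- function(states) {
  states <- rbind(states)
  pair <- array(states, c(1L, nrow(states), ncol(states)))
  contact_series(aperm(pair, c(1, 2, 3)), rownames(states) %||%
                   paste0("A:", seq_len(nrow(states))), 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
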