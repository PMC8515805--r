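# File I/O for coarse-grained systems.
#
# GRO is read/written natively in nm.  PDB and DCD carry Angstrom and are
# converted on the way in/out.  Only orthorhombic boxes are accepted;
# triclinic inputs are rejected with a clear message.  XTC is not supported
# (no decoder available offline); DCD covers the binary-trajectory path.

NM_PER_ANGSTROM <- 0.1

# ---- GRO ------------------------------------------------------------------

#' Read a (possibly multi-frame) GRO file
#'
#' @param path GRO file.
#' @return list with `atoms` (data.frame: resid, resname, atom, from frame 1),
#'   `coords` (`n x 3 x F` array, nm), `box` (`F x 3`, nm), `times` (ps; parsed
#'   from "t=" in title lines when present, else the frame index).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  lines <- readLines(path)
  frames <- list(); boxes <- list(); times <- numeric(); atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    if (!nzchar(trimws(title)) && i == length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1L) stop("malformed GRO: bad atom count at line ", i + 1L)
    body <- lines[(i + 2L):(i + 1L + nat)]
    boxline <- strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]]
    boxnum <- as.numeric(boxline)
    if (length(boxnum) > 3 && any(abs(boxnum[-(1:3)]) > 1e-9)) {
      stop("triclinic box not supported (off-diagonal box vectors present)")
    }
    if (length(boxnum) < 3) stop("malformed GRO box line")
    x <- as.numeric(substr(body, 21, 28))
    y <- as.numeric(substr(body, 29, 36))
    z <- as.numeric(substr(body, 37, 44))
    if (anyNA(c(x, y, z))) stop("malformed GRO coordinates")
    if (is.null(atoms)) {
      atoms <- data.frame(
        resid = as.integer(substr(body, 1, 5)),
        resname = trimws(substr(body, 6, 10)),
        atom = trimws(substr(body, 11, 15)),
        stringsAsFactors = FALSE)
    }
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <- boxnum[1:3]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else length(frames))
    i <- i + 3L + nat
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("zero frames in ", path)
  coords <- array(0, c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  if (any(duplicated(times))) times <- seq_along(frames)
  list(atoms = atoms, coords = coords,
       box = do.call(rbind, boxes), times = times)
}

#' Write one frame of a bead system to GRO
#'
#' Coordinates are written at the format's native 3-decimal (pm) precision.
#'
#' @param sys a `bead_system`.
#' @param path output file.
#' @param frame frame index to write.
#' @param atom_names optional per-bead atom names (default "B<k mod 5>").
#' @export
write_gro <- function(sys, path, frame = 1L, atom_names = NULL) {
  xyz <- frame_coords(sys, frame)
  n <- n_beads(sys)
  resname <- sys$resname
  resid <- sys$resid
  # non-protein beads may lack resid; synthesize per-molecule ids
  fill <- is.na(resid)
  if (any(fill)) resid[fill] <- sys$bead_molecule[fill]
  resname[is.na(resname)] <- "UNK"
  if (is.null(atom_names)) atom_names <- sprintf("B%d", seq_len(n) %% 100)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("satbind frame t= %.3f", frame), con)
  writeLines(sprintf("%5d", n), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resid %% 100000L, substr(resname, 1, 5),
                     substr(atom_names, 1, 5), seq_len(n) %% 100000L,
                     xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f",
                     sys$box[frame, 1], sys$box[frame, 2], sys$box[frame, 3]), con)
  invisible(path)
}

# ---- PDB ------------------------------------------------------------------

#' Read coordinates from a PDB file (Angstrom converted to nm)
#'
#' Multi-MODEL files yield multiple frames.  CRYST1 supplies the box; angles
#' other than 90 degrees are rejected.
#'
#' @param path PDB file.
#' @return same shape as [read_gro()], plus a `chain` column in `atoms`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  lines <- readLines(path)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- c(5, 5, 5) * 10  # fallback, Angstrom
  if (length(cryst)) {
    v <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33)))
    ang <- as.numeric(c(substr(cryst[1], 34, 40), substr(cryst[1], 41, 47),
                        substr(cryst[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-3)) stop("triclinic box not supported (CRYST1 angles != 90)")
    box <- v
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_breaks <- grepl("^ENDMDL", lines)
  frame_of <- cumsum(model_breaks) + 1L
  at <- lines[is_atom]
  fidx <- frame_of[is_atom]
  fidx <- fidx - min(fidx) + 1L
  nfr <- max(fidx)
  per <- tabulate(fidx)
  if (length(unique(per)) != 1L) stop("inconsistent atom counts across MODELs")
  n <- per[1]
  first <- at[fidx == 1L]
  atoms <- data.frame(
    resid = as.integer(substr(first, 23, 26)),
    resname = trimws(substr(first, 18, 21)),
    atom = trimws(substr(first, 13, 16)),
    chain = trimws(substr(first, 22, 22)),
    stringsAsFactors = FALSE)
  coords <- array(0, c(n, 3, nfr))
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  for (f in seq_len(nfr)) coords[, , f] <- xyz[fidx == f, , drop = FALSE]
  list(atoms = atoms, coords = coords * NM_PER_ANGSTROM,
       box = matrix(rep(box * NM_PER_ANGSTROM, nfr), ncol = 3, byrow = TRUE),
       times = seq_len(nfr))
}

# ---- DCD ------------------------------------------------------------------

.dcd_record <- function(con, payload_raw) {
  writeBin(length(payload_raw), con, size = 4L, endian = "little")
  writeBin(payload_raw, con)
  writeBin(length(payload_raw), con, size = 4L, endian = "little")
}

#' Write a bead system's trajectory as a CHARMM-style DCD file
#'
#' Coordinates are converted to Angstrom; the orthorhombic unit cell is
#' stored per frame with cosine angle convention (0 = 90 degrees).  The
#' header delta field records the inter-frame time in ps.
#'
#' @param sys a `bead_system`.
#' @param path output file.
#' @param dt_ps time between saved frames, ps.
#' @export
write_dcd <- function(sys, path, dt_ps = 1) {
  con <- file(path, "wb")
  on.exit(close(con))
  nfr <- n_frames(sys); nat <- n_beads(sys)
  icntrl <- integer(20)
  icntrl[1] <- nfr; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nfr
  icntrl[10] <- readBin(writeBin(as.numeric(dt_ps), raw(), size = 4L,
                                 endian = "little"),
                        "integer", size = 4L, endian = "little")
  icntrl[11] <- 1L  # crystal record present
  icntrl[20] <- 24L
  hdr <- c(charToRaw("CORD"),
           writeBin(icntrl, raw(), size = 4L, endian = "little"))
  .dcd_record(con, hdr)
  title <- sprintf("%-80s", "Created by satbind")
  .dcd_record(con, c(writeBin(1L, raw(), size = 4L, endian = "little"),
                     charToRaw(title)))
  .dcd_record(con, writeBin(nat, raw(), size = 4L, endian = "little"))
  for (f in seq_len(nfr)) {
    b <- sys$box[f, ] / NM_PER_ANGSTROM
    cell <- c(b[1], 0, b[2], 0, 0, b[3])  # XTLABC, cosine angles
    .dcd_record(con, writeBin(as.numeric(cell), raw(), size = 8L,
                              endian = "little"))
    xyz <- frame_coords(sys, f) / NM_PER_ANGSTROM
    for (d in 1:3) {
      .dcd_record(con, writeBin(as.numeric(xyz[, d]), raw(), size = 4L,
                                endian = "little"))
    }
  }
  invisible(path)
}

#' Read a CHARMM/NAMD-style DCD trajectory
#'
#' Little- and big-endian files are handled; triclinic unit cells are
#' rejected.  Coordinates return in nm.
#'
#' @param path DCD file.
#' @return list with `coords` (`n x 3 x F`, nm), `box` (`F x 3`, nm),
#'   `times` (ps, from the header delta when available).
#' @export
read_dcd <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  m <- readBin(con, "integer", size = 4L, endian = endian)
  if (m != 84L) {
    endian <- "big"
    seek(con, 0L)
    m <- readBin(con, "integer", size = 4L, endian = endian)
    if (m != 84L) stop("not a DCD file (bad header record length)")
  }
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "CORD") stop("not a DCD file (missing CORD magic)")
  icntrl <- readBin(con, "integer", n = 20L, size = 4L, endian = endian)
  readBin(con, "integer", size = 4L, endian = endian)
  nfr <- icntrl[1]
  has_cell <- icntrl[11] == 1L
  dt_ps <- readBin(writeBin(icntrl[10], raw(), size = 4L, endian = "little"),
                   "numeric", size = 4L, endian = "little")
  if (!is.finite(dt_ps) || dt_ps <= 0) dt_ps <- 1
  tlen <- readBin(con, "integer", size = 4L, endian = endian)
  readBin(con, "raw", tlen)
  readBin(con, "integer", size = 4L, endian = endian)
  readBin(con, "integer", size = 4L, endian = endian)
  nat <- readBin(con, "integer", size = 4L, endian = endian)
  readBin(con, "integer", size = 4L, endian = endian)
  coords <- array(0, c(nat, 3, nfr))
  box <- matrix(0, nfr, 3)
  for (f in seq_len(nfr)) {
    if (has_cell) {
      readBin(con, "integer", size = 4L, endian = endian)
      cell <- readBin(con, "numeric", n = 6L, size = 8L, endian = endian)
      readBin(con, "integer", size = 4L, endian = endian)
      ang <- cell[c(2, 4, 5)]
      ortho <- all(abs(ang) < 1e-6) || all(abs(ang - 90) < 1e-3)
      if (!ortho) stop("triclinic box not supported in DCD input")
      box[f, ] <- cell[c(1, 3, 6)]
    }
    for (d in 1:3) {
      readBin(con, "integer", size = 4L, endian = endian)
      coords[, d, f] <- readBin(con, "numeric", n = nat, size = 4L,
                                endian = endian)
      readBin(con, "integer", size = 4L, endian = endian)
    }
  }
  list(coords = coords * NM_PER_ANGSTROM, box = box * NM_PER_ANGSTROM,
       times = seq_len(nfr) * dt_ps)
}

# ---- system assembly ------------------------------------------------------

# Assign molecules and chains from per-atom resid/resname runs.  A new
# molecule starts whenever resid or resname changes; contiguous protein
# residues share a molecule, with the chain label advanced whenever resid
# fails to increase (handles multimeric proteins written as repeated
# 1..N resid blocks; GRO has no chain column).
.assign_molecules <- function(atoms, species_map, chain = NULL) {
  sp_of <- function(rn) {
    s <- species_map[[rn]]
    if (is.null(s)) stop("molecule name absent from species map: \"", rn, "\"")
    s
  }
  species_atom <- vapply(atoms$resname, sp_of, character(1), USE.NAMES = FALSE)
  new_res <- c(TRUE, atoms$resid[-1] != atoms$resid[-nrow(atoms)] |
                 atoms$resname[-1] != atoms$resname[-nrow(atoms)])
  res_run <- cumsum(new_res)
  first_of_run <- which(new_res)
  run_species <- species_atom[first_of_run]
  run_resid <- atoms$resid[first_of_run]
  # molecule id per run: protein runs merge while contiguous, others 1 per run
  mol_of_run <- integer(length(first_of_run))
  chain_of_run <- character(length(first_of_run))
  mol <- 0L; chain_i <- 1L
  for (r in seq_along(first_of_run)) {
    if (run_species[r] == "protein") {
      prev_prot <- r > 1L && run_species[r - 1L] == "protein"
      if (!prev_prot) {
        mol <- mol + 1L
      } else if (run_resid[r] <= run_resid[r - 1L]) {
        chain_i <- chain_i + 1L
        mol <- mol + 1L
      }
      chain_of_run[r] <- LETTERS[(chain_i - 1L) %% 26L + 1L]
    } else {
      mol <- mol + 1L
      chain_of_run[r] <- NA_character_
    }
    mol_of_run[r] <- mol
  }
  bead_mol <- mol_of_run[res_run]
  mol_species <- run_species[!duplicated(mol_of_run)]
  chain_bead <- if (is.null(chain)) chain_of_run[res_run] else chain
  resid_bead <- atoms$resid
  resid_bead[species_atom != "protein"] <- NA_integer_
  if (!is.null(chain)) chain_bead[species_atom != "protein"] <- NA_character_
  list(bead_molecule = bead_mol, molecule_species = mol_species,
       chain = chain_bead, resid = resid_bead, resname = atoms$resname)
}

#' Load a coarse-grained system and trajectory
#'
#' Reads a GRO or PDB coordinate file for the topology (bead -> residue and
#' molecule maps) and, optionally, a DCD or multi-frame GRO trajectory for
#' the frames.  Every residue name must appear in `species_map`.
#'
#' @param coordinate_file GRO or PDB path.
#' @param trajectory_file optional DCD or GRO path; when NULL the coordinate
#'   file's own frame(s) are used.
#' @param species_map named list/vector: residue name -> one of `"protein"`,
#'   `"CHOL"`, `"POPC"`, `"other"`, `"solvent"`.
#' @param stride keep every `stride`-th frame (the save interval used for
#'   analysis is not fixed by the method; expose it).
#' @return list with `system` (a [bead_system()]) and `window`
#'   (a [trajectory_window()]).
#' @export
load_system <- function(coordinate_file, trajectory_file = NULL,
                        species_map, stride = 1L) {
  stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  ext <- function(p) tolower(tools::file_ext(p))
  if (!file.exists(coordinate_file)) stop("unreadable file: ", coordinate_file)
  top <- switch(ext(coordinate_file),
                gro = read_gro(coordinate_file),
                pdb = read_pdb(coordinate_file),
                stop("unsupported coordinate format: .", ext(coordinate_file)))
  traj <- top
  if (!is.null(trajectory_file)) {
    if (ext(trajectory_file) == "xtc") {
      stop("XTC trajectories are not supported; convert to DCD or multi-frame GRO")
    }
    traj <- switch(ext(trajectory_file),
                   dcd = read_dcd(trajectory_file),
                   gro = read_gro(trajectory_file),
                   stop("unsupported trajectory format: .", ext(trajectory_file)))
    if (dim(traj$coords)[1] != nrow(top$atoms)) {
      stop(sprintf("trajectory has %d beads but coordinate file has %d",
                   dim(traj$coords)[1], nrow(top$atoms)))
    }
  }
  keep <- seq(1L, dim(traj$coords)[3], by = stride)
  maps <- .assign_molecules(top$atoms, as.list(species_map),
                            chain = top$atoms$chain)
  sys <- bead_system(traj$coords[, , keep, drop = FALSE],
                     maps$bead_molecule, maps$molecule_species,
                     maps$chain, maps$resid, maps$resname,
                     traj$box[keep, , drop = FALSE])
  list(system = sys, window = trajectory_window(traj$times[keep], stride))
}
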