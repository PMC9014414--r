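#' Atom trajectory container
#'
#' @param coords Numeric array `frames x atoms x 3` (nm).
#' @param atoms Data frame with columns `name`, `resid` (residue index,
#'   non-decreasing), `resname`.
#' @param times Frame times (defaults to `0:(frames-1)`).
#' @return An `atom_trajectory`.
#' @export
atom_trajectory <- function(coords, atoms, times = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  atoms <- as.data.frame(atoms)
  if (!all(c("name", "resid", "resname") %in% names(atoms)))
    stop("'atoms' needs columns name, resid, resname")
  if (nrow(atoms) != dim(coords)[2])
    stop("atom table and coordinate array disagree on atom count")
  if (is.unsorted(atoms$resid))
    stop("residue indices must be non-decreasing")
  if (is.null(times)) times <- seq_len(dim(coords)[1]) - 1
  stopifnot(length(times) == dim(coords)[1])
  structure(list(coords = coords, atoms = atoms, times = times),
            class = "atom_trajectory")
}

#' @export
print.atom_trajectory <- function(x, ...) {
  cat(sprintf("Atom trajectory: %d frame(s), %d atom(s), %d residue(s)\n",
              dim(x$coords)[1], dim(x$coords)[2], length(unique(x$atoms$resid))))
  invisible(x)
}

#' Specification for a toy protein trajectory
#'
#' Describes the programmable features of the synthetic coordinate
#' generator: a chain of residues laid out on a line (0.8 nm spacing, three
#' atoms per residue: N, CA, C), an optional driven dihedral quadruple with
#' a programmed angle series, a mobile region with isotropic Gaussian
#' jitter, and plantable hydrogen-bond and contact geometries realized in a
#' stated fraction of frames.
#'
#' @param n_residues Number of residues.
#' @param n_frames Number of frames.
#' @param mobile_residues Residue indices receiving jitter.
#' @param mobile_sigma Jitter standard deviation per coordinate (nm).
#' @param dihedral_atoms Optional 4 atom indices for the driven dihedral.
#' @param dihedral_series Programmed dihedral values (radians), recycled to
#'   `n_frames`.
#' @param hbonds List of planted donor-H-acceptor geometries: each element a
#'   list with `donor`, `hydrogen`, `acceptor` atom indices, optional
#'   `distance` (donor-acceptor, nm, default 0.28) and `fraction` of frames
#'   (default 1) in which the bond geometry is realized (the leading
#'   `round(fraction * n_frames)` frames).
#' @param contacts List of planted atom-pair contacts: each a list with
#'   `i`, `j`, optional `distance` (default 0.30 nm) and `fraction`
#'   (default 1); in the remaining frames the pair is parked 1.5 nm apart.
#' @return A `toy_protein_spec` list.
#' @export
toy_protein_spec <- function(n_residues = 20, n_frames = 100,
                             mobile_residues = integer(0),
                             mobile_sigma = 0.02,
                             dihedral_atoms = NULL, dihedral_series = NULL,
                             hbonds = list(), contacts = list()) {
  stopifnot(n_residues >= 1, n_frames >= 1, mobile_sigma >= 0)
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 mobile_residues = as.integer(mobile_residues),
                 mobile_sigma = mobile_sigma,
                 dihedral_atoms = dihedral_atoms,
                 dihedral_series = dihedral_series,
                 hbonds = hbonds, contacts = contacts),
            class = "toy_protein_spec")
}

#' Generate a toy protein trajectory
#'
#' Builds coordinates realizing the programmed features of a
#' [toy_protein_spec()]: the driven dihedral is exact (before jitter), the
#' mobile region gets isotropic Gaussian noise, and planted hydrogen-bond /
#' contact geometries satisfy their criteria in exactly the stated fraction
#' of frames.  Non-adjacent residues on the backbone line are always
#' farther apart than any contact cutoff, so planted features are the only
#' signals present.
#'
#' @param spec A [toy_protein_spec()].
#' @param seed Optional seed for the jitter.
#' @return An [atom_trajectory()].
#' @export
make_toy_protein_trajectory <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "toy_protein_spec"))
  if (!is.null(seed)) set.seed(seed)
  nr <- spec$n_residues
  nf <- spec$n_frames
  na <- nr * 3L
  check_idx <- function(i, what) {
    if (any(i < 1 | i > na)) stop(sprintf("%s atom index out of range", what))
    i
  }
  # base geometry: residues on a line along x, 0.8 nm apart
  base <- matrix(0, na, 3)
  for (r in seq_len(nr)) {
    x0 <- 0.8 * (r - 1)
    base[3 * r - 2, ] <- c(x0, 0.00, 0)        # N
    base[3 * r - 1, ] <- c(x0 + 0.15, 0.10, 0) # CA
    base[3 * r, ]     <- c(x0 + 0.30, 0.00, 0) # C
  }
  atoms <- data.frame(name = rep(c("N", "CA", "C"), nr),
                      resid = rep(seq_len(nr), each = 3),
                      resname = rep("GLY", na))
  coords <- array(rep(base, each = nf), dim = c(nf, na, 3))

  # driven dihedral: exact construction, torsion(p1,p2,p3,p4) = theta
  if (!is.null(spec$dihedral_atoms)) {
    di <- check_idx(as.integer(spec$dihedral_atoms), "dihedral")
    if (length(di) != 4) stop("dihedral_atoms must list 4 atoms")
    th <- rep_len(spec$dihedral_series, nf)
    s <- 0.15
    origin <- c(0, 0, 3)  # off the backbone line
    for (f in seq_len(nf)) {
      coords[f, di[1], ] <- origin + c(s, 0, 0)
      coords[f, di[2], ] <- origin
      coords[f, di[3], ] <- origin + c(0, 0, s)
      coords[f, di[4], ] <- origin + c(s * cos(th[f]), s * sin(th[f]), s)
    }
  }

  # planted hydrogen bonds: linear D-H...A at the requested distance
  on_frames <- function(fraction) seq_len(round(fraction * nf))
  for (k in seq_along(spec$hbonds)) {
    hb <- spec$hbonds[[k]]
    d <- check_idx(hb$donor, "hbond donor")
    h <- check_idx(hb$hydrogen, "hbond hydrogen")
    a <- check_idx(hb$acceptor, "hbond acceptor")
    dist <- if (is.null(hb$distance)) 0.28 else hb$distance
    frac <- if (is.null(hb$fraction)) 1 else hb$fraction
    dirv <- c(0, 1, 0)
    anchor <- c(0.1 * k, 0.5, -3 - 0.8 * k)  # dedicated pocket per bond
    on <- on_frames(frac)
    for (f in seq_len(nf)) {
      coords[f, d, ] <- anchor
      coords[f, h, ] <- anchor + 0.10 * dirv
      coords[f, a, ] <- anchor +
        (if (f %in% on) dist else 1.2) * dirv
    }
  }

  # planted contacts
  for (k in seq_along(spec$contacts)) {
    ct <- spec$contacts[[k]]
    i <- check_idx(ct$i, "contact")
    j <- check_idx(ct$j, "contact")
    dist <- if (is.null(ct$distance)) 0.30 else ct$distance
    frac <- if (is.null(ct$fraction)) 1 else ct$fraction
    anchor <- c(0.1 * k, -0.5, 3 + 0.8 * k)
    on <- on_frames(frac)
    for (f in seq_len(nf)) {
      coords[f, i, ] <- anchor
      coords[f, j, ] <- anchor + c(0, (if (f %in% on) dist else 1.5), 0)
    }
  }

  # mobile-region jitter
  if (length(spec$mobile_residues) > 0 && spec$mobile_sigma > 0) {
    if (any(spec$mobile_residues < 1 | spec$mobile_residues > nr))
      stop("mobile residue index out of range")
    at <- which(atoms$resid %in% spec$mobile_residues)
    coords[, at, ] <- coords[, at, ] +
      array(rnorm(nf * length(at) * 3, sd = spec$mobile_sigma),
            dim = c(nf, length(at), 3))
  }
  atom_trajectory(coords, atoms)
}

#' Write a trajectory as minimal multi-model PDB
#'
#' MODEL / ATOM / ENDMDL records; coordinates converted from nm to
#' angstroms on write.
#'
#' @param traj An [atom_trajectory()].
#' @param path Output path.
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "atom_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(traj$coords)[1]
  na <- dim(traj$coords)[2]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[f, , , drop = FALSE] * 10  # nm -> angstrom
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(na), traj$atoms$name, traj$atoms$resname, traj$atoms$resid,
      xyz[1, , 1], xyz[1, , 2], xyz[1, , 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a minimal multi-model PDB trajectory
#'
#' Inverse of [write_pdb_trajectory()]; coordinates are converted back to
#' nm.  Frame times are the model numbers minus one.
#'
#' @param path PDB file path.
#' @return An [atom_trajectory()].
#' @export
read_pdb_trajectory <- function(path) {
  lines <- readLines(path)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0)
    stop("no MODEL records found")
  frames <- list()
  atoms <- NULL
  for (ms in model_starts) {
    i <- ms + 1
    xyz <- list()
    nm <- character(0); rid <- integer(0); rnm <- character(0)
    while (i <= length(lines) && startsWith(lines[i], "ATOM")) {
      ln <- lines[i]
      nm <- c(nm, trimws(substr(ln, 13, 16)))
      rnm <- c(rnm, trimws(substr(ln, 18, 20)))
      rid <- c(rid, as.integer(substr(ln, 23, 26)))
      xyz[[length(xyz) + 1]] <- as.numeric(c(substr(ln, 31, 38),
                                             substr(ln, 39, 46),
                                             substr(ln, 47, 54)))
      i <- i + 1
    }
    if (is.null(atoms))
      atoms <- data.frame(name = nm, resid = rid, resname = rnm)
    frames[[length(frames) + 1]] <- do.call(rbind, xyz) / 10
  }
  na <- nrow(atoms)
  coords <- array(NA_real_, dim = c(length(frames), na, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  atom_trajectory(coords, atoms, times = seq_along(frames) - 1)
}
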