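#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares optimal rigid transform mapping `mobile` onto `reference`
#' over the fit atoms, with a proper rotation enforced (determinant +1, so
#' reflections are never fit).
#'
#' @param mobile,reference n x 3 coordinate matrices (nm).
#' @param fit_indices Atom indices used for the fit (default: all); at
#'   least 3 non-collinear atoms.
#' @return List with `rotation` (3 x 3) and `translation` (length 3): the
#'   fitted coordinates are `coords %*% t(rotation) + translation` (see
#'   [apply_transform()]).
#' @export
kabsch_superpose <- function(mobile, reference, fit_indices = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  A <- mobile[fit_indices, , drop = FALSE]
  B <- reference[fit_indices, , drop = FALSE]
  if (nrow(A) < 3) stop("need at least 3 fit atoms")
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  if (.rank3(A0) < 2 || .rank3(B0) < 2)
    stop("degenerate fit set: atoms coincident or collinear")
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(cb - R %*% ca))
}

.rank3 <- function(X) sum(svd(X)$d > 1e-10 * max(1, max(abs(X))))

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform A [kabsch_superpose()] result.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

.frame_mat <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3)
}

.resolve_reference <- function(traj, reference) {
  if (is.matrix(reference)) return(reference)
  .frame_mat(traj, reference)
}

#' Per-frame RMSD after superposition
#'
#' Each frame is first rigidly fitted to the reference on `fit_indices`;
#' the root-mean-square deviation is then measured over `measure_indices`.
#'
#' @param traj An [atom_trajectory()].
#' @param reference Frame index (default 1) or an n x 3 reference matrix.
#' @param fit_indices Atoms used for the fit (default: all).
#' @param measure_indices Atoms entering the RMSD (default: all).
#' @return Numeric vector of per-frame RMSD values (nm).
#' @export
rmsd_series <- function(traj, reference = 1, fit_indices = NULL,
                        measure_indices = NULL) {
  stopifnot(inherits(traj, "atom_trajectory"))
  ref <- .resolve_reference(traj, reference)
  na <- dim(traj$coords)[2]
  if (is.null(measure_indices)) measure_indices <- seq_len(na)
  vapply(seq_len(dim(traj$coords)[1]), function(f) {
    x <- .frame_mat(traj, f)
    tr <- kabsch_superpose(x, ref, fit_indices)
    xf <- apply_transform(x, tr)
    sqrt(mean(rowSums((xf[measure_indices, , drop = FALSE] -
                         ref[measure_indices, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Per-residue RMSF
#'
#' Superposes every frame on the reference over `fit_indices`, computes the
#' per-atom root-mean-square fluctuation about the time-average position,
#' and averages over the atoms of each residue (or only the CA atoms with
#' `calpha_only`).
#'
#' @param traj An [atom_trajectory()] with at least 2 frames.
#' @param fit_indices Atoms used for the fit (default: all).
#' @param calpha_only Use only atoms named `"CA"` for the per-residue
#'   reduction.
#' @return Data frame with `resid` and `rmsf` (nm).
#' @export
rmsf_per_residue <- function(traj, fit_indices = NULL, calpha_only = FALSE) {
  stopifnot(inherits(traj, "atom_trajectory"))
  nf <- dim(traj$coords)[1]
  if (nf < 2) stop("need at least 2 frames")
  ref <- .frame_mat(traj, 1)
  na <- dim(traj$coords)[2]
  fitted <- array(NA_real_, dim = c(nf, na, 3))
  for (f in seq_len(nf)) {
    x <- .frame_mat(traj, f)
    tr <- kabsch_superpose(x, ref, fit_indices)
    fitted[f, , ] <- apply_transform(x, tr)
  }
  mean_pos <- apply(fitted, c(2, 3), mean)
  dev2 <- sapply(seq_len(na), function(a)
    mean(rowSums((matrix(fitted[, a, ], ncol = 3) -
                    matrix(mean_pos[a, ], nf, 3, byrow = TRUE))^2)))
  rmsf_atom <- sqrt(dev2)
  use <- if (calpha_only) traj$atoms$name == "CA" else rep(TRUE, na)
  agg <- tapply(rmsf_atom[use], traj$atoms$resid[use], mean)
  data.frame(resid = as.integer(names(agg)), rmsf = as.numeric(agg))
}

#' Hydrogen-bond counts per frame
#'
#' Geometric criterion: a candidate donor-hydrogen-acceptor triple is
#' counted in a frame iff the donor-acceptor distance is at most `r_cut`
#' and the H-D-A angle (vertex at the donor) is at most `angle_cut` - the
#' common geometric hydrogen-bond convention.
#'
#' @param traj An [atom_trajectory()].
#' @param donor_triples Matrix (or data frame) with 3 columns: donor,
#'   hydrogen, acceptor atom indices.
#' @param r_cut Donor-acceptor cutoff in nm (default 0.35).
#' @param angle_cut H-D-A cutoff in radians (default 30 degrees).
#' @return List with `counts` (per-frame integer vector) and `distribution`
#'   (normalized histogram of the counts, named by count value).
#' @export
hbond_counts <- function(traj, donor_triples, r_cut = 0.35,
                         angle_cut = 30 * pi / 180) {
  stopifnot(inherits(traj, "atom_trajectory"))
  tri <- as.matrix(donor_triples)
  stopifnot(ncol(tri) == 3)
  na <- dim(traj$coords)[2]
  if (any(tri < 1 | tri > na)) stop("triple atom index out of range")
  nf <- dim(traj$coords)[1]
  counts <- vapply(seq_len(nf), function(f) {
    x <- .frame_mat(traj, f)
    n <- 0L
    for (t in seq_len(nrow(tri))) {
      D <- x[tri[t, 1], ]; H <- x[tri[t, 2], ]; A <- x[tri[t, 3], ]
      if (sqrt(sum((D - A)^2)) > r_cut) next
      if (planar_angle(H, D, A) <= angle_cut) n <- n + 1L
    }
    n
  }, integer(1))
  tab <- table(factor(counts, levels = 0:max(counts)))
  list(counts = counts, distribution = as.numeric(tab) / nf,
       values = as.integer(names(tab)))
}

#' Residue-residue contact frequencies
#'
#' Two residues are in contact in a frame iff their minimum heavy-atom pair
#' distance does not exceed `r_cut` (0.35 nm by default).  Frequencies are
#' (frames in contact) / (total frames).  Residue pairs within
#' `exclude_window` of each other in sequence are excluded (default 1, i.e.
#' self and sequence neighbors).
#'
#' @param traj An [atom_trajectory()].
#' @param r_cut Contact cutoff in nm.
#' @param exclude_window Sequence-separation exclusion (default 1).
#' @param heavy_only Exclude hydrogen atoms (names starting with H).
#' @return A `contact_matrix`: symmetric residue x residue frequency matrix
#'   with `NA` on the excluded band, plus the cutoff and frame count.
#' @export
contact_frequency <- function(traj, r_cut = 0.35, exclude_window = 1,
                              heavy_only = TRUE) {
  stopifnot(inherits(traj, "atom_trajectory"))
  keep <- if (heavy_only) !startsWith(traj$atoms$name, "H")
          else rep(TRUE, nrow(traj$atoms))
  resid <- traj$atoms$resid[keep]
  res_levels <- sort(unique(traj$atoms$resid))
  nr <- length(res_levels)
  nf <- dim(traj$coords)[1]
  hits <- matrix(0, nr, nr, dimnames = list(res_levels, res_levels))
  for (f in seq_len(nf)) {
    x <- .frame_mat(traj, f)[keep, , drop = FALSE]
    dmat <- as.matrix(stats::dist(x))
    close <- dmat <= r_cut
    for (a in seq_len(nr - 1)) {
      ia <- which(resid == res_levels[a])
      for (b in (a + 1):nr) {
        if (abs(res_levels[b] - res_levels[a]) <= exclude_window) next
        ib <- which(resid == res_levels[b])
        if (any(close[ia, ib])) {
          hits[a, b] <- hits[a, b] + 1
          hits[b, a] <- hits[b, a] + 1
        }
      }
    }
  }
  freq <- hits / nf
  for (a in seq_len(nr))
    for (b in seq_len(nr))
      if (abs(res_levels[b] - res_levels[a]) <= exclude_window)
        freq[a, b] <- NA_real_
  structure(list(frequency = freq, r_cut = r_cut, n_frames = nf,
                 exclude_window = exclude_window),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  nonzero <- sum(x$frequency > 0, na.rm = TRUE) / 2
  cat(sprintf(paste0("Contact matrix over %d frames (cutoff %.2f nm): ",
                     "%d residue pair(s) in contact\n"),
              x$n_frames, x$r_cut, nonzero))
  invisible(x)
}
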