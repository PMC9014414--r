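#' Wrap angles to the periodic domain
#'
#' Maps angles to \eqn{[-\pi, \pi)}, the half-open convention used by the
#' bias basis and all histograms in the package (\eqn{\pi} maps to
#' \eqn{-\pi}). Idempotent.
#'
#' @param x Numeric vector of angles in radians.
#' @return Wrapped angles in \eqn{[-\pi, \pi)}.
#' @examples
#' wrap_periodic(c(3 * pi / 2, -pi, 7))
#' @export
wrap_periodic <- function(x) {
  y <- (x + pi) %% (2 * pi)
  y - pi
}

#' Signed dihedral (torsion) angle of four points
#'
#' Uses the atan2 formulation with the IUPAC sign convention; the result is
#' wrapped to \eqn{[-\pi, \pi)}, so an exactly trans (antiperiplanar)
#' arrangement reports \eqn{-\pi}.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates (nm).
#' @return Angle in radians in \eqn{[-\pi, \pi)}.
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(cos(0.7), sin(0.7), 1))
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n2 <- sqrt(sum(b2^2))
  if (n2 < 1e-12) stop("degenerate dihedral: p2 and p3 coincide")
  c1 <- .cross3(b1, b2)
  c2 <- .cross3(b2, b3)
  if (sum(c1^2) < 1e-20) stop("degenerate dihedral: p1, p2, p3 collinear")
  if (sum(c2^2) < 1e-20) stop("degenerate dihedral: p2, p3, p4 collinear")
  x <- sum(c1 * c2)
  y <- sum(.cross3(c1, c2) * b2) / n2
  wrap_periodic(atan2(y, x))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Planar (in-plane rotation) angle at a vertex
#'
#' Angle at vertex `b` between the rays `b -> a` and `b -> c`, from the
#' normalized dot product.  Used for the in-plane chromophore rotation
#' observable, with the vertex at the middle listed atom.
#'
#' @param a,b,c Numeric length-3 coordinates (nm).
#' @return Angle in radians in \eqn{[0, \pi]}.
#' @examples
#' planar_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # pi/2
#' @export
planar_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-length ray in planar angle")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct)))
}

#' Collective-variable definition
#'
#' @param kind `"dihedral"` (4 atoms) or `"planar_angle"` (3 atoms).
#' @param atoms Integer atom indices (1-based into the trajectory's atom
#'   list), 4 for a dihedral and 3 for a planar angle.
#' @param label Unique label, e.g. `"phi"`.
#' @return A `cv_definition` object.
#' @export
cv_definition <- function(kind = c("dihedral", "planar_angle"), atoms, label) {
  kind <- match.arg(kind)
  atoms <- as.integer(atoms)
  arity <- if (kind == "dihedral") 4L else 3L
  if (length(atoms) != arity)
    stop(sprintf("'%s' needs %d atom indices, got %d", kind, arity,
                 length(atoms)))
  stopifnot(is.character(label), length(label) == 1)
  structure(list(kind = kind, atoms = atoms, label = label),
            class = "cv_definition")
}

#' Evaluate collective variables along a trajectory
#'
#' @param traj An [atom_trajectory()].
#' @param defs List of [cv_definition()] objects (may be empty).
#' @return A data frame with a `time` column and one column per definition,
#'   plus a zero `bias` column, of class `cv_trajectory` when the
#'   definitions include labels `phi` and `psi`.
#' @export
compute_cv_series <- function(traj, defs) {
  stopifnot(inherits(traj, "atom_trajectory"))
  if (inherits(defs, "cv_definition")) defs <- list(defs)
  labels <- vapply(defs, function(d) d$label, character(1))
  if (anyDuplicated(labels)) stop("CV labels must be unique")
  na <- dim(traj$coords)[2]
  for (d in defs)
    if (any(d$atoms < 1 | d$atoms > na))
      stop("CV atom index out of range")
  nf <- dim(traj$coords)[1]
  out <- data.frame(time = traj$times)
  for (d in defs) {
    vals <- vapply(seq_len(nf), function(f) {
      x <- traj$coords[f, , ]
      if (d$kind == "dihedral")
        dihedral_angle(x[d$atoms[1], ], x[d$atoms[2], ],
                       x[d$atoms[3], ], x[d$atoms[4], ])
      else
        planar_angle(x[d$atoms[1], ], x[d$atoms[2], ], x[d$atoms[3], ])
    }, numeric(1))
    out[[d$label]] <- vals
  }
  out$bias <- rep(0, nf)
  if (all(c("phi", "psi") %in% names(out)))
    class(out) <- c("cv_trajectory", "data.frame")
  out
}
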