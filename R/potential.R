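#' Analytic periodic model potential on the torus
#'
#' Builds a 2\eqn{\pi}-periodic energy surface \eqn{U(\Phi, \Psi)} from a sum
#' of product von Mises wells,
#' \deqn{U(z) = -\sum_i d_i \exp[c_i(\cos(\Phi-\Phi_i) + \cos(\Psi-\Psi_i) - 2)],}
#' optionally plus explicit Fourier terms, shifted so that \eqn{\min U = 0}.
#' The von Mises kernel is smooth and periodic and has an exact analytic
#' gradient, which makes the surface usable as ground truth for every
#' free-energy estimator in the package.
#'
#' @param wells Data frame (or matrix) with columns `phi`, `psi` (well centers
#'   in radians), `depth` (kJ/mol, > 0) and `conc` (dimensionless
#'   concentration, > 0). May be `NULL` for a pure-Fourier potential.
#' @param fourier Optional data frame with columns `k1`, `k2` (integer
#'   wavevector components), `type` (one of `"cc"`, `"cs"`, `"sc"`, `"ss"`,
#'   the cosine/sine factor for each coordinate) and `coef` (kJ/mol).
#' @return An object of class `model_potential`.
#' @seealso [make_four_state_potential()], [evaluate_potential()],
#'   [fes_from_potential()]
#' @examples
#' # U = 10 cos(phi) + 6 cos(psi)
#' p <- model_potential(fourier = data.frame(
#'   k1 = c(1, 0), k2 = c(0, 1), type = "cc", coef = c(10, 6)))
#' evaluate_potential(p, c(0, 0))
#' @export
model_potential <- function(wells = NULL, fourier = NULL) {
  if (is.null(wells) && is.null(fourier))
    stop("at least one of 'wells' and 'fourier' must be given")
  if (!is.null(wells)) {
    wells <- as.data.frame(wells)
    need <- c("phi", "psi", "depth", "conc")
    if (!all(need %in% names(wells)))
      stop("'wells' needs columns phi, psi, depth, conc")
    wells <- wells[need]
    if (any(wells$depth <= 0)) stop("well depths must be positive")
    if (any(wells$conc <= 0)) stop("well concentrations must be positive")
    if (nrow(wells) > 1) {
      ctr <- cbind(wrap_periodic(wells$phi), wrap_periodic(wells$psi))
      for (i in seq_len(nrow(ctr) - 1))
        for (j in (i + 1):nrow(ctr))
          if (.torus_dist(ctr[i, ], ctr[j, ]) < 1e-8)
            stop("well centers must be pairwise distinct on the torus")
    }
  } else {
    wells <- data.frame(phi = numeric(0), psi = numeric(0),
                        depth = numeric(0), conc = numeric(0))
  }
  if (!is.null(fourier)) {
    fourier <- as.data.frame(fourier)
    need <- c("k1", "k2", "type", "coef")
    if (!all(need %in% names(fourier)))
      stop("'fourier' needs columns k1, k2, type, coef")
    fourier <- fourier[need]
    if (!all(fourier$type %in% c("cc", "cs", "sc", "ss")))
      stop("fourier 'type' must be one of cc, cs, sc, ss")
    sin1 <- fourier$type %in% c("sc", "ss") & fourier$k1 == 0
    sin2 <- fourier$type %in% c("cs", "ss") & fourier$k2 == 0
    if (any(sin1 | sin2))
      stop("sine factors require a nonzero wavevector component")
  } else {
    fourier <- data.frame(k1 = numeric(0), k2 = numeric(0),
                          type = character(0), coef = numeric(0))
  }
  p <- structure(list(wells = wells, fourier = fourier, offset = 0),
                 class = "model_potential")
  p$offset <- -.pot_min(p)
  p
}

# fourier data frame -> numeric matrix for the C++ kernels
.fterms_mat <- function(fourier) {
  ty <- match(fourier$type, c("cc", "cs", "sc", "ss"))
  cbind(k1 = as.numeric(fourier$k1), k2 = as.numeric(fourier$k2),
        type = as.numeric(ty), coef = as.numeric(fourier$coef))
}

.wells_mat <- function(wells) {
  cbind(phi = wells$phi, psi = wells$psi, depth = wells$depth,
        conc = wells$conc)
}

.pot_raw_eval <- function(p, z) {
  z <- matrix(z, ncol = 2)
  .pot_eval_core(z, .wells_mat(p$wells), .fterms_mat(p$fourier), p$offset)
}

# locate the unshifted minimum: coarse grid scan + local refinement
.pot_min <- function(p) {
  gr <- seq(-pi, pi, length.out = 241)[-241]
  zz <- as.matrix(expand.grid(phi = gr, psi = gr))
  u <- .pot_raw_eval(p, zz)[, 1]
  z0 <- zz[which.min(u), ]
  fn <- function(z) .pot_raw_eval(p, z)[1, 1]
  grf <- function(z) .pot_raw_eval(p, z)[1, 2:3]
  opt <- stats::optim(z0, fn, grf, method = "BFGS")
  min(opt$value, min(u))
}

#' Four-well potential with the canonical basin layout
#'
#' Convenience constructor for the four-basin surface used throughout the
#' package: middle, vertical, horizontal and corner basins (labels `S_m`,
#' `S_v`, `S_h`, `S_c`) at the default centers (0,0), (0,\eqn{\pi}),
#' (\eqn{\pi},0) and (\eqn{\pi},\eqn{\pi}).
#'
#' @param centers 4 x 2 matrix of basin centers (radians), rows in the order
#'   `S_m`, `S_v`, `S_h`, `S_c`.
#' @param depths Well depths in kJ/mol (recycled to length 4), same order.
#' @param concentrations Well concentrations (recycled to length 4).
#' @return A `model_potential` with a `centers` attribute carrying the
#'   labeled basin centers, usable as a labeling reference downstream.
#' @examples
#' p <- make_four_state_potential()
#' evaluate_potential(p, c(pi, 0))
#' @export
make_four_state_potential <- function(centers = default_state_centers(),
                                      depths = c(30, 20, 28, 15),
                                      concentrations = 6) {
  centers <- as.matrix(centers)
  if (nrow(centers) != 4 || ncol(centers) != 2)
    stop("'centers' must be a 4 x 2 matrix")
  depths <- rep_len(depths, 4)
  concentrations <- rep_len(concentrations, 4)
  p <- model_potential(wells = data.frame(
    phi = centers[, 1], psi = centers[, 2],
    depth = depths, conc = concentrations))
  rc <- centers
  rownames(rc) <- c("S_m", "S_v", "S_h", "S_c")
  attr(p, "centers") <- rc
  p
}

#' Reference centers of the four metastable states
#'
#' @return 4 x 2 matrix with rows `S_m` (0,0), `S_v` (0,\eqn{\pi}), `S_h`
#'   (\eqn{\pi},0), `S_c` (\eqn{\pi},\eqn{\pi}).
#' @export
default_state_centers <- function() {
  m <- rbind(S_m = c(0, 0), S_v = c(0, pi), S_h = c(pi, 0), S_c = c(pi, pi))
  colnames(m) <- c("phi", "psi")
  m
}

#' Phantom photoswitch presets
#'
#' Two calibrated four-well surfaces standing in for the red-resting and
#' far-red-illuminated conformers of a phytochrome-chromophore complex:
#' global amplitudes of 140 (`"pr"`) and 125 (`"pfr"`) kJ/mol and a 25 kJ/mol
#' depth asymmetry of the middle basin `S_m` between the two.  In the
#' `"pr"` surface the deepest basin is `S_h` (the dark-state dihedral
#' geometry) with `S_m` 25 kJ/mol above it; in `"pfr"` the deepest basin is
#' `S_m`.  These presets exercise the full pipeline end-to-end; they are a
#' schematic calibration, not a reconstruction of any atomistic landscape.
#'
#' @param which `"pr"` or `"pfr"`.
#' @return A `model_potential` (see [make_four_state_potential()]).
#' @examples
#' p <- phantom_potential("pfr")
#' global_barrier(fes_from_potential(p, nbins = 50))
#' @export
phantom_potential <- function(which = c("pr", "pfr")) {
  which <- match.arg(which)
  depths <- switch(which,
    pr  = c(S_m = 115, S_v = 112, S_h = 140, S_c = 108),
    pfr = c(S_m = 125, S_v = 100, S_h = 120, S_c = 95))
  make_four_state_potential(depths = depths, concentrations = 6)
}

#' Evaluate a model potential
#'
#' @param p A `model_potential`.
#' @param z Torus point `c(phi, psi)` in radians, or an n x 2 matrix of
#'   points. Points are wrapped to \eqn{[-\pi, \pi)}.
#' @return For a single point, a list with `energy` (kJ/mol) and `gradient`
#'   (kJ/mol/rad, length 2); for a matrix, a list of vectors `energy` and an
#'   n x 2 `gradient` matrix.
#' @examples
#' p <- make_four_state_potential()
#' evaluate_potential(p, c(0, 0))$gradient  # ~ (0, 0) at a well center
#' @export
evaluate_potential <- function(p, z) {
  stopifnot(inherits(p, "model_potential"))
  single <- is.null(dim(z))
  out <- .pot_raw_eval(p, z)
  if (single)
    list(energy = out[1, 1], gradient = out[1, 2:3])
  else
    list(energy = out[, 1], gradient = out[, 2:3, drop = FALSE])
}

# max |grad U| over a grid scan (used by the Langevin stability guard)
.pot_max_grad <- function(p, n = 181) {
  gr <- seq(-pi, pi, length.out = n + 1)[-(n + 1)]
  zz <- as.matrix(expand.grid(gr, gr))
  g <- .pot_raw_eval(p, zz)[, 2:3, drop = FALSE]
  max(sqrt(rowSums(g^2)))
}

#' @export
print.model_potential <- function(x, ...) {
  cat("Periodic model potential on [-pi, pi)^2\n")
  if (nrow(x$wells) > 0) {
    cat(sprintf("  %d von Mises well(s); depths %s kJ/mol\n", nrow(x$wells),
                paste(format(x$wells$depth), collapse = ", ")))
  }
  if (nrow(x$fourier) > 0)
    cat(sprintf("  %d explicit Fourier term(s)\n", nrow(x$fourier)))
  cat(sprintf("  offset %.6g kJ/mol (min U = 0)\n", x$offset))
  invisible(x)
}
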