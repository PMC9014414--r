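#' Statistical weights of biased CV samples
#'
#' Discards a leading burn-in fraction of the series (the adaptive bias, and
#' hence the weights \eqn{e^{\beta V}}, is not yet equilibrated there) and
#' attaches to each remaining sample the umbrella-reweighting weight
#' \eqn{e^{\beta V_t}} computed from the bias recorded at sampling time.
#' Weights are scaled to the range 0 to 1 (division by the maximum over
#' unmasked samples) to avoid numerical overflow.
#'
#' @param traj A `cv_trajectory` with a `bias` column (kJ/mol).
#' @param temperature Temperature in kelvin used for \eqn{\beta}.
#' @param burn_in_fraction Leading fraction of rows to mask (default 0.02).
#' @return A `weighted_samples` object: data frame `samples` (time, phi,
#'   psi, bias, weight, keep) plus `beta` and `burn_in_fraction`.  `weight`
#'   is the scaled weight; masked rows carry their weight but are excluded
#'   from every estimator.
#' @export
compute_weights <- function(traj, temperature = 300, burn_in_fraction = 0.02) {
  stopifnot(is.data.frame(traj))
  if (!all(c("phi", "psi", "bias") %in% names(traj)))
    stop("trajectory must have phi, psi and bias columns")
  stopifnot(burn_in_fraction >= 0, burn_in_fraction < 1)
  n <- nrow(traj)
  n_mask <- floor(burn_in_fraction * n)
  if (n_mask >= n) stop("all samples masked by burn-in")
  keep <- seq_len(n) > n_mask
  beta <- 1 / kT(temperature)
  logw <- beta * traj$bias
  logw_max <- max(logw[keep])
  s <- data.frame(time = if ("time" %in% names(traj)) traj$time else seq_len(n),
                  phi = wrap_periodic(traj$phi), psi = wrap_periodic(traj$psi),
                  bias = traj$bias,
                  weight = exp(logw - logw_max), keep = keep)
  structure(list(samples = s, beta = beta,
                 burn_in_fraction = burn_in_fraction),
            class = "weighted_samples")
}

#' @export
print.weighted_samples <- function(x, ...) {
  cat(sprintf(paste0("Weighted CV samples: %d total, %d after burn-in ",
                     "(fraction %.3g), beta = %.5g mol/kJ\n"),
              nrow(x$samples), sum(x$samples$keep), x$burn_in_fraction,
              x$beta))
  invisible(x)
}

.bin_index <- function(x, nbins) {
  i <- floor((wrap_periodic(x) + pi) / (2 * pi / nbins)) + 1
  pmin(pmax(i, 1), nbins)
}

#' Bin centers of a periodic grid
#' @noRd
.bin_centers <- function(nbins) {
  w <- 2 * pi / nbins
  -pi + w * (seq_len(nbins) - 0.5)
}

#' Reweighted 2D free-energy landscape
#'
#' Accumulates the scaled weights on a regular periodic grid over
#' \eqn{[-\pi,\pi)^2} and converts the weighted histogram
#' \eqn{\hat p(\mathrm{bin})} to \eqn{F = -\beta^{-1}\ln\hat p}, shifted so
#' the deepest finite bin sits exactly at 0 kJ/mol.  Bins with no samples
#' are flagged `NA` and never enter arithmetic.
#'
#' @param ws A [compute_weights()] result.
#' @param nbins Number of bins per axis (default 100).
#' @return A `fes_grid`: matrix `F` (phi in rows), `counts`, bin `centers`,
#'   `beta`, `nbins`.
#' @export
estimate_fes_2d <- function(ws, nbins = 100) {
  stopifnot(inherits(ws, "weighted_samples"))
  s <- ws$samples[ws$samples$keep, ]
  if (nrow(s) == 0) stop("no unmasked samples")
  .fes_from_samples(s$phi, s$psi, s$weight, nbins, ws$beta)
}

.fes_from_samples <- function(phi, psi, w, nbins, beta) {
  i <- .bin_index(phi, nbins)
  j <- .bin_index(psi, nbins)
  idx <- i + nbins * (j - 1)
  mass <- numeric(nbins * nbins)
  acc <- rowsum(w, idx)
  mass[as.integer(rownames(acc))] <- acc
  cnt <- numeric(nbins * nbins)
  acc2 <- rowsum(rep(1, length(idx)), idx)
  cnt[as.integer(rownames(acc2))] <- acc2
  if (all(mass == 0)) stop("zero bins occupied")
  F <- matrix(NA_real_, nbins, nbins)
  occ <- mass > 0
  F[occ] <- -log(mass[occ]) / beta
  F <- F - min(F, na.rm = TRUE)
  structure(list(F = F, counts = matrix(cnt, nbins, nbins),
                 centers = .bin_centers(nbins), beta = beta,
                 nbins = as.integer(nbins)),
            class = "fes_grid")
}

#' Exact bin-averaged free energy of a model potential
#'
#' Ground-truth reference: for each grid bin, the Boltzmann average of
#' \eqn{e^{-\beta U}} over a sub-grid of quadrature points, converted to a
#' free energy and shifted to min 0.  Every sampling-based estimator in the
#' package can be scored against this oracle on the same grid.
#'
#' @param p A [model_potential()].
#' @param nbins Bins per axis.
#' @param temperature Temperature in kelvin.
#' @param subsample Quadrature points per bin per axis (default 5).
#' @return A `fes_grid` (with per-bin `counts` set to `Inf`).
#' @export
fes_from_potential <- function(p, nbins = 100, temperature = 300,
                               subsample = 5) {
  beta <- 1 / kT(temperature)
  w <- 2 * pi / nbins
  off <- (seq_len(subsample) - 0.5) / subsample * w
  fine <- as.vector(outer(-pi + w * (0:(nbins - 1)), off, "+"))
  zz <- as.matrix(expand.grid(phi = fine, psi = fine))
  u <- matrix(.pot_raw_eval(p, zz)[, 1], nrow = length(fine))
  bw <- exp(-beta * (u - min(u)))
  # average the fine grid down to bins
  grp <- rep(seq_len(nbins), times = subsample)
  m1 <- rowsum(bw, grp)              # collapse phi
  m2 <- t(rowsum(t(m1), grp)) / subsample^2
  F <- -log(m2) / beta
  F <- F - min(F)
  dimnames(F) <- NULL
  structure(list(F = F, counts = matrix(Inf, nbins, nbins),
                 centers = .bin_centers(nbins), beta = beta,
                 nbins = as.integer(nbins)),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf(paste0("Free-energy grid %d x %d, %d empty bin(s), ",
                     "barrier %.3f kJ/mol\n"), x$nbins, x$nbins,
              sum(is.na(x$F)), global_barrier(x)))
  invisible(x)
}

#' Marginal free-energy profile along one axis
#'
#' Integrates out the other collective variable through the Boltzmann
#' weights: \eqn{F_1(x) = -\beta^{-1} \ln \sum_y e^{-\beta F(x, y)}\Delta y}
#' over finite bins, re-shifted to min 0.
#'
#' @param fes A `fes_grid`.
#' @param axis `"phi"` or `"psi"`.
#' @return Data frame with the retained coordinate and `F` (kJ/mol);
#'   coordinates whose entire row/column is empty carry `NA`.
#' @export
marginal_profile <- function(fes, axis = c("phi", "psi")) {
  axis <- match.arg(axis)
  stopifnot(inherits(fes, "fes_grid"))
  M <- if (axis == "phi") fes$F else t(fes$F)
  dy <- 2 * pi / fes$nbins
  F1 <- apply(M, 1, function(row) {
    f <- row[is.finite(row)]
    if (length(f) == 0) return(NA_real_)
    -log(sum(exp(-fes$beta * f)) * dy) / fes$beta
  })
  F1 <- F1 - min(F1, na.rm = TRUE)
  out <- data.frame(fes$centers, F1)
  names(out) <- c(axis, "F")
  out
}

#' Global free-energy barrier of a landscape
#'
#' Difference between the highest and lowest finite bins; since landscapes
#' are normalized to min 0, this is simply the finite maximum.
#'
#' @param fes A `fes_grid`.
#' @return Barrier in kJ/mol.
#' @export
global_barrier <- function(fes) {
  stopifnot(inherits(fes, "fes_grid"))
  if (!any(is.finite(fes$F))) stop("no finite bins")
  max(fes$F, na.rm = TRUE) - min(fes$F, na.rm = TRUE)
}

#' Minimax path barrier between two grid bins
#'
#' Over all 4-connected paths on the periodic grid, the minimum of the
#' maximum free energy along the path, minus the free energy of the start
#' bin: the saddle height controlling the activated transition.  Empty bins
#' are impassable.  The saddle value itself is direction-independent; the
#' directed barriers from two basins differ exactly by the difference in
#' their floor energies.
#'
#' @param fes A `fes_grid`.
#' @param start,end Length-2 integer bin indices `c(i, j)`, or length-2
#'   numeric torus points (radians) mapped to bins via [fes_bin()].
#' @return Barrier in kJ/mol (0 when `start == end`).
#' @export
minimax_path_barrier <- function(fes, start, end) {
  stopifnot(inherits(fes, "fes_grid"))
  start <- fes_bin(fes, start)
  end <- fes_bin(fes, end)
  Fs <- fes$F[start[1], start[2]]
  Fe <- fes$F[end[1], end[2]]
  if (!is.finite(Fs) || !is.finite(Fe))
    stop("start and end bins must be finite")
  saddle <- .minimax_core(fes$F, start[1] - 1L, start[2] - 1L,
                          end[1] - 1L, end[2] - 1L)
  if (is.na(saddle))
    stop("end bin unreachable through finite bins")
  saddle - Fs
}

#' Map a torus point to its grid bin
#'
#' @param fes A `fes_grid`.
#' @param z Length-2 numeric point (radians) or, as a pass-through, a
#'   length-2 integer bin index.
#' @return Integer bin index `c(i, j)`.
#' @export
fes_bin <- function(fes, z) {
  if (is.integer(z) || all(z == round(z) & z >= 1 & z <= fes$nbins))
    return(as.integer(z))
  c(.bin_index(z[1], fes$nbins), .bin_index(z[2], fes$nbins))
}

#' Write a free-energy grid as three-column text
#'
#' Layout `phi psi F` in grid-major order (phi varying fastest) with a
#' header describing the grid and \eqn{\beta} - the layout commonly produced
#' by free-energy tools.  Empty bins are written as `nan`.
#'
#' @param fes A `fes_grid`.
#' @param path Output path.
#' @export
write_fes <- function(fes, path) {
  stopifnot(inherits(fes, "fes_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#! FIELDS phi psi free_energy"),
               sprintf("#! SET nbins %d", fes$nbins),
               sprintf("#! SET beta %.17g", fes$beta)), con)
  phi <- rep(fes$centers, times = fes$nbins)
  psi <- rep(fes$centers, each = fes$nbins)
  Fv <- as.vector(fes$F)
  writeLines(sprintf("%s %s %s",
                     formatC(phi, format = "e", digits = 12),
                     formatC(psi, format = "e", digits = 12),
                     ifelse(is.na(Fv), "nan",
                            formatC(Fv, format = "e", digits = 12))), con)
  invisible(path)
}

#' Read a free-energy grid written by [write_fes()]
#'
#' @param path File path.
#' @return A `fes_grid` (counts unavailable, set to `NA`).
#' @export
read_fes <- function(path) {
  lines <- readLines(path)
  nbins <- as.integer(sub(".*nbins ", "", lines[startsWith(lines, "#! SET nbins")]))
  beta <- as.numeric(sub(".*beta ", "", lines[startsWith(lines, "#! SET beta")]))
  body <- lines[!startsWith(lines, "#")]
  parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  Fv <- suppressWarnings(as.numeric(parts[, 3]))
  structure(list(F = matrix(Fv, nbins, nbins),
                 counts = matrix(NA_real_, nbins, nbins),
                 centers = .bin_centers(nbins), beta = beta, nbins = nbins),
            class = "fes_grid")
}
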