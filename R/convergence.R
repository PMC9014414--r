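#' Cumulative free-energy checkpoints
#'
#' For each requested time, estimates the landscape from all unmasked
#' samples recorded up to that time.  The sequence of checkpoints feeds the
#' statistical-distance convergence diagnostic.
#'
#' @param ws A [compute_weights()] result.
#' @param times Increasing checkpoint times within the series; every
#'   checkpoint must lie beyond the end of the burn-in.
#' @param nbins Grid resolution (default 50).
#' @return List of `fes_grid` objects, one per checkpoint.
#' @export
fes_checkpoints <- function(ws, times, nbins = 50) {
  stopifnot(inherits(ws, "weighted_samples"))
  if (is.unsorted(times)) stop("checkpoint times must be increasing")
  s <- ws$samples
  t_burn <- if (any(!s$keep)) max(s$time[!s$keep]) else -Inf
  lapply(times, function(t) {
    if (t <= t_burn)
      stop("checkpoint before the end of the burn-in period")
    sub <- s[s$keep & s$time <= t, ]
    if (nrow(sub) == 0) stop("no samples before checkpoint")
    .fes_from_samples(sub$phi, sub$psi, sub$weight, nbins, ws$beta)
  })
}

#' Statistical distance between two free-energy landscapes
#'
#' Converts each landscape to a probability vector \eqn{p \propto
#' e^{-\beta F}} over the jointly finite bins, renormalizes, and returns the
#' symmetrized Kullback-Leibler (Jeffreys) divergence
#' \eqn{\tfrac12[\mathrm{KL}(p\|q) + \mathrm{KL}(q\|p)]} in nats.
#' Jensen-Shannon is available as an alternative symmetrization.
#'
#' @param fes_a,fes_b `fes_grid`s on identical grids with identical
#'   \eqn{\beta}.
#' @param method `"jeffreys"` (default) or `"jensen_shannon"`.
#' @return Non-negative dimensionless distance; zero iff the induced
#'   probability vectors are equal.
#' @export
statistical_distance <- function(fes_a, fes_b,
                                 method = c("jeffreys", "jensen_shannon")) {
  method <- match.arg(method)
  stopifnot(inherits(fes_a, "fes_grid"), inherits(fes_b, "fes_grid"))
  if (fes_a$nbins != fes_b$nbins) stop("grids differ")
  if (!isTRUE(all.equal(fes_a$beta, fes_b$beta)))
    stop("landscapes computed at different temperatures")
  ok <- is.finite(fes_a$F) & is.finite(fes_b$F)
  if (!any(ok)) stop("no jointly finite bins")
  p <- exp(-fes_a$beta * fes_a$F[ok])
  q <- exp(-fes_b$beta * fes_b$F[ok])
  p <- p / sum(p)
  q <- q / sum(q)
  kl <- function(a, b) sum(a * log(a / b))
  if (method == "jeffreys") {
    0.5 * (kl(p, q) + kl(q, p))
  } else {
    m <- (p + q) / 2
    0.5 * (kl(p, m) + kl(q, m))
  }
}

#' Convergence series with plateau detection
#'
#' Computes the statistical distance of each checkpoint to its predecessor
#' and searches for a plateau: the earliest checkpoint from which, through
#' the end of the series, every sliding window of `window` consecutive
#' distance increments has mean absolute slope below `slope_tol` *and* the
#' sampled support is stable (the occupied-bin fraction grows by at most a
#' relative `coverage_tol` across the window).  The support condition keeps
#' a landscape whose explored region is still expanding - e.g. a run still
#' filling its first basin - from being declared converged merely because
#' the estimate over the already-visited region has stabilized.
#'
#' @param checkpoints List of `fes_grid`s (>= 3).
#' @param times Checkpoint times (same length).
#' @param window Sliding-window length in checkpoints (default 5).
#' @param slope_tol Tolerance on the mean absolute per-checkpoint change of
#'   the distance (default 0.01, nats per checkpoint).
#' @param coverage_tol Maximum allowed relative change of the occupied-bin
#'   fraction across a window (default 0.05, i.e. the support must be stable
#'   to within 5 percent).
#' @param method Distance symmetrization, see [statistical_distance()].
#' @return A `convergence_series`: data frame (`time`, `distance`) starting
#'   at the second checkpoint, `plateau_time` (`NA` when none), `window`,
#'   `slope_tol`, `coverage_tol` and the per-checkpoint `coverage`.
#' @export
convergence_series <- function(checkpoints, times, window = 5,
                               slope_tol = 0.01, coverage_tol = 0.05,
                               method = c("jeffreys", "jensen_shannon")) {
  method <- match.arg(method)
  n <- length(checkpoints)
  if (n < 3) stop("need at least 3 checkpoints")
  if (length(times) != n) stop("times and checkpoints differ in length")
  if (window > n - 1) stop("window longer than the distance series")
  d <- vapply(2:n, function(i)
    statistical_distance(checkpoints[[i - 1]], checkpoints[[i]],
                         method = method), numeric(1))
  coverage <- vapply(checkpoints, function(f) mean(is.finite(f$F)),
                     numeric(1))
  td <- times[-1]
  slopes <- abs(diff(d))
  plateau <- NA_real_
  if (length(slopes) >= window) {
    wm <- vapply(seq_len(length(slopes) - window + 1), function(j) {
      cv <- coverage[j:min(n, j + window + 1)]
      c(mean(slopes[j:(j + window - 1)]), (max(cv) - min(cv)) / max(cv))
    }, numeric(2))
    ok <- wm[1, ] < slope_tol & wm[2, ] <= coverage_tol
    ok <- rev(cumprod(rev(ok))) > 0  # window j..end all compliant
    j <- which(ok)[1]
    if (!is.na(j)) plateau <- td[j]
  }
  structure(list(series = data.frame(time = td, distance = d),
                 plateau_time = plateau, window = as.integer(window),
                 slope_tol = slope_tol, coverage_tol = coverage_tol,
                 coverage = coverage, method = method),
            class = "convergence_series")
}

#' @export
print.convergence_series <- function(x, ...) {
  cat(sprintf("Convergence series over %d checkpoints\n", nrow(x$series) + 1))
  if (is.na(x$plateau_time))
    cat("  no plateau detected\n")
  else
    cat(sprintf("  plateau reached at time %s\n", format(x$plateau_time)))
  invisible(x)
}

#' Landscape variability over a window of checkpoints
#'
#' Per-bin standard deviation of the free energy across the last `window`
#' checkpoints (population standard deviation over jointly finite bins),
#' averaged over bins: a kJ/mol-scale summary of how much the landscape
#' still moves.
#'
#' @param checkpoints List of `fes_grid`s.
#' @param window Number of trailing checkpoints to use (default: all).
#' @return Mean per-bin standard deviation in kJ/mol.
#' @export
fes_variability <- function(checkpoints, window = length(checkpoints)) {
  n <- length(checkpoints)
  stopifnot(window >= 2, window <= n)
  use <- checkpoints[(n - window + 1):n]
  mats <- lapply(use, function(f) f$F)
  ok <- Reduce(`&`, lapply(mats, is.finite))
  if (!any(ok)) stop("no jointly finite bins")
  vals <- vapply(mats, function(m) m[ok], numeric(sum(ok)))
  vals <- matrix(vals, nrow = sum(ok))
  mu <- rowMeans(vals)
  sdpop <- sqrt(rowMeans((vals - mu)^2))
  mean(sdpop)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used to build circular fixtures and by
#' the bootstrap coverage checks.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0; 0 gives the uniform circle).
#' @return Angles in \eqn{[-\pi, \pi)}.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrap_periodic(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16, ceiling((n - length(out)) * 1.5))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  wrap_periodic(mu + out[seq_len(n)])
}

#' Circular mean
#'
#' @param values Angles in radians.
#' @return `atan2(mean sin, mean cos)`, in \eqn{[-\pi, \pi)}.
#' @export
circular_mean <- function(values) {
  s <- mean(sin(values))
  c <- mean(cos(values))
  if (sqrt(s^2 + c^2) < 1e-10)
    stop("mean resultant length ~ 0: circular mean undefined")
  wrap_periodic(atan2(s, c))
}

#' Bootstrap estimate of a circular mean
#'
#' Percentile bootstrap on the circular mean: resampled means are wrapped
#' around the point estimate before taking quantiles so that the interval
#' is seam-safe.
#'
#' @param values Angles in radians (non-empty).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return List with `mean`, `ci` (length 2, wrapped), `half_width`
#'   (half the CI width in radians) and `spread` (circular standard
#'   deviation of the data).
#' @export
bootstrap_circular <- function(values, n_boot = 2000, ci_level = 0.95,
                               seed = NULL) {
  n <- length(values)
  if (n == 0) stop("empty sample")
  if (!is.null(seed)) set.seed(seed)
  est <- circular_mean(values)
  sv <- sin(values)
  cv <- cos(values)
  idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
  bm <- atan2(rowMeans(matrix(sv[idx], n_boot, n)),
              rowMeans(matrix(cv[idx], n_boot, n)))
  delta <- wrap_periodic(bm - est)
  a <- (1 - ci_level) / 2
  qs <- quantile(delta, c(a, 1 - a), names = FALSE, type = 7)
  R <- sqrt(mean(sv)^2 + mean(cv)^2)
  list(mean = est,
       ci = wrap_periodic(est + qs),
       half_width = (qs[2] - qs[1]) / 2,
       spread = sqrt(-2 * log(R)))
}

#' Count modes of a circular distribution
#'
#' Builds a wrap-aware circular histogram (relative frequencies) and counts
#' peaks whose topographic prominence exceeds a threshold; prominence of a
#' peak is its height minus the higher of the two minima separating it from
#' higher terrain (walking circularly in both directions).
#'
#' @param values Angles in radians (non-empty).
#' @param bins Histogram bins (default 36).
#' @param min_prominence Prominence threshold in relative-frequency units
#'   (default 0.02).
#' @return Integer number of modes.
#' @export
count_modes <- function(values, bins = 36, min_prominence = 0.02) {
  if (length(values) == 0) stop("empty sample")
  h <- tabulate(.bin_index(values, bins), nbins = bins) / length(values)
  n <- bins
  nxt <- function(i, d) ((i - 1 + d) %% n) + 1
  n_modes <- 0
  for (i in seq_len(n)) {
    if (h[i] < h[nxt(i, 1)] || h[i] < h[nxt(i, -1)]) next
    if (h[i] == h[nxt(i, -1)] && h[nxt(i, -1)] > 0) {
      # plateau: count only the first bin of the plateau
      next
    }
    prom_side <- function(d) {
      lo <- h[i]
      j <- i
      for (k in seq_len(n - 1)) {
        j <- nxt(j, d)
        if (h[j] > h[i]) return(h[i] - lo)
        lo <- min(lo, h[j])
      }
      h[i] - lo  # no higher terrain: global peak, full drop
    }
    prom <- min(prom_side(1), prom_side(-1))
    # global maximum: prominence is drop to the global minimum
    if (h[i] == max(h)) prom <- h[i] - min(h)
    if (prom >= min_prominence) n_modes <- n_modes + 1
  }
  n_modes
}
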