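test_that("statistical distance is a symmetric premetric with known values", {
  nb <- 20
  A <- as_fes(matrix(runif(nb * nb, 0, 10), nb, nb) - 0)
  expect_equal(statistical_distance(A, A), 0)
  set.seed(17)
  B <- as_fes(matrix(runif(nb * nb, 0, 10), nb, nb))
  expect_equal(statistical_distance(A, B), statistical_distance(B, A))
  expect_gt(statistical_distance(A, B), 0)
  # hand-computable two-bin case: p = (0.7, 0.3), q = (0.5, 0.5)
  beta <- 1 / kT(300)
  mk <- function(p) {
    F <- -log(p) / beta
    as_fes(matrix(F - min(F), 2, 1), beta = beta)
  }
  d <- statistical_distance(mk(c(0.7, 0.3)), mk(c(0.5, 0.5)))
  want <- 0.5 * (0.7 * log(0.7 / 0.5) + 0.3 * log(0.3 / 0.5) +
                   0.5 * log(0.5 / 0.7) + 0.5 * log(0.5 / 0.3))
  expect_equal(d, want, tolerance = 1e-12)
  # zero iff the induced probability vectors coincide
  expect_gt(d, 0)
  shifted <- A
  shifted$F <- shifted$F + 0  # identical
  expect_identical(statistical_distance(A, shifted), 0)
  expect_error(statistical_distance(A, as_fes(matrix(0, 5, 5))), "differ")
})

test_that("checkpoints accumulate samples up to each time", {
  fx <- fixture_converged_run()
  ws <- fx$ws
  tmax <- max(ws$samples$time)
  tburn <- max(ws$samples$time[!ws$samples$keep])
  cks <- fes_checkpoints(ws, c(tmax / 2, tmax, tmax), nbins = 50)
  # final checkpoint equals the full estimate; duplicate times identical
  expect_equal(cks[[2]]$F, fx$fes$F)
  expect_identical(cks[[2]]$F, cks[[3]]$F)
  expect_error(fes_checkpoints(ws, c(tburn / 2, tmax), nbins = 50),
               "burn-in")
  expect_error(fes_checkpoints(ws, c(tmax, tmax / 2), nbins = 50),
               "increasing")
})

test_that("plateau detection follows the slope and coverage rules", {
  # constant series -> plateau at the first eligible checkpoint
  nb <- 10
  base <- as_fes(matrix(runif(100, 0, 5), nb, nb))
  cks <- rep(list(base), 10)
  times <- seq_len(10)
  cs <- convergence_series(cks, times, window = 3, slope_tol = 0.01)
  expect_equal(cs$plateau_time, 2)
  expect_true(all(cs$series$distance == 0))
  # strictly growing distances -> no plateau
  cks2 <- lapply(seq_len(10), function(i) {
    f <- base
    f$F <- base$F * (1 + 0.5 * i^2)  # accelerating change
    f
  })
  cs2 <- convergence_series(cks2, times, window = 3, slope_tol = 0.001)
  expect_true(is.na(cs2$plateau_time))
  # exponential decay with known rate: first compliant window is where the
  # analytic mean |slope| of the distance series drops below tolerance
  lam <- 0.5
  cks3 <- lapply(seq_len(12), function(i) {
    f <- base
    f$F <- base$F * (1 + exp(-lam * i))
    f
  })
  cs3 <- convergence_series(cks3, seq_len(12), window = 3, slope_tol = 1e-4)
  d <- cs3$series$distance
  sl <- abs(diff(d))
  wm <- vapply(seq_len(length(sl) - 2), function(j) mean(sl[j:(j + 2)]),
               numeric(1))
  ok <- rev(cumprod(rev(wm < 1e-4))) > 0
  expect_equal(cs3$plateau_time, cs3$series$time[which(ok)[1]])
  expect_error(convergence_series(cks[1:2], 1:2), "at least 3")
  expect_error(convergence_series(cks, times, window = 20), "window")
})

test_that("converged runs plateau and truncated runs do not", {
  fx <- fixture_converged_run()
  ws <- fx$ws
  tmax <- max(ws$samples$time)
  tburn <- max(ws$samples$time[!ws$samples$keep])
  ck_times <- seq(tburn, tmax, length.out = 26)[-1]
  cs <- convergence_series(fes_checkpoints(ws, ck_times, nbins = 50),
                           ck_times)
  expect_false(is.na(cs$plateau_time))

  tr <- fixture_truncated_run()
  traj <- tr$run$trajectory
  # genuinely truncated: no inter-basin transition ever occurred
  expect_true(all(abs(traj$phi) < pi / 2 & abs(traj$psi) < pi / 2))
  wst <- compute_weights(traj)
  tmt <- max(wst$samples$time)
  tbt <- max(wst$samples$time[!wst$samples$keep])
  ckt <- seq(tbt, tmt, length.out = 13)[-1]
  cst <- convergence_series(fes_checkpoints(wst, ckt, nbins = 50), ckt)
  expect_true(is.na(cst$plateau_time))
})

test_that("late-stage distance to uniform is non-increasing when converged", {
  # block histograms of the biased run drift monotonically toward uniform
  fx <- fixture_converged_run()
  tr <- fx$run$trajectory
  n <- nrow(tr)
  blocks <- split(seq_len(n), cut(seq_len(n), 8, labels = FALSE))
  kl_uniform <- function(rows) {
    h <- tabulate(.bin <- (floor((tr$phi[rows] + pi) / (2 * pi / 8)) +
                             8 * floor((tr$psi[rows] + pi) / (2 * pi / 8))) + 1,
                  nbins = 64)
    p <- (h + 0.5) / sum(h + 0.5)
    sum(p * log(p * 64))
  }
  d <- vapply(blocks, kl_uniform, numeric(1))
  late <- d[5:8]
  # allow a small noise band on top of monotone decrease
  expect_true(all(diff(late) < 0.05))
  expect_lt(late[4], d[1])
})

test_that("fes variability measures the checkpoint spread in kJ/mol", {
  nb <- 10
  base <- as_fes(matrix(runif(100, 0, 5), nb, nb))
  expect_equal(fes_variability(list(base, base, base)), 0)
  # two checkpoints differing by a constant c: population sd = c / 2
  up <- base
  up$F <- base$F + 1.5
  expect_equal(fes_variability(list(base, up)), 0.75)
  # three hand-made 2 x 2 grids
  g1 <- as_fes(matrix(c(0, 1, 2, 3), 2, 2))
  g2 <- as_fes(matrix(c(1, 1, 2, 5), 2, 2))
  g3 <- as_fes(matrix(c(2, 1, 2, 4), 2, 2))
  vals <- cbind(c(0, 1, 2, 3), c(1, 1, 2, 5), c(2, 1, 2, 4))
  want <- mean(apply(vals, 1, function(x) sqrt(mean((x - mean(x))^2))))
  expect_equal(fes_variability(list(g1, g2, g3)), want)
  expect_error(fes_variability(list(base)), "window")
})

test_that("circular means and bootstrap intervals are wrap-correct", {
  expect_error(circular_mean(c(0, pi)), "undefined")
  # values straddling the seam average to +/- pi, not 0
  m <- circular_mean(c(pi - 0.1, -pi + 0.1))
  expect_lt(abs(abs(m) - pi), 1e-9)
  bc <- bootstrap_circular(rep(1.2, 50), n_boot = 200, seed = 1)
  expect_equal(bc$mean, 1.2)
  expect_equal(bc$half_width, 0, tolerance = 1e-12)
  set.seed(18)
  v <- rvonmises(500, 2.5, 4)
  bc2 <- bootstrap_circular(v, n_boot = 500, seed = 2)
  expect_lt(abs(bc2$mean - 2.5), 0.2)
  expect_gt(bc2$half_width, 0)
  # seeded reproducibility
  bc3 <- bootstrap_circular(v, n_boot = 500, seed = 2)
  expect_identical(bc2, bc3)
})

test_that("bootstrap CI half-width shrinks like 1/sqrt(n)", {
  set.seed(19)
  hw <- vapply(c(100, 400, 1600), function(n)
    bootstrap_circular(rvonmises(n, 2.5, 4), n_boot = 1000, seed = n)$half_width,
    numeric(1))
  expect_lt(abs(hw[1] / hw[2] - 2) / 2, 0.2)
  expect_lt(abs(hw[2] / hw[3] - 2) / 2, 0.2)
})

test_that("mode counting is prominence-aware and wrap-aware", {
  set.seed(20)
  expect_equal(count_modes(rvonmises(4000, 2.5, 8), bins = 36,
                           min_prominence = 0.02), 1)
  two <- c(rvonmises(2000, 2.5, 8), rvonmises(2000, 2.7 - pi, 8))
  expect_equal(count_modes(two, bins = 36, min_prominence = 0.02), 2)
  # uniform sample under a strict prominence threshold
  expect_equal(count_modes(runif(4000, -pi, pi), bins = 36,
                           min_prominence = 0.05), 0)
  # a mode straddling the seam is one mode, not two
  expect_equal(count_modes(rvonmises(4000, pi, 8), bins = 36,
                           min_prominence = 0.02), 1)
})

test_that("von Mises sampler matches the target density", {
  set.seed(21)
  v <- rvonmises(2e4, 0.8, 3)
  h <- tabulate(.bin_index <- floor((v - 0.8 + pi) %% (2 * pi) / (2 * pi / 24)) + 1,
                nbins = 24)
  th <- -pi + 2 * pi / 24 * (seq_len(24) - 0.5)
  dens <- exp(3 * cos(th))
  dens <- dens / sum(dens)
  chi <- sum((h - 2e4 * dens)^2 / (2e4 * dens))
  # chi-squared with 23 dof: stay below the 0.001 quantile
  expect_lt(chi, stats::qchisq(0.999, 23))
})
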