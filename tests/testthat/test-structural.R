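test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(22)
  ref <- matrix(rnorm(30), 10, 3)
  # identity
  tr <- kabsch_superpose(ref, ref)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tr$translation, numeric(3), tolerance = 1e-10)
  # 90 degree rotation about z plus a shift
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  mob <- ref %*% t(Rz) + matrix(c(1, -2, 0.5), 10, 3, byrow = TRUE)
  tr2 <- kabsch_superpose(mob, ref)
  fitted <- apply_transform(mob, tr2)
  expect_lt(sqrt(mean(rowSums((fitted - ref)^2))), 1e-9)
  expect_equal(det(tr2$rotation), 1, tolerance = 1e-10)
})

test_that("reflections are never fit: rotation stays proper", {
  set.seed(23)
  ref <- matrix(rnorm(24), 8, 3)
  mirrored <- ref %*% diag(c(-1, 1, 1))
  tr <- kabsch_superpose(mirrored, ref)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
  fitted <- apply_transform(mirrored, tr)
  expect_gt(sqrt(mean(rowSums((fitted - ref)^2))), 1e-3)
  # degenerate fit sets are refused
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate|collinear")
})

test_that("rmsd series vanishes for rigid motions and scales with a shift", {
  spec <- toy_protein_spec(n_residues = 8, n_frames = 6)
  traj <- make_toy_protein_trajectory(spec)
  expect_equal(rmsd_series(traj), rep(0, 6), tolerance = 1e-12)
  # rigidly transformed copies superpose to zero
  set.seed(24)
  for (f in 2:6) {
    tr <- random_rigid()
    traj$coords[f, , ] <- apply_transform(traj$coords[1, , ], tr)
  }
  expect_lt(max(rmsd_series(traj)), 1e-9)
  # one measured atom displaced by delta with fit atoms untouched
  delta <- 0.4
  n_measure <- 4
  traj2 <- make_toy_protein_trajectory(spec)
  traj2$coords[3, 24, 1] <- traj2$coords[3, 24, 1] + delta
  r <- rmsd_series(traj2, fit_indices = 1:12, measure_indices = 21:24)
  expect_equal(r[3], sqrt(delta^2 / n_measure), tolerance = 1e-9)
  expect_equal(r[1], 0)
})

test_that("rmsf reflects planted mobility", {
  spec0 <- toy_protein_spec(n_residues = 6, n_frames = 5, mobile_sigma = 0)
  frozen <- make_toy_protein_trajectory(spec0)
  expect_true(all(rmsf_per_residue(frozen)$rmsf == 0))
  # isotropic jitter sigma on one residue: per-atom RMSF -> sigma * sqrt(3)
  sigma <- 0.05
  spec <- toy_protein_spec(n_residues = 6, n_frames = 2000,
                           mobile_residues = 4, mobile_sigma = sigma)
  traj <- make_toy_protein_trajectory(spec, seed = 25)
  fit <- which(traj$atoms$resid != 4)
  rmsf <- rmsf_per_residue(traj, fit_indices = fit)
  expect_lt(abs(rmsf$rmsf[rmsf$resid == 4] - sigma * sqrt(3)) /
              (sigma * sqrt(3)), 0.05)
  # planted mobile region carries the strictly largest values
  expect_true(all(rmsf$rmsf[rmsf$resid == 4] >
                    max(rmsf$rmsf[rmsf$resid != 4]) + 0.01))
})

test_that("hydrogen bonds follow the geometric criterion exactly", {
  spec <- toy_protein_spec(
    n_residues = 10, n_frames = 10,
    hbonds = list(list(donor = 3, hydrogen = 6, acceptor = 9,
                       distance = 0.28, fraction = 1),
                  list(donor = 12, hydrogen = 15, acceptor = 18,
                       distance = 0.36, fraction = 1)))
  traj <- make_toy_protein_trajectory(spec)
  triples <- rbind(c(3, 6, 9), c(12, 15, 18))
  hb <- hbond_counts(traj, triples, r_cut = 0.35)
  # ideal linear geometry at 0.28 nm counted, 0.36 nm beyond cutoff never
  expect_equal(hb$counts, rep(1L, 10))
  # brute-force all-triples oracle on randomized frames
  set.seed(26)
  rnd <- make_toy_protein_trajectory(toy_protein_spec(n_residues = 10,
                                                      n_frames = 20))
  rnd$coords <- rnd$coords + array(rnorm(length(rnd$coords), sd = 0.15),
                                   dim = dim(rnd$coords))
  tri <- cbind(sample(1:30, 12), sample(1:30, 12), sample(1:30, 12))
  ok <- tri[, 1] != tri[, 2] & tri[, 2] != tri[, 3] & tri[, 1] != tri[, 3]
  tri <- tri[ok, , drop = FALSE]
  got <- hbond_counts(rnd, tri, r_cut = 0.5, angle_cut = 1.0)
  brute <- vapply(seq_len(20), function(f) {
    x <- matrix(rnd$coords[f, , ], ncol = 3)
    n <- 0L
    for (t in seq_len(nrow(tri))) {
      D <- x[tri[t, 1], ]; H <- x[tri[t, 2], ]; A <- x[tri[t, 3], ]
      dda <- sqrt(sum((D - A)^2))
      u <- H - D; v <- A - D
      ang <- acos(min(1, max(-1, sum(u * v) /
                               sqrt(sum(u^2) * sum(v^2)))))
      if (dda <= 0.5 && ang <= 1.0) n <- n + 1L
    }
    n
  }, integer(1))
  expect_identical(got$counts, brute)
  expect_equal(sum(got$distribution), 1)
})

test_that("contact frequencies count planted contacts exactly", {
  spec <- toy_protein_spec(
    n_residues = 12, n_frames = 10,
    contacts = list(list(i = 2, j = 29, distance = 0.30, fraction = 0.7)))
  traj <- make_toy_protein_trajectory(spec)
  cm <- contact_frequency(traj)
  expect_equal(cm$frequency["1", "10"], 0.7)
  expect_equal(cm$frequency["10", "1"], 0.7)
  # always-distant pair and excluded neighbours
  expect_equal(cm$frequency["3", "8"], 0)
  expect_true(is.na(cm$frequency["4", "5"]))
  # permanent contact
  spec2 <- toy_protein_spec(n_residues = 12, n_frames = 10,
                            contacts = list(list(i = 2, j = 29,
                                                 distance = 0.30)))
  cm2 <- contact_frequency(make_toy_protein_trajectory(spec2))
  expect_equal(cm2$frequency["1", "10"], 1.0)
  expect_true(isSymmetric(unname(cm2$frequency)))
})

test_that("contact maps agree with a brute-force oracle on random frames", {
  set.seed(27)
  traj <- make_toy_protein_trajectory(toy_protein_spec(n_residues = 8,
                                                       n_frames = 15))
  traj$coords <- traj$coords + array(rnorm(length(traj$coords), sd = 0.25),
                                     dim = dim(traj$coords))
  cm <- contact_frequency(traj, r_cut = 0.6, exclude_window = 1)
  res <- sort(unique(traj$atoms$resid))
  brute <- matrix(0, 8, 8)
  for (f in 1:15) {
    x <- matrix(traj$coords[f, , ], ncol = 3)
    for (a in 1:7) for (b in (a + 1):8) {
      if (b - a <= 1) next
      ia <- which(traj$atoms$resid == res[a])
      ib <- which(traj$atoms$resid == res[b])
      dmin <- min(vapply(ia, function(i)
        min(sqrt(colSums((t(x[ib, , drop = FALSE]) - x[i, ])^2))),
        numeric(1)))
      if (dmin <= 0.6) {
        brute[a, b] <- brute[a, b] + 1
        brute[b, a] <- brute[b, a] + 1
      }
    }
  }
  brute <- brute / 15
  comparable <- !is.na(cm$frequency)
  expect_equal(unname(cm$frequency[comparable]), brute[comparable])
})

test_that("structural observables are invariant under global rigid motion", {
  set.seed(28)
  spec <- toy_protein_spec(
    n_residues = 8, n_frames = 8, mobile_residues = 5, mobile_sigma = 0.03,
    contacts = list(list(i = 2, j = 20, distance = 0.3, fraction = 0.5)))
  traj <- make_toy_protein_trajectory(spec, seed = 29)
  tr <- random_rigid()
  moved <- traj
  for (f in 1:8) moved$coords[f, , ] <- apply_transform(traj$coords[f, , ], tr)
  expect_equal(rmsd_series(moved, reference = traj$coords[1, , ]),
               rmsd_series(traj), tolerance = 1e-9)
  expect_equal(rmsf_per_residue(moved)$rmsf, rmsf_per_residue(traj)$rmsf,
               tolerance = 1e-9)
  cm1 <- contact_frequency(traj)
  cm2 <- contact_frequency(moved)
  expect_equal(cm1$frequency, cm2$frequency)
  hb1 <- hbond_counts(traj, rbind(c(1, 2, 3)))
  hb2 <- hbond_counts(moved, rbind(c(1, 2, 3)))
  expect_identical(hb1$counts, hb2$counts)
})
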