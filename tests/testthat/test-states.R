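test_that("weight sieving keeps exactly the samples above the cutoff", {
  traj <- data.frame(time = 1:3, phi = c(0, 1, 2), psi = 0,
                     bias = kT(300) * log(c(1, 0.5, 0.1)))
  ws <- compute_weights(traj, burn_in_fraction = 0)
  # cutoff kT ln 2 keeps weights {1, 0.5}, drops 0.1
  sub <- select_high_weight(ws, kT(300) * log(2) + 1e-9)
  expect_equal(sub$samples$index, c(1, 2))
  # very large cutoff keeps everything
  expect_equal(nrow(select_high_weight(ws, 1e6)$samples), 3)
  # cutoff below the gap to the second-highest keeps only the maximum
  sub2 <- select_high_weight(ws, 0.5)
  expect_equal(sub2$samples$index, 1)
  expect_error(select_high_weight(compute_weights(
    data.frame(time = 1, phi = 0, psi = 0, bias = 0), burn_in = 0), -1),
    "fe_cutoff")
})

test_that("clustering separates four tight blobs and respects the seam", {
  set.seed(15)
  centers <- default_state_centers()
  n <- 200
  comp <- rep(1:4, each = n)
  traj <- data.frame(
    time = seq_len(4 * n),
    phi = wrap_periodic(centers[comp, 1] + rvonmises(4 * n, 0, 120)),
    psi = wrap_periodic(centers[comp, 2] + rvonmises(4 * n, 0, 120)),
    bias = 0)
  ws <- compute_weights(traj, burn_in_fraction = 0)
  set <- cluster_states(select_high_weight(ws, 100), toroidal_eps = 0.5,
                        min_members = 10)
  expect_length(set$states, 4)
  # memberships exactly match the generating components
  got <- lapply(set$states, function(s) sort(s$members))
  want <- split(seq_len(4 * n), comp)
  for (g in got)
    expect_true(any(vapply(want, identical, logical(1), y = g)))
  # blobs at S_h and S_c straddle the phi = +/-pi seam: one cluster each,
  # centroid at the seam rather than two half-clusters
  seam <- set$states[vapply(set$states, function(s)
    abs(abs(s$centroid[1]) - pi) < 0.2, logical(1))]
  expect_length(seam, 2)
  # single blob -> single cluster
  one <- data.frame(time = 1:300, phi = rvonmises(300, 1, 60),
                    psi = rvonmises(300, -1, 60), bias = 0)
  ws1 <- compute_weights(one, burn_in_fraction = 0)
  expect_length(cluster_states(select_high_weight(ws1, 100), 0.5, 10)$states,
                1)
})

test_that("labeling maps clusters to nearest references, resolving clashes", {
  mk_set <- function(centroids) {
    states <- lapply(seq_len(nrow(centroids)), function(i)
      structure(list(label = "unassigned", members = i,
                     centroid = centroids[i, ], free_energy = NA_real_,
                     count = 1), class = "metastable_state"))
    structure(list(states = states, unassigned = integer(0),
                   beta = 1 / kT(300), eps = 0.35, min_members = 1),
              class = "state_set")
  }
  # exact hits
  set <- label_states(mk_set(rbind(c(pi, pi), c(0, 0))))
  labs <- vapply(set$states, function(s) s$label, character(1))
  expect_equal(labs, c("S_c", "S_m"))
  # permuting input order leaves the labeling invariant
  set2 <- label_states(mk_set(rbind(c(0, 0), c(pi, pi))))
  labs2 <- vapply(set2$states, function(s) s$label, character(1))
  expect_equal(labs2, c("S_m", "S_c"))
  # two clusters nearest S_m: the closer keeps it, the other takes its
  # next-nearest free label (S_v at (0, pi))
  set3 <- label_states(mk_set(rbind(c(0.1, 0.4), c(0, 0))))
  labs3 <- vapply(set3$states, function(s) s$label, character(1))
  expect_equal(labs3, c("S_v", "S_m"))
})

test_that("state free energies follow weight shares and the sign contract", {
  # two states with weight ratio 2:1 -> shallower at kT ln 2
  traj <- boltzmann_mixture(3e5, rbind(c(0, 0), c(pi, 0)), c(2, 1) / 3)
  ws <- compute_weights(traj, burn_in_fraction = 0)
  set <- cluster_states(select_high_weight(ws, 100), 0.5, 10)
  set <- state_free_energy(ws, set)
  F <- sort(vapply(set$states, function(s) s$free_energy, numeric(1)))
  expect_equal(F[1], 0)
  expect_lt(abs(F[2] - kT(300) * log(2)), 0.05)
  # single state containing everything -> 0
  one <- boltzmann_mixture(1000, rbind(c(0, 0)), 1)
  ws1 <- compute_weights(one, burn_in_fraction = 0)
  set1 <- state_free_energy(ws1, cluster_states(
    select_high_weight(ws1, 100), 0.5, 10))
  expect_equal(set1$states[[1]]$free_energy, 0)
})

test_that("state differences compare labels across landscapes", {
  # in A the middle state sits 5 kJ/mol above S_h; in B it is deepened by
  # construction to the same level as S_h, i.e. its relative F is 5 lower
  r <- exp(-5 / kT(300))
  mix_a <- boltzmann_mixture(2e5, default_state_centers()[c(1, 3), ],
                             c(r, 1) / (r + 1))
  mix_b <- boltzmann_mixture(2e5, default_state_centers()[c(1, 3), ],
                             c(0.5, 0.5))
  setup <- function(traj) {
    ws <- compute_weights(traj, burn_in_fraction = 0)
    set <- cluster_states(select_high_weight(ws, 100), 0.5, 10)
    state_free_energy(ws, label_states(set))
  }
  sa <- setup(mix_a)
  sb <- setup(mix_b)
  d <- state_fe_difference(sa, sb)
  expect_setequal(names(d), c("S_m", "S_h"))
  # S_m more populated in B -> positive difference of about +5
  expect_lt(abs(d[["S_m"]] - 5), 0.2)
  expect_lt(abs(d[["S_h"]]), 0.2)
  # sign contract: the state more populated in A gets a negative value
  expect_gt(d[["S_m"]], 0)
  # identical landscapes -> zero for all labels
  d0 <- state_fe_difference(sa, sa)
  expect_true(all(abs(d0) < 1e-12))
})

test_that("clusters joined by a sub-threshold saddle merge into one state", {
  # two blobs 0.9 rad apart on a landscape whose saddle between them is low
  set.seed(16)
  n <- 300
  traj <- data.frame(
    time = seq_len(2 * n),
    phi = wrap_periodic(c(rvonmises(n, -0.45, 150), rvonmises(n, 0.45, 150))),
    psi = wrap_periodic(rvonmises(2 * n, 0, 150)),
    bias = 0)
  ws <- compute_weights(traj, burn_in_fraction = 0)
  set <- cluster_states(select_high_weight(ws, 100), 0.3, 10)
  expect_length(set$states, 2)
  # landscape: twin minima at the blob centers, saddle ~2.8 kJ/mol between
  nb <- 40
  gr <- -pi + 2 * pi / nb * (seq_len(nb) - 0.5)
  fphi <- 3 - 3 * exp(-((gr - 0.45) / 0.25)^2) -
    3 * exp(-((gr + 0.45) / 0.25)^2)
  Fm <- outer(fphi, rep(0, nb), `+`)
  fes <- as_fes(Fm - min(Fm))
  merged <- merge_states(set, fes, merge_threshold = 5)
  expect_length(merged$states, 1)
  expect_equal(sort(merged$states[[1]]$members), seq_len(2 * n))
  # with a strict threshold they stay apart
  kept <- merge_states(set, fes, merge_threshold = 0.1)
  expect_length(kept$states, 2)
})

test_that("four-state Boltzmann mixture free energies match construction", {
  # weights chosen as exact Boltzmann factors of 0, 2, 5, 9 kJ/mol
  dF <- c(0, 2, 5, 9)
  pr <- exp(-dF / kT(300))
  traj <- boltzmann_mixture(1e6, default_state_centers(), pr / sum(pr))
  ws <- compute_weights(traj, burn_in_fraction = 0)
  set <- cluster_states(select_high_weight(ws, 100), 0.5, 25)
  set <- state_free_energy(ws, label_states(set))
  st <- states_table(set)
  got <- st$F[match(c("S_m", "S_v", "S_h", "S_c"), st$label)]
  expect_lt(max(abs(got - dF)), 0.3)
})
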