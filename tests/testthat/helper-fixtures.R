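# Shared fixtures, memoized so expensive runs are computed once per session.
.fixtures <- new.env(parent = emptyenv())

# Converged VES run on the low-barrier four-state surface (depths
# 30/20/28/15 kJ/mol, conc 6): the workhorse for reweighting-accuracy and
# convergence-diagnostic checks.
fixture_converged_run <- function() {
  if (is.null(.fixtures$converged)) {
    p <- make_four_state_potential()
    run <- run_ves(p, langevin_params(diffusion = 0.005, record_stride = 2,
                                      seed = 11),
                   N = 10, mu = 0.1, stride = 1000, n_iterations = 4000)
    ws <- compute_weights(run$trajectory)
    .fixtures$converged <- list(potential = p, run = run, ws = ws,
                                fes = estimate_fes_2d(ws, nbins = 50))
  }
  .fixtures$converged
}

# A run truncated while still filling its first basin (small learning rate,
# few iterations): no inter-basin transition occurs.
fixture_truncated_run <- function() {
  if (is.null(.fixtures$truncated)) {
    p <- make_four_state_potential()
    run <- run_ves(p, langevin_params(diffusion = 0.005, record_stride = 2,
                                      seed = 12),
                   N = 10, mu = 0.02, stride = 1000, n_iterations = 16)
    .fixtures$truncated <- list(potential = p, run = run)
  }
  .fixtures$truncated
}

# Exact Boltzmann draws from a mixture of tight product von Mises states.
# Components are chosen by their analytic weights; positions are von Mises
# around the centers, so state weight shares are exact by construction.
boltzmann_mixture <- function(n, centers, probs, kappa = 80) {
  comp <- sample.int(nrow(centers), n, replace = TRUE, prob = probs)
  data.frame(time = seq_len(n),
             phi = wrap_periodic(centers[comp, 1] + rvonmises(n, 0, kappa)),
             psi = wrap_periodic(centers[comp, 2] + rvonmises(n, 0, kappa)),
             bias = 0)
}

# Exhaustive threshold-search oracle for the minimax path barrier on a
# periodic grid: the barrier is the smallest level h such that start and end
# are connected through bins with F <= h (breadth-first search per level).
minimax_oracle <- function(F, s, e) {
  nr <- nrow(F); nc <- ncol(F)
  for (h in sort(unique(as.vector(F[is.finite(F)])))) {
    ok <- is.finite(F) & F <= h
    if (!ok[s[1], s[2]] || !ok[e[1], e[2]]) next
    vis <- matrix(FALSE, nr, nc)
    vis[s[1], s[2]] <- TRUE
    q <- list(s)
    while (length(q) > 0) {
      u <- q[[1]]; q <- q[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        v <- c((u[1] - 1 + d[1]) %% nr + 1, (u[2] - 1 + d[2]) %% nc + 1)
        if (ok[v[1], v[2]] && !vis[v[1], v[2]]) {
          vis[v[1], v[2]] <- TRUE
          q <- c(q, list(v))
        }
      }
    }
    if (vis[e[1], e[2]]) return(h - F[s[1], s[2]])
  }
  NA_real_
}

# Wrap a bare F matrix as a fes_grid (bins assumed periodic over [-pi, pi)).
as_fes <- function(F, beta = 1 / kT(300)) {
  structure(list(F = F, counts = (F * 0) + 1,
                 centers = -pi + 2 * pi / nrow(F) * (seq_len(nrow(F)) - 0.5),
                 beta = beta, nbins = as.integer(nrow(F))),
            class = "fes_grid")
}

# Random rigid transform (proper rotation + translation)
random_rigid <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = rnorm(3))
}
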