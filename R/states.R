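#' Sieve high-weight CV samples
#'
#' Keeps unmasked samples whose scaled weight is at least
#' \eqn{e^{-\beta\,\mathrm{fe\_cutoff}}}, i.e. samples within `fe_cutoff`
#' kJ/mol of the weight maximum on the free-energy scale.  Samples below the
#' threshold are negligible for state free energies since their weight
#' decays exponentially with energy.
#'
#' @param ws A [compute_weights()] result.
#' @param fe_cutoff Cutoff on the free-energy scale, kJ/mol (> 0); the
#'   default 45 keeps basins whose floors lie up to roughly 45 kJ/mol above
#'   the global minimum, with a few kT of capture margin for the shallowest.
#' @return A `cv_subset`: data frame of the kept samples with their original
#'   row indices, plus `beta` and the cutoff.
#' @export
select_high_weight <- function(ws, fe_cutoff = 45) {
  stopifnot(inherits(ws, "weighted_samples"), fe_cutoff > 0)
  thr <- exp(-ws$beta * fe_cutoff)
  keep <- which(ws$samples$keep & ws$samples$weight >= thr)
  if (length(keep) == 0)
    stop("no samples above the weight threshold; increase fe_cutoff")
  structure(list(samples = cbind(ws$samples[keep, ], index = keep),
                 beta = ws$beta, fe_cutoff = fe_cutoff),
            class = "cv_subset")
}

.circular_centroid <- function(phi, psi, w = NULL) {
  if (is.null(w)) w <- rep(1, length(phi))
  c(atan2(sum(w * sin(phi)), sum(w * cos(phi))),
    atan2(sum(w * sin(psi)), sum(w * cos(psi))))
}

#' Cluster sieved samples into metastable states
#'
#' Density-based clustering (DBSCAN) under the toroidal metric
#' \eqn{d(a,b) = \sqrt{\sum_i \mathrm{wrap}(a_i-b_i)^2}}, so basins
#' straddling the \eqn{\pm\pi} seam come out as single clusters.  For
#' scalability the density is evaluated on a periodic grid of cells no wider
#' than `toroidal_eps / 2`: points are pooled per cell, a cell is a core
#' cell when the cells within `toroidal_eps` of its center hold at least
#' `min_members` points, clusters grow through overlapping core cells, and
#' every point inherits the cluster of its cell.  The procedure is
#' deterministic given the input: no seed and no cluster-count parameter.
#' Points in no dense region are left unassigned.
#'
#' @param subset A [select_high_weight()] result.
#' @param toroidal_eps Neighborhood radius in radians (default 0.35).
#' @param min_members Minimum number of points in a core neighborhood
#'   (default 25).
#' @return A `state_set`: list of unlabeled `metastable_state` records
#'   (member indices into the original sample series, circular centroid,
#'   member count) plus the unassigned indices.
#' @export
cluster_states <- function(subset, toroidal_eps = 0.35, min_members = 25) {
  stopifnot(inherits(subset, "cv_subset"), toroidal_eps > 0, min_members >= 1)
  s <- subset$samples
  ncell <- max(8L, as.integer(min(1024, ceiling(2 * pi / (toroidal_eps / 2)))))
  w <- 2 * pi / ncell
  ci <- .bin_index(s$phi, ncell)
  cj <- .bin_index(s$psi, ncell)
  cell <- ci + ncell * (cj - 1)
  counts <- tabulate(cell, nbins = ncell * ncell)
  occ <- which(counts > 0)
  ctr <- .bin_centers(ncell)
  cpts <- cbind(ctr[(occ - 1) %% ncell + 1], ctr[(occ - 1) %/% ncell + 1])
  no <- length(occ)
  # toroidal adjacency between occupied cells
  d1 <- abs(wrap_periodic(outer(cpts[, 1], cpts[, 1], `-`)))
  d2 <- abs(wrap_periodic(outer(cpts[, 2], cpts[, 2], `-`)))
  nbr <- (d1^2 + d2^2) <= toroidal_eps^2
  mass <- as.vector(nbr %*% counts[occ])
  core <- mass >= min_members
  # grow clusters over core cells; border cells join the first claimant
  lab <- integer(no)
  ncl <- 0L
  for (i in seq_len(no)) {
    if (!core[i] || lab[i] > 0) next
    ncl <- ncl + 1L
    queue <- i
    lab[i] <- ncl
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      for (v in which(nbr[u, ])) {
        if (lab[v] == 0) {
          lab[v] <- ncl
          if (core[v]) queue <- c(queue, v)
        }
      }
    }
  }
  ptlab <- integer(nrow(s))
  ptlab <- lab[match(cell, occ)]
  states <- lapply(seq_len(ncl), function(l) {
    m <- ptlab == l
    structure(list(label = "unassigned",
                   members = s$index[m],
                   centroid = .circular_centroid(s$phi[m], s$psi[m]),
                   free_energy = NA_real_,
                   count = sum(m)),
              class = "metastable_state")
  })
  structure(list(states = states, unassigned = s$index[ptlab == 0],
                 beta = subset$beta,
                 eps = toroidal_eps, min_members = as.integer(min_members)),
            class = "state_set")
}

#' @export
print.state_set <- function(x, ...) {
  cat(sprintf("%d metastable state(s), %d unassigned sample(s)\n",
              length(x$states), length(x$unassigned)))
  for (s in x$states)
    cat(sprintf("  %-10s centroid (% .3f, % .3f)  n = %d  F = %s kJ/mol\n",
                s$label, s$centroid[1], s$centroid[2], s$count,
                ifelse(is.na(s$free_energy), "?",
                       sprintf("%.3f", s$free_energy))))
  invisible(x)
}

#' Merge clusters separated by sub-threshold barriers
#'
#' Clusters whose connecting minimax path barrier on the landscape (saddle
#' height above the shallower of the two basin floors) is below
#' `merge_threshold` are treated as substates of one superstate and merged
#' before labeling: transitions across such low barriers are frequent
#' enough that the pair acts as a single thermodynamic state.
#'
#' @param set A [cluster_states()] result.
#' @param fes A `fes_grid` for the same samples.
#' @param merge_threshold Barrier below which clusters merge (kJ/mol;
#'   default 5).
#' @return A `state_set` with merged states.
#' @export
merge_states <- function(set, fes, merge_threshold = 5) {
  stopifnot(inherits(set, "state_set"), inherits(fes, "fes_grid"))
  states <- set$states
  repeat {
    n <- length(states)
    if (n < 2) break
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        bi <- fes_bin(fes, states[[i]]$centroid)
        bj <- fes_bin(fes, states[[j]]$centroid)
        Fi <- fes$F[bi[1], bi[2]]
        Fj <- fes$F[bj[1], bj[2]]
        if (!is.finite(Fi) || !is.finite(Fj)) next
        saddle <- tryCatch(
          minimax_path_barrier(fes, bi, bj) + Fi, error = function(e) Inf)
        if (saddle - max(Fi, Fj) >= merge_threshold) next
        mem <- c(states[[i]]$members, states[[j]]$members)
        keep_i <- states[[i]]$count >= states[[j]]$count
        base <- if (keep_i) states[[i]] else states[[j]]
        base$members <- sort(mem)
        base$count <- length(mem)
        states[[i]] <- base
        states[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  set$states <- states
  set
}

#' Label states by nearest reference centroid
#'
#' Each cluster receives the label of the toroidally nearest reference
#' centroid.  When two clusters map to the same label, the closer cluster
#' keeps it and the other takes its nearest free label; ties are broken in
#' the fixed label order `S_m`, `S_v`, `S_h`, `S_c`.  Labeling is invariant
#' to the input order of the clusters.
#'
#' @param set A `state_set`.
#' @param reference Named 4 x 2 matrix of reference centroids (default
#'   [default_state_centers()]).
#' @return The `state_set` with labels assigned (clusters beyond the number
#'   of labels stay `"unassigned"`).
#' @export
label_states <- function(set, reference = default_state_centers()) {
  stopifnot(inherits(set, "state_set"))
  labs <- rownames(reference)
  if (is.null(labs) || length(labs) < 1)
    stop("reference centroids must carry labels as row names")
  ns <- length(set$states)
  if (ns == 0) return(set)
  D <- matrix(Inf, ns, length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(ns)) {
    ctr <- matrix(set$states[[i]]$centroid, nrow = nrow(reference),
                  ncol = 2, byrow = TRUE)
    D[i, ] <- .torus_dist(ctr, reference)
  }
  assigned <- rep(NA_character_, ns)
  free <- labs
  pool <- seq_len(ns)
  while (length(pool) > 0 && length(free) > 0) {
    # each pooled cluster's nearest free label; closest claimant wins
    best <- matrix(vapply(pool, function(i) {
      d <- D[i, free]
      j <- which(d == min(d))[1]  # tie -> first in fixed label order
      c(d[j], j)
    }, numeric(2)), nrow = 2, dimnames = list(c("dist", "lab"), NULL))
    ord <- order(best["dist", ], match(free[best["lab", ]], labs))
    w <- ord[1]
    assigned[pool[w]] <- free[best["lab", w]]
    free <- setdiff(free, free[best["lab", w]])
    pool <- pool[-w]
  }
  for (i in seq_len(ns))
    if (!is.na(assigned[i])) set$states[[i]]$label <- assigned[i]
  set
}

#' State free energies from weight shares
#'
#' The free energy of state \eqn{s} is
#' \eqn{F_s = -\beta^{-1} \ln\big(\sum_{i \in s} w_i / \sum_{\mathrm{all}}
#' w_i\big)} with the sums over scaled weights of, respectively, the state
#' members and all unmasked samples; afterwards all states are shifted so
#' the deepest sits exactly at 0 kJ/mol.
#'
#' @param ws The [compute_weights()] result the states were extracted from.
#' @param set A `state_set` (labeled or not).
#' @return The `state_set` with `free_energy` filled in.
#' @export
state_free_energy <- function(ws, set) {
  stopifnot(inherits(ws, "weighted_samples"), inherits(set, "state_set"))
  if (length(set$states) == 0) stop("no states")
  wtot <- sum(ws$samples$weight[ws$samples$keep])
  F <- vapply(set$states, function(s) {
    if (length(s$members) == 0) stop("empty state")
    -log(sum(ws$samples$weight[s$members]) / wtot) / ws$beta
  }, numeric(1))
  F <- F - min(F)
  for (i in seq_along(set$states)) set$states[[i]]$free_energy <- F[i]
  set
}

#' Per-state free-energy differences between two landscapes
#'
#' For every label present in both state sets, \eqn{\Delta_s = F_s^{A} -
#' F_s^{B}} (each landscape normalized to its own deepest state).  With A
#' the red-resting and B the far-red landscape, a negative value means the
#' state is more populated in A and a positive value that it is more
#' populated in B.  Labels missing on either side are reported as `NA`,
#' never as zero.
#'
#' @param states_a,states_b Labeled `state_set`s with free energies
#'   attached, analyzed with the same \eqn{\beta}.
#' @return Named numeric vector of differences (kJ/mol) over the union of
#'   labels.
#' @export
state_fe_difference <- function(states_a, states_b) {
  stopifnot(inherits(states_a, "state_set"), inherits(states_b, "state_set"))
  if (!isTRUE(all.equal(states_a$beta, states_b$beta)))
    stop("state sets analyzed at different temperatures")
  fa <- .state_fe_table(states_a)
  fb <- .state_fe_table(states_b)
  labs <- union(names(fa), names(fb))
  labs <- setdiff(labs, "unassigned")
  if (!any(labs %in% names(fa) & labs %in% names(fb)))
    stop("no shared labels between the two state sets")
  out <- setNames(rep(NA_real_, length(labs)), labs)
  shared <- labs[labs %in% names(fa) & labs %in% names(fb)]
  out[shared] <- fa[shared] - fb[shared]
  out
}

.state_fe_table <- function(set) {
  labs <- vapply(set$states, function(s) s$label, character(1))
  F <- vapply(set$states, function(s) s$free_energy, numeric(1))
  if (any(is.na(F)))
    stop("state free energies not computed; call state_free_energy() first")
  setNames(F, labs)
}

#' Tabulate a state set
#'
#' @param set A `state_set`.
#' @return Data frame with label, centroid, member count and free energy.
#' @export
states_table <- function(set) {
  stopifnot(inherits(set, "state_set"))
  data.frame(
    label = vapply(set$states, function(s) s$label, character(1)),
    phi = vapply(set$states, function(s) s$centroid[1], numeric(1)),
    psi = vapply(set$states, function(s) s$centroid[2], numeric(1)),
    members = vapply(set$states, function(s) s$count, numeric(1)),
    F = vapply(set$states, function(s) s$free_energy, numeric(1)))
}
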