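#' Index table of the Fourier basis
#'
#' The bias is expanded in the real product basis
#' \eqn{f_{ab}(\Phi,\Psi) = u_a(\Phi)\, u_b(\Psi)} with per-dimension
#' functions \eqn{u_0 = 1}, \eqn{u_{2k-1} = \cos(kx)}, \eqn{u_{2k} =
#' \sin(kx)} for \eqn{k = 1..N}; there are \eqn{(2N+1)^2} independent real
#' basis functions.  The flattened ordering is column-major with the
#' \eqn{\Phi} factor varying fastest; this table documents it.
#'
#' @param N Expansion order (>= 1).
#' @return Data frame with columns `index`, `k1`, `k2`, `type` (`"cc"`,
#'   `"cs"`, `"sc"`, `"ss"`) and `label`.
#' @examples
#' head(basis_index(2))
#' @export
basis_index <- function(N) {
  stopifnot(N >= 1)
  M <- 2 * N + 1
  dim1 <- function(i) { # 0-based per-dimension index -> (k, is_sin)
    k <- ceiling(i / 2)
    list(k = k, s = i > 0 & i %% 2 == 0)
  }
  i <- rep(0:(M - 1), times = M)
  j <- rep(0:(M - 1), each = M)
  a <- dim1(i)
  b <- dim1(j)
  type <- paste0(ifelse(a$s, "s", "c"), ifelse(b$s, "s", "c"))
  lab1 <- ifelse(a$k == 0, "1", paste0(ifelse(a$s, "sin", "cos"),
                                       ifelse(a$k == 1, "", a$k), "phi"))
  lab2 <- ifelse(b$k == 0, "1", paste0(ifelse(b$s, "sin", "cos"),
                                       ifelse(b$k == 1, "", b$k), "psi"))
  data.frame(index = seq_len(M * M), k1 = a$k, k2 = b$k, type = type,
             label = paste(lab1, lab2, sep = "*"))
}

#' Evaluate the basis functions at torus points
#'
#' @param z Torus point `c(phi, psi)` or n x 2 matrix.
#' @param N Expansion order.
#' @return Numeric vector of length \eqn{(2N+1)^2} (or an n-row matrix) in
#'   the order documented by [basis_index()].
#' @examples
#' length(basis_functions(c(0, 0), 10))  # 441
#' @export
basis_functions <- function(z, N) {
  stopifnot(N >= 1)
  single <- is.null(dim(z))
  out <- .basis_core(matrix(z, ncol = 2), as.integer(N))
  if (single) out[1, ] else out
}

#' Fourier-series bias potential
#'
#' @param N Expansion order (>= 1).
#' @param coefficients Optional coefficient matrix (\eqn{(2N+1) \times
#'   (2N+1)}, kJ/mol; rows index the \eqn{\Phi} factor) or flat vector of
#'   length \eqn{(2N+1)^2} in [basis_index()] order. Defaults to zero
#'   (\eqn{V \equiv 0}).
#' @return A `bias_model` object.
#' @export
bias_model <- function(N, coefficients = NULL) {
  stopifnot(N >= 1)
  M <- as.integer(2 * N + 1)
  if (is.null(coefficients)) coefficients <- matrix(0, M, M)
  if (is.null(dim(coefficients))) {
    if (length(coefficients) != M * M)
      stop(sprintf("need %d coefficients for N = %d", M * M, N))
    coefficients <- matrix(coefficients, M, M)
  }
  stopifnot(nrow(coefficients) == M, ncol(coefficients) == M)
  structure(list(N = as.integer(N), coef = coefficients),
            class = "bias_model")
}

#' Evaluate a bias potential
#'
#' @param b A [bias_model()].
#' @param z Torus point or n x 2 matrix.
#' @return Bias energy in kJ/mol (vectorized over rows of `z`).
#' @export
evaluate_bias <- function(b, z) {
  stopifnot(inherits(b, "bias_model"))
  single <- is.null(dim(z))
  v <- .bias_eval_core(matrix(z, ncol = 2), b$coef)
  if (single) v[1] else v
}

#' Functional gradient of the variational bias objective
#'
#' For the convex variational functional with a uniform target distribution,
#' the gradient with respect to the coefficient of basis function \eqn{f_k}
#' is \eqn{-\langle f_k \rangle_{\mathrm{batch}} + \langle f_k
#' \rangle_{p_T}}; for the uniform target, the target-side average is 1 for
#' the constant basis function and 0 otherwise, so the constant coefficient
#' never moves and the bias is determined up to an irrelevant constant.
#'
#' @param batch n x 2 matrix of biased CV samples.
#' @param b A [bias_model()] (or an expansion order `N`).
#' @param target Target distribution kind; only `"uniform"` is implemented.
#' @return Gradient vector of length \eqn{(2N+1)^2} in [basis_index()] order.
#' @export
omega_gradient <- function(batch, b, target = "uniform") {
  target <- match.arg(target, "uniform")
  N <- if (inherits(b, "bias_model")) b$N else as.integer(b)
  batch <- matrix(batch, ncol = 2)
  if (nrow(batch) == 0) stop("empty sample batch")
  fbar <- colMeans(basis_functions(batch, N))
  tvec <- numeric(length(fbar))
  tvec[1] <- 1
  -fbar + tvec
}

#' Uniform-target average of each basis function
#'
#' @param N Expansion order.
#' @return Vector with 1 on the constant function, 0 elsewhere.
#' @export
target_average <- function(N) {
  v <- numeric((2 * N + 1)^2)
  v[1] <- 1
  v
}

#' Optimizer state for stochastic gradient descent with iterate averaging
#'
#' @param N Expansion order.
#' @param mu Learning rate (default 0.1).
#' @param stride Langevin steps between coefficient updates (default 1000).
#' @return An `optimizer_state` holding instantaneous and averaged
#'   coefficient vectors and the iteration counter.
#' @export
optimizer_state <- function(N, mu = 0.1, stride = 1000) {
  K <- (2 * N + 1)^2
  structure(list(N = as.integer(N), mu = mu, stride = as.integer(stride),
                 iteration = 0L, alpha = numeric(K), alpha_bar = numeric(K)),
            class = "optimizer_state")
}

#' One stochastic-gradient update
#'
#' Applies \eqn{\alpha \leftarrow \alpha - \mu\, g} to the instantaneous
#' coefficients and refreshes the running mean \eqn{\bar\alpha} over
#' completed iterations.  The acting bias during propagation is
#' \eqn{\bar\alpha} (averaged SGD).
#'
#' @param state An [optimizer_state()].
#' @param grad Gradient vector (length \eqn{(2N+1)^2}).
#' @return The updated state.
#' @export
sgd_update <- function(state, grad) {
  stopifnot(inherits(state, "optimizer_state"))
  if (length(grad) != length(state$alpha))
    stop("gradient dimension mismatch")
  state$alpha <- state$alpha - state$mu * grad
  state$iteration <- state$iteration + 1L
  state$alpha_bar <- state$alpha_bar +
    (state$alpha - state$alpha_bar) / state$iteration
  state
}

#' Run variationally enhanced sampling
#'
#' Alternates `stride` overdamped Langevin steps under the acting bias with
#' one stochastic-gradient coefficient update, driving the biased marginal
#' toward a uniform distribution over the torus.  At convergence the
#' averaged bias satisfies \eqn{V(z) \approx -U(z) + \mathrm{const}} on the
#' span of the basis, so for any potential expressible in the basis the
#' converged coefficients equal the negated potential coefficients.
#'
#' @param p A [model_potential()].
#' @param params A [langevin_params()]; its `n_steps` is ignored (the run
#'   length is `stride * n_iterations`).
#' @param N Expansion order (default 10, i.e. 441 basis functions).
#' @param mu Learning rate (default 0.1).
#' @param stride Steps between updates (default 1000).
#' @param n_iterations Number of update cycles.
#' @param average_bias Propagate under the averaged iterates (default TRUE);
#'   set FALSE for plain SGD.
#' @param curvature Include the curvature (Hessian-vector) correction of
#'   averaged stochastic gradient descent in the instantaneous update
#'   (default TRUE).  The correction damps the random-walk fluctuations of
#'   the instantaneous iterate, which otherwise grow with the landscape
#'   amplitude; plain first-order updates remain selectable.
#' @param avg_start_fraction Fraction of the iterations run as a fill stage
#'   before iterate averaging of the acting bias begins (default 0.1).
#'   Averaging from the first iteration makes the acting bias lag the fill
#'   of deep wells (the running mean must itself climb to the well depth,
#'   forcing the instantaneous iterate to overshoot by up to a factor of
#'   two); starting the average once the landscape is roughly filled
#'   removes that transient from the converged bias.
#' @param z0 Starting point; defaults to the deepest well center.
#' @param history_stride Store the acting coefficients every this many
#'   iterations.
#' @return A `ves_run` list: `trajectory` (a `cv_trajectory` whose `bias`
#'   column holds the acting bias at each recorded position, i.e. the bias at
#'   sampling time), `bias` (averaged [bias_model()]), `bias_instantaneous`,
#'   and `optimizer` (iteration count, `mu`, `stride`, coefficient history).
#' @examples
#' p <- model_potential(fourier = data.frame(k1 = 1, k2 = 0, type = "cc",
#'                                           coef = 4))
#' run <- run_ves(p, langevin_params(diffusion = 0.02, seed = 1), N = 1,
#'                stride = 200, n_iterations = 50)
#' run$bias$coef[2, 1]  # approaches -4
#' @export
run_ves <- function(p, params = langevin_params(), N = 10, mu = 0.1,
                    stride = 1000, n_iterations = 500, average_bias = TRUE,
                    curvature = TRUE, avg_start_fraction = 0.1, z0 = NULL,
                    history_stride = max(1L, n_iterations %/% 200)) {
  stopifnot(inherits(p, "model_potential"), inherits(params, "langevin_params"),
            N >= 1, mu > 0, stride >= 1, n_iterations >= 1)
  .check_stability(p, params, margin = 2)
  if (is.null(z0)) z0 <- .default_start(p)
  if (!is.null(params$seed)) set.seed(params$seed)
  res <- .ves_core(.wells_mat(p$wells), .fterms_mat(p$fourier), p$offset,
                   as.integer(N), mu, as.integer(stride),
                   as.integer(n_iterations), params$beta, params$diffusion,
                   params$time_step, params$record_stride, z0[1], z0[2],
                   average_bias, as.integer(history_stride), curvature,
                   as.integer(max(1, round(avg_start_fraction * n_iterations))))
  structure(list(
    trajectory = .as_cv_trajectory(res$traj),
    bias = bias_model(N, res$alpha_bar),
    bias_instantaneous = bias_model(N, res$alpha_inst),
    optimizer = list(iterations = as.integer(n_iterations), mu = mu,
                     stride = as.integer(stride),
                     average_bias = average_bias,
                     history = res$history,
                     history_iteration = res$history_iter),
    params = params), class = "ves_run")
}

#' @export
print.ves_run <- function(x, ...) {
  cat(sprintf(paste0("VES run: N = %d (%d basis functions), mu = %g, ",
                     "stride = %d, %d iterations\n"),
              x$bias$N, length(x$bias$coef), x$optimizer$mu,
              x$optimizer$stride, x$optimizer$iterations))
  cat(sprintf("  %d recorded samples\n", nrow(x$trajectory)))
  invisible(x)
}

#' Serialize a bias potential as plain text
#'
#' Header lines carry the expansion order and domain; then one
#' `k1 k2 type coefficient` row per basis function.  Round-trips bit-exactly
#' through [read_bias()].
#'
#' @param b A [bias_model()].
#' @param path Output file path.
#' @export
write_bias <- function(b, path) {
  stopifnot(inherits(b, "bias_model"))
  idx <- basis_index(b$N)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# torusves bias N=%d", b$N),
               "# domain [-pi,pi)^2",
               "# k1 k2 type coefficient"), con)
  writeLines(sprintf("%d %d %s %s", idx$k1, idx$k2, idx$type,
                     formatC(as.vector(b$coef), format = "e", digits = 17)),
             con)
  invisible(path)
}

#' Read a serialized bias potential
#'
#' @param path File written by [write_bias()].
#' @return A [bias_model()].
#' @export
read_bias <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  N <- as.integer(sub(".*N=", "", hdr))
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(trimws(body), "\\s+")
  coef <- vapply(parts, function(x) as.numeric(x[4]), numeric(1))
  bias_model(N, coef)
}
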