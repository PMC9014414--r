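#' Parameters for the overdamped Langevin propagator
#'
#' The propagator is an Euler-Maruyama discretization of overdamped Langevin
#' dynamics on the torus,
#' \deqn{z \leftarrow \mathrm{wrap}(z - \beta D \nabla(U+V)\Delta t +
#'   \sqrt{2 D \Delta t}\,\xi),}
#' with \eqn{\xi} standard normal per coordinate.  Time units are arbitrary
#' ("steps"): the surrogate carries no physical nanosecond scale.
#'
#' @param temperature Temperature in kelvin (default 300).
#' @param diffusion Diffusion coefficient in rad^2 per time unit.
#' @param time_step Integration time step (time units).
#' @param n_steps Number of integration steps.
#' @param record_stride Store every `record_stride`-th step.
#' @param seed Optional integer seed; when given, runs are bitwise
#'   reproducible.
#' @return A `langevin_params` list with the derived inverse temperature
#'   `beta` attached.
#' @export
langevin_params <- function(temperature = 300, diffusion = 0.002,
                            time_step = 1, n_steps = 100000,
                            record_stride = 10, seed = NULL) {
  stopifnot(temperature > 0, diffusion > 0, time_step > 0,
            n_steps >= 1, record_stride >= 1)
  structure(list(temperature = temperature, diffusion = diffusion,
                 time_step = time_step, n_steps = as.integer(n_steps),
                 record_stride = as.integer(record_stride), seed = seed,
                 beta = 1 / kT(temperature)),
            class = "langevin_params")
}

# Single-step drift must stay below pi or the discretization is meaningless.
.check_stability <- function(p, params, margin = 1) {
  mg <- .pot_max_grad(p) * margin
  drift <- params$time_step * params$diffusion * params$beta * mg
  if (drift >= pi) {
    dt_max <- pi / (params$diffusion * params$beta * mg)
    stop(sprintf(paste0("unstable integration: single-step drift %.3g rad ",
                        ">= pi; use time_step < %.3g"), drift, dt_max))
  }
  invisible(drift)
}

.as_cv_trajectory <- function(m) {
  d <- as.data.frame(m)
  names(d) <- c("time", "phi", "psi", "bias")
  class(d) <- c("cv_trajectory", "data.frame")
  d
}

#' Run overdamped Langevin dynamics on a model potential
#'
#' Propagates a single walker under `U + V`, where `V` is an optional fixed
#' bias potential, and records the biased collective-variable time series.
#'
#' @param p A [model_potential()].
#' @param bias Optional [bias_model()] held fixed during the run; `NULL` for
#'   unbiased dynamics.
#' @param params A [langevin_params()].
#' @param z0 Starting point `c(phi, psi)`; defaults to the deepest well
#'   center (or `c(0, 0)` for a pure-Fourier potential).
#' @return A `cv_trajectory` data frame with columns `time`, `phi`, `psi`
#'   and `bias` (the bias energy at each recorded position, kJ/mol; zero when
#'   unbiased).
#' @examples
#' p <- make_four_state_potential(depths = 5)
#' traj <- run_langevin(p, params = langevin_params(n_steps = 2000, seed = 1))
#' head(traj)
#' @export
run_langevin <- function(p, bias = NULL, params = langevin_params(),
                         z0 = NULL) {
  stopifnot(inherits(p, "model_potential"), inherits(params, "langevin_params"))
  .check_stability(p, params, margin = if (is.null(bias)) 1 else 2)
  if (is.null(z0)) z0 <- .default_start(p)
  has_bias <- !is.null(bias)
  A <- if (has_bias) bias$coef else matrix(0, 1, 1)
  if (!is.null(params$seed)) set.seed(params$seed)
  m <- .langevin_core(.wells_mat(p$wells), .fterms_mat(p$fourier), p$offset,
                      A, has_bias, params$beta, params$diffusion,
                      params$time_step, params$n_steps, params$record_stride,
                      z0[1], z0[2])
  .as_cv_trajectory(m)
}

.default_start <- function(p) {
  if (nrow(p$wells) > 0) {
    i <- which.max(p$wells$depth)
    c(p$wells$phi[i], p$wells$psi[i])
  } else c(0, 0)
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat(sprintf("CV trajectory: %d stored samples, time %s .. %s\n",
              nrow(x), format(min(x$time)), format(max(x$time))))
  NextMethod()
}
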