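#' Write a CV trajectory in COLVAR-style columnar text
#'
#' Whitespace-separated columns under a `#! FIELDS time phi psi bias`
#' header (extra columns are appended to the field list).  Values carry 12
#' significant digits; output is byte-deterministic for identical input.
#'
#' @param traj A `cv_trajectory` (or any data frame with `time`, `phi`,
#'   `psi`, `bias`).
#' @param path Output path.
#' @export
write_colvar <- function(traj, path) {
  stopifnot(is.data.frame(traj))
  need <- c("time", "phi", "psi", "bias")
  if (!all(need %in% names(traj)))
    stop("trajectory must have time, phi, psi and bias columns")
  cols <- c(need, setdiff(names(traj), need))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#! FIELDS", cols), collapse = " "), con)
  if (nrow(traj) > 0) {
    body <- do.call(paste, lapply(cols, function(cn)
      formatC(traj[[cn]], format = "e", digits = 12)))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a COLVAR-style file
#'
#' Parses the `#! FIELDS ...` header and maps columns by name.  Repeated
#' header blocks (as left by restarted runs) are tolerated: later blocks
#' are appended and duplicated times are dropped keeping the last
#' occurrence.
#'
#' @param path File path.
#' @return A `cv_trajectory` data frame (extra columns preserved).
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  hdr_idx <- which(startsWith(lines, "#! FIELDS"))
  if (length(hdr_idx) == 0) stop("no '#! FIELDS' header found")
  blocks <- list()
  bounds <- c(hdr_idx, length(lines) + 1)
  for (b in seq_along(hdr_idx)) {
    fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[hdr_idx[b]])),
                       "\\s+")[[1]]
    need <- c("time", "phi", "psi", "bias")
    miss <- setdiff(need, fields)
    if (length(miss) > 0)
      stop(sprintf("missing mandatory column(s): %s",
                   paste(miss, collapse = ", ")))
    rng <- (bounds[b] + 1):(bounds[b + 1] - 1)
    rng <- rng[rng <= length(lines)]
    body <- lines[rng]
    keep <- !startsWith(body, "#") & nzchar(trimws(body))
    lineno <- rng[keep]
    body <- body[keep]
    if (length(body) == 0) {
      blocks[[b]] <- as.data.frame(setNames(
        rep(list(numeric(0)), length(fields)), fields))
      next
    }
    parts <- strsplit(trimws(body), "\\s+")
    nf <- length(fields)
    bad <- which(vapply(parts, length, integer(1)) != nf)
    if (length(bad) > 0)
      stop(sprintf("unparseable row at line %d of %s", lineno[bad[1]], path))
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = nf, byrow = TRUE)
    nonnum <- which(rowSums(is.na(m)) > 0)
    if (length(nonnum) > 0)
      stop(sprintf("unparseable row at line %d of %s", lineno[nonnum[1]], path))
    colnames(m) <- fields
    blocks[[b]] <- as.data.frame(m)
  }
  out <- do.call(rbind, blocks)
  # duplicate times: keep the last occurrence
  out <- out[!duplicated(out$time, fromLast = TRUE), , drop = FALSE]
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cv_trajectory", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Run configuration
# ---------------------------------------------------------------------------

.config_defaults <- function() {
  list(
    potential = list(preset = "pr", depths = NULL, concentrations = NULL),
    temperature = 300,
    diffusion = 0.004,
    time_step = 1,
    ves = list(N = 10, mu = 0.1, stride = 1000, n_iterations = 10000,
               record_stride = 10),
    grid_nbins = 50,
    burn_in_fraction = 0.02,
    fe_cutoff = 45,
    cluster_eps = 0.35,
    cluster_min_members = 25,
    merge_threshold = 5,
    n_checkpoints = 20,
    convergence_window = 5,
    slope_tol = 0.01,
    n_boot = 2000,
    ci_level = 0.95,
    seed = 1,
    out_dir = NULL)
}

#' Pipeline run configuration
#'
#' A single configuration object drives the full workflow (simulate,
#' enhance, reweight, cluster, diagnose).  Every defaulted field is
#' serialized back out, so a written configuration round-trips to an
#' equivalent one; unknown keys are rejected.
#'
#' @param ... Overrides of the default fields (nested lists `potential` and
#'   `ves` are merged field-wise).
#' @return A `ves_config` list.
#' @examples
#' cfg <- ves_config(seed = 7, ves = list(n_iterations = 100))
#' cfg$ves$N
#' @export
ves_config <- function(...) {
  defaults <- .config_defaults()
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  for (nested in c("potential", "ves")) {
    if (!is.null(over[[nested]])) {
      bad <- setdiff(names(over[[nested]]), names(defaults[[nested]]))
      if (length(bad) > 0)
        stop(sprintf("unknown configuration key(s): %s",
                     paste(paste0(nested, ".", bad), collapse = ", ")))
      defaults[[nested]] <- modifyList(defaults[[nested]], over[[nested]])
      over[[nested]] <- NULL
    }
  }
  cfg <- modifyList(defaults, over)
  structure(cfg, class = "ves_config")
}

#' Write a configuration as YAML
#'
#' @param config A [ves_config()].
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ves_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' Unknown keys are rejected; defaulted fields survive the round trip.
#'
#' @param path YAML file path.
#' @return A [ves_config()].
#' @export
read_config <- function(path) {
  ves_config(yaml::read_yaml(path))
}

.config_hash <- function(config) {
  # hash the scientific configuration only, not the output location
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

.config_potential <- function(config) {
  pot <- config$potential
  if (!is.null(pot$depths)) {
    make_four_state_potential(depths = unlist(pot$depths),
                              concentrations = if (is.null(pot$concentrations))
                                6 else unlist(pot$concentrations))
  } else {
    phantom_potential(pot$preset)
  }
}

# ---------------------------------------------------------------------------
# Pipeline
# ---------------------------------------------------------------------------

#' Run the full enhanced-sampling analysis pipeline
#'
#' Executes the stages in order on one landscape: build the model
#' potential, run variationally enhanced sampling, reweight to a
#' free-energy landscape with marginal profiles, compute convergence
#' diagnostics over cumulative checkpoints, sieve and cluster metastable
#' states, label them against the canonical four-state layout, and attach
#' state free energies.  All randomness flows from `config$seed`, so
#' re-running with an identical configuration reproduces every numeric
#' output bitwise.  When `config$out_dir` is set, the stage outputs
#' (COLVAR series, bias checkpoint, landscape, profiles, states table,
#' convergence report, summary) are written there as deterministic text,
#' each stamped with the configuration hash.
#'
#' @param config A [ves_config()].
#' @return A `ves_pipeline` list: `potential`, `run`, `weights`, `fes`,
#'   `profiles`, `barrier`, `states` (a labeled `state_set` with free
#'   energies), `convergence`, `variability`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = ves_config()) {
  stopifnot(inherits(config, "ves_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  hash <- .config_hash(config)
  p <- stage("potential", .config_potential(config))
  params <- stage("params", langevin_params(
    temperature = config$temperature, diffusion = config$diffusion,
    time_step = config$time_step,
    record_stride = config$ves$record_stride, seed = config$seed))
  run <- stage("ves", run_ves(
    p, params, N = config$ves$N, mu = config$ves$mu,
    stride = config$ves$stride, n_iterations = config$ves$n_iterations))
  ws <- stage("weights", compute_weights(
    run$trajectory, temperature = config$temperature,
    burn_in_fraction = config$burn_in_fraction))
  fes <- stage("fes", estimate_fes_2d(ws, nbins = config$grid_nbins))
  profiles <- stage("profiles", list(phi = marginal_profile(fes, "phi"),
                                     psi = marginal_profile(fes, "psi")))
  barrier <- stage("barrier", global_barrier(fes))
  tmax <- max(ws$samples$time)
  tburn <- if (any(!ws$samples$keep)) max(ws$samples$time[!ws$samples$keep])
           else min(ws$samples$time)
  ck_times <- seq(tburn, tmax, length.out = config$n_checkpoints + 1)[-1]
  checkpoints <- stage("checkpoints",
                       fes_checkpoints(ws, ck_times, nbins = config$grid_nbins))
  conv <- stage("convergence", convergence_series(
    checkpoints, ck_times, window = config$convergence_window,
    slope_tol = config$slope_tol))
  variability <- stage("variability", fes_variability(
    checkpoints, window = max(2L, length(checkpoints) %/% 2)))
  states <- stage("states", {
    subset <- select_high_weight(ws, fe_cutoff = config$fe_cutoff)
    set <- cluster_states(subset, toroidal_eps = config$cluster_eps,
                          min_members = config$cluster_min_members)
    set <- merge_states(set, fes, merge_threshold = config$merge_threshold)
    set <- label_states(set)
    state_free_energy(ws, set)
  })
  out <- structure(list(potential = p, run = run, weights = ws, fes = fes,
                        profiles = profiles, barrier = barrier,
                        states = states, convergence = conv,
                        variability = variability, config = config,
                        config_hash = hash),
                   class = "ves_pipeline")
  if (!is.null(config$out_dir)) .write_pipeline(out, config$out_dir)
  out
}

.write_pipeline <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- sprintf("# config %s", res$config_hash)
  write_colvar(res$run$trajectory, file.path(dir, "colvar.dat"))
  write_bias(res$run$bias, file.path(dir, "bias.dat"))
  write_fes(res$fes, file.path(dir, "fes.dat"))
  for (ax in c("phi", "psi")) {
    f <- file.path(dir, sprintf("profile_%s.dat", ax))
    pr <- res$profiles[[ax]]
    writeLines(c(stamp, sprintf("# %s F", ax),
                 sprintf("%s %s", formatC(pr[[1]], format = "e", digits = 12),
                         formatC(pr$F, format = "e", digits = 12))), f)
  }
  st <- states_table(res$states)
  writeLines(c(stamp, "# label phi psi members F",
               sprintf("%s %s %s %d %s", st$label,
                       formatC(st$phi, format = "e", digits = 12),
                       formatC(st$psi, format = "e", digits = 12),
                       as.integer(st$members),
                       formatC(st$F, format = "e", digits = 12))),
             file.path(dir, "states.dat"))
  cs <- res$convergence$series
  writeLines(c(stamp, "# time distance",
               sprintf("%s %s", formatC(cs$time, format = "e", digits = 12),
                       formatC(cs$distance, format = "e", digits = 12)),
               if (is.na(res$convergence$plateau_time)) "# plateau none"
               else sprintf("# plateau %s",
                            formatC(res$convergence$plateau_time,
                                    format = "e", digits = 12))),
             file.path(dir, "convergence.dat"))
  writeLines(c(stamp,
               sprintf("barrier_kJmol %s",
                       formatC(res$barrier, format = "e", digits = 12)),
               sprintf("variability_kJmol %s",
                       formatC(res$variability, format = "e", digits = 12)),
               sprintf("seed %d", res$config$seed)),
             file.path(dir, "summary.dat"))
  write_config(res$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.ves_pipeline <- function(x, ...) {
  cat(sprintf("Pipeline result (config %s)\n", substr(x$config_hash, 1, 8)))
  cat(sprintf("  global barrier %.2f kJ/mol, landscape variability %.3f kJ/mol\n",
              x$barrier, x$variability))
  print(x$states)
  print(x$convergence)
  invisible(x)
}

#' Compare two analyzed landscapes
#'
#' Takes the pipeline results of two conformer surrogates (by convention A
#' = red-resting, B = far-red) and reports per-state free-energy
#' differences \eqn{F_s^A - F_s^B}, global barriers, and Arrhenius
#' time-scale estimates for the barrier separating the two X-ray-analog
#' states (`S_h` to `S_m` in A, `S_m` to `S_h` in B) when both states are
#' present.
#'
#' @param res_a,res_b `ves_pipeline` results.
#' @param model A [rate_model()] for the time-scale estimates.
#' @return List with `delta_f` (named vector, kJ/mol), `barriers`,
#'   `transition` (directed inter-state barriers and times).
#' @export
compare_landscapes <- function(res_a, res_b, model = rate_model()) {
  stopifnot(inherits(res_a, "ves_pipeline"), inherits(res_b, "ves_pipeline"))
  delta <- state_fe_difference(res_a$states, res_b$states)
  trans <- NULL
  tr_one <- function(res, from, to) {
    st <- states_table(res$states)
    if (!all(c(from, to) %in% st$label)) return(NULL)
    zf <- unlist(st[st$label == from, c("phi", "psi")])
    zt <- unlist(st[st$label == to, c("phi", "psi")])
    b <- minimax_path_barrier(res$fes, zf, zt)
    data.frame(from = from, to = to, barrier = b,
               time_s = arrhenius_time(b, model))
  }
  trans <- rbind(tr_one(res_a, "S_h", "S_m"), tr_one(res_b, "S_m", "S_h"))
  list(delta_f = delta,
       barriers = c(A = res_a$barrier, B = res_b$barrier),
       transition = trans)
}
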