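#' Run configuration
#'
#' Assembles and validates everything a simulation run needs: grid size,
#' time step and horizon, initial condition (seeds, bulk solute, onset
#' supercooling), material-parameter overrides, and run toggles. Defaults
#' are the base scenario: 5 seeds, `phi_c0 = 0.05`, `T~0 = -1`, cooling at
#' 100 K/s, `dt~ = 2e-4`.
#'
#' @param n grid points per side.
#' @param dt_tilde scaled time step.
#' @param t_end_tilde scaled end time.
#' @param output_every_tilde diagnostics/snapshot interval (scaled time).
#' @param phi_c0 initial bulk solute volume fraction.
#' @param T_tilde0 initial scaled temperature.
#' @param seeds a [seed_spec()], a preset name (`"base5"`, `"dense25"`), or
#'   a list of `seed_spec()` arguments.
#' @param material named list of [material_params()] overrides.
#' @param flow,gravity run toggles.
#' @param tau_sl phase-transition time scale override (`NULL`: Pe = 1).
#' @param outdir optional output directory for snapshots/diagnostics.
#' @param rng_seed integer seed recorded with the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n = 128, dt_tilde = 2e-4, t_end_tilde = 2.5,
                       output_every_tilde = 0.1, phi_c0 = 0.05,
                       T_tilde0 = -1, seeds = "base5", material = list(),
                       flow = TRUE, gravity = TRUE, tau_sl = NULL,
                       outdir = NULL, rng_seed = 1L) {
  if (!is.numeric(dt_tilde) || dt_tilde <= 0) stop("dt_tilde must be > 0")
  if (!is.numeric(t_end_tilde) || t_end_tilde <= 0)
    stop("t_end_tilde must be > 0")
  if (!is.numeric(output_every_tilde) || output_every_tilde <= 0)
    stop("output_every_tilde must be > 0")
  if (!is.numeric(phi_c0) || phi_c0 < 0 || phi_c0 > 1)
    stop("phi_c0 must lie in [0, 1]")
  params <- do.call(material_params, material)
  if (is.character(seeds)) seeds <- seeds_preset(seeds)
  if (is.list(seeds) && !inherits(seeds, "seed_spec"))
    seeds <- do.call(seed_spec, seeds)
  stopifnot(inherits(seeds, "seed_spec"))
  cfg <- list(n = as.integer(n), dt_tilde = dt_tilde,
              t_end_tilde = t_end_tilde,
              output_every_tilde = output_every_tilde, phi_c0 = phi_c0,
              T_tilde0 = T_tilde0, seeds = seeds, material = material,
              flow = isTRUE(flow), gravity = isTRUE(gravity),
              tau_sl = tau_sl, outdir = outdir,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run_config: n=%d, dt~=%g, t_end~=%g, %d seeds (r=%g), phi_c0=%g, T~0=%g\n",
    x$n, x$dt_tilde, x$t_end_tilde, x$seeds$count, x$seeds$radius, x$phi_c0,
    x$T_tilde0))
  cat(sprintf("  flow=%s gravity=%s", x$flow, x$gravity))
  if (length(x$material))
    cat("  material overrides:",
        paste(names(x$material), unlist(x$material), sep = "=",
              collapse = ", "))
  cat("\n")
  invisible(x)
}

.config_keys <- c("n", "dt_tilde", "t_end_tilde", "output_every_tilde",
                  "phi_c0", "T_tilde0", "seeds", "material", "flow",
                  "gravity", "tau_sl", "outdir", "rng_seed")
.seed_keys <- c("count", "positions", "radius", "min_separation", "rng_seed",
                "preset")

#' Read a run configuration from a YAML file
#'
#' Unset keys take the defaults of [run_config()] (an empty file yields the
#' full default run). Unknown keys are rejected with a message naming the
#' key. Physical values are SI; scaled quantities carry the `_tilde` suffix.
#' Seeds are given either as `seeds: {preset: base5}` or as
#' `seeds: {count: ..., radius: ..., positions: [[x, y], ...]}`.
#'
#' @param path path to a YAML configuration file.
#' @return A [run_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  # YAML 1.1 reads the bare key `n` as a boolean; map it back
  names(raw)[names(raw) %in% c("FALSE", "F")] <- "n"
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$seeds)) {
    s <- raw$seeds
    bad <- setdiff(names(s), .seed_keys)
    if (length(bad))
      stop("unknown seeds key(s): ", paste(bad, collapse = ", "))
    if (!is.null(s$preset)) {
      raw$seeds <- seeds_preset(s$preset,
                                radius = if (is.null(s$radius)) 0.3 else
                                  s$radius)
    } else {
      if (!is.null(s$positions))
        s$positions <- do.call(rbind, lapply(s$positions, unlist))
      s$preset <- NULL
      raw$seeds <- do.call(seed_spec, s)
    }
  }
  do.call(run_config, raw)
}

#' Write a run configuration to a YAML file
#'
#' Inverse of [load_config()]: the written file reproduces the
#' configuration exactly on re-read.
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$seeds <- list(
    count = cfg$seeds$count,
    radius = cfg$seeds$radius,
    min_separation = cfg$seeds$min_separation,
    rng_seed = cfg$seeds$rng_seed)
  if (cfg$seeds$count > 0)
    out$seeds$positions <- lapply(seq_len(cfg$seeds$count), function(i)
      as.numeric(cfg$seeds$positions[i, ]))
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
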