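#' Run a freeze-concentration simulation
#'
#' Top-level driver: builds the grid, seeds and initial condition from a
#' [run_config()], integrates the coupled system, and collects diagnostics
#' at every output interval. If `config$outdir` is set, a snapshot of the
#' full field state (RDS) is written at each interval and the diagnostics
#' table as CSV at the end. Runs are deterministic given the configuration
#' (seed placement uses the recorded RNG seed).
#'
#' @param config a [run_config()] (or a path to a YAML config file).
#' @param verbose print a log line per output interval.
#' @return An object of class `freeze_sim`: `config`, final `state`,
#'   `diagnostics` (one row per output interval), `groups`
#'   (dimensionless groups of the run).
#' @examples
#' \donttest{
#' sim <- freeze_sim(run_config(n = 64, t_end_tilde = 0.1))
#' summary(sim)
#' }
#' @export
freeze_sim <- function(config = run_config(), verbose = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$rng_seed)
  params <- do.call(material_params, config$material)
  ctx <- model_context(params, tau_sl = config$tau_sl, flow = config$flow,
                       gravity = config$gravity)
  grid <- spectral_grid(config$n)
  state <- init_fields(grid, config$seeds, config$phi_c0, config$T_tilde0,
                       params)
  steps_per_out <- max(1L, round(config$output_every_tilde / config$dt_tilde))
  n_out <- ceiling(config$t_end_tilde / config$dt_tilde / steps_per_out)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  diag <- list(compute_diagnostics(state))
  t0 <- Sys.time()
  for (i in seq_len(n_out)) {
    run <- advance(state, steps_per_out, config$dt_tilde, ctx)
    state <- run$state
    diag[[i + 1]] <- compute_diagnostics(state)
    if (verbose) {
      d <- diag[[i + 1]]
      message(sprintf(
        "t~=%.3f  max phi_c=%.4f  T~ in [%.2f, %.2f]  area=%.3f  wall=%.1fs",
        d$t_tilde, d$max_phi_c, d$min_T_tilde, d$max_T_tilde,
        d$crystal_area_fraction,
        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    if (!is.null(outdir))
      save_snapshot(state, file.path(outdir,
                                     sprintf("snapshot_%04d.rds", i)),
                    config = config)
  }
  out <- list(config = config, state = state,
              diagnostics = do.call(rbind, diag),
              groups = ctx$groups)
  class(out) <- "freeze_sim"
  if (!is.null(outdir))
    utils::write.csv(out$diagnostics,
                     file.path(outdir, "diagnostics.csv"), row.names = FALSE)
  out
}

#' Save / load a field-state snapshot
#'
#' Snapshots are RDS files holding the field state plus the run
#' configuration and package version, sufficient to resume or render.
#'
#' @param state a `field_state`.
#' @param path file path.
#' @param config optional [run_config()] stored alongside.
#' @return `path` (save) or the snapshot list (load).
#' @export
save_snapshot <- function(state, path, config = NULL) {
  saveRDS(list(state = state, config = config,
               version = as.character(utils::packageVersion("icefield"))),
          path)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot not found: ", path)
  readRDS(path)
}

#' @export
print.freeze_sim <- function(x, ...) {
  cat("freeze_sim run\n")
  print(x$config)
  d <- x$diagnostics[nrow(x$diagnostics), ]
  cat(sprintf(
    "  final t~=%.3f: max phi_c=%.4f (x%.1f over initial bulk), area=%.3f, T~ in [%.2f, %.2f]\n",
    d$t_tilde, d$max_phi_c, d$max_phi_c / max(x$config$phi_c0, 1e-12),
    d$crystal_area_fraction, d$min_T_tilde, d$max_T_tilde))
  invisible(x)
}

#' @export
summary.freeze_sim <- function(object, ...) {
  d <- object$diagnostics
  cat("Freeze-concentration run summary\n")
  print(object$config)
  cat(sprintf("  outputs: %d, t~ from %g to %g\n", nrow(d), d$t_tilde[1],
              d$t_tilde[nrow(d)]))
  cat(sprintf("  max phi_c: initial %.4f -> final %.4f (concentration factor %.2f)\n",
              d$max_phi_c[1], d$max_phi_c[nrow(d)],
              d$max_phi_c[nrow(d)] / max(object$config$phi_c0, 1e-12)))
  cat(sprintf("  crystal area fraction: %.3f -> %.3f\n",
              d$crystal_area_fraction[1],
              d$crystal_area_fraction[nrow(d)]))
  cat(sprintf("  temperature range over run: [%.2f, %.2f] (scaled)\n",
              min(d$min_T_tilde), max(d$max_T_tilde)))
  cat(sprintf("  solute conservation: mean phi_c drift %.3g\n",
              abs(d$mean_phi_c[nrow(d)] - d$mean_phi_c[1])))
  invisible(d)
}

#' Plot a field of a simulation or state
#'
#' Filled image of one of the evolving fields on the periodic domain
#' (base graphics).
#'
#' @param x a `freeze_sim` object.
#' @param field one of `"phi_sl"`, `"phi_c"`, `"T_tilde"`, `"div_v"`,
#'   `"rho"`, `"eta"`, `"speed"`, `"vorticity"`.
#' @param ... passed to [graphics::image()].
#' @return The plotted matrix, invisibly.
#' @export
plot.freeze_sim <- function(x, field = "phi_c", ...) {
  m <- field_matrix(x$state, field)
  graphics::image(x$state$grid$x, x$state$grid$y, t(m),
                  col = grDevices::hcl.colors(128, "viridis"),
                  xlab = "x (scaled)", ylab = "y (scaled)",
                  main = sprintf("%s at t~ = %.3g", field, x$state$t_tilde),
                  useRaster = TRUE, asp = 1, ...)
  invisible(m)
}

#' Extract a named derived field from a state
#'
#' @param state a `field_state`.
#' @param field field name; see [plot.freeze_sim()].
#' @param params a [material_params()] object for derived properties.
#' @return A matrix.
#' @export
field_matrix <- function(state, field = "phi_c",
                         params = material_params()) {
  g <- state$grid
  switch(field,
    phi_sl = state$phi_sl,
    phi_c = state$phi_c,
    T_tilde = state$T_tilde,
    p_tilde = state$p_tilde,
    vx = state$vx, vy = state$vy,
    speed = sqrt(state$vx^2 + state$vy^2),
    div_v = div_spec(state$vx, state$vy, g),
    vorticity = ifft2r(1i * g$KX * fft2(state$vy) -
                         1i * g$KY * fft2(state$vx)),
    rho = density_scaled(params$T0 + params$dT * state$T_tilde,
                         state$phi_sl, .clip_phic(state$phi_c), params,
                         warn = FALSE),
    eta = viscosity_liquid(params$T0 + params$dT * state$T_tilde,
                           .clip_phic(state$phi_c), params, warn = FALSE),
    stop("unknown field: ", field)
  )
}
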