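#' Finite-difference reference implementation of the right-hand sides
#'
#' Second-order central-difference evaluation of the full right-hand sides
#' of the phase-field, solute and thermal equations on the periodic grid
#' (including the terms the time stepper treats implicitly). These serve as
#' an independent cross-check of the spectral operators: on smooth resolved
#' fields the two agree to O(dx^2) under grid refinement.
#'
#' @param state a [init_fields()] state.
#' @param ctx a [model_context()].
#' @return The full RHS field (d/dt~ of the variable).
#' @name fd_rhs
NULL

.sh <- function(f, di, dj) {             # periodic shift: rows +di, cols +dj
  n <- nrow(f)
  f[(seq_len(n) - 1 + di) %% n + 1, (seq_len(n) - 1 + dj) %% n + 1]
}
.fd_dx <- function(f, dx) (.sh(f, 0, 1) - .sh(f, 0, -1)) / (2 * dx)
.fd_dy <- function(f, dx) (.sh(f, 1, 0) - .sh(f, -1, 0)) / (2 * dx)
.fd_lap <- function(f, dx)
  (.sh(f, 0, 1) + .sh(f, 0, -1) + .sh(f, 1, 0) + .sh(f, -1, 0) - 4 * f) / dx^2

#' @rdname fd_rhs
#' @export
fd_rhs_phase <- function(state, ctx = model_context()) {
  pr <- eval_props(state, ctx)
  dx <- state$grid$dx
  base <- rhs_phase_local(state, pr, ctx)
  out <- base + ctx$Ch2 * .fd_lap(state$phi_sl, dx)
  if (ctx$flow)
    out <- out - ctx$Pe * (state$vx * .fd_dx(state$phi_sl, dx) +
                             state$vy * .fd_dy(state$phi_sl, dx))
  out
}

# pointwise (derivative-free) part of the phase RHS, shared by both routes
rhs_phase_local <- function(state, pr, ctx) {
  drive <- ctx$Lambda * (1 - pr$pc) * pr$dP * (state$T_tilde - pr$Teq_tilde) /
    ((1 + ctx$eps_T * state$T_tilde) * (1 + ctx$eps_T * pr$Teq_tilde))
  drive + (1 - pr$pc) * (state$phi_sl - state$phi_sl^3) -
    ctx$R_h * pr$dchi * pr$G
}

#' @rdname fd_rhs
#' @export
fd_rhs_solute <- function(state, ctx = model_context()) {
  pr <- eval_props(state, ctx)
  dx <- state$grid$dx
  p <- ctx$params
  pc <- state$phi_c
  m <- pr$pc - pr$pc^2
  Deff <- (1 - pr$pc) / p$N + pr$pc + m * pr$chi * pr$d2G
  lap <- .fd_lap(pc, dx)
  c4coef <- ctx$Ch2 * ctx$h_R * pr$D * m
  Fx <- ctx$ratio_c * (pr$D * Deff * .fd_dx(pc, dx) +
                         pr$D * m * pr$dG * pr$dchi * .fd_dx(state$phi_sl, dx) -
                         c4coef * .fd_dx(lap, dx))
  Fy <- ctx$ratio_c * (pr$D * Deff * .fd_dy(pc, dx) +
                         pr$D * m * pr$dG * pr$dchi * .fd_dy(state$phi_sl, dx) -
                         c4coef * .fd_dy(lap, dx))
  out <- .fd_dx(Fx, dx) + .fd_dy(Fy, dx)
  if (ctx$flow)
    out <- out - ctx$Pe * (state$vx * .fd_dx(pc, dx) +
                             state$vy * .fd_dy(pc, dx))
  out
}

#' @rdname fd_rhs
#' @param Dphi_sl,Dphi_c material-derivative source fields.
#' @export
fd_rhs_thermal <- function(state, ctx = model_context(), Dphi_sl, Dphi_c) {
  pr <- eval_props(state, ctx)
  dx <- state$grid$dx
  a <- pr$kT / (pr$rho * pr$cp)
  cond <- .fd_dx(a * .fd_dx(state$T_tilde, dx), dx) +
    .fd_dy(a * .fd_dy(state$T_tilde, dx), dx)
  theta <- state$T_tilde + ctx$T0_dT
  latent <- (pr$dP + ctx$Ste2 * theta * pr$dchi * pr$G) / (pr$cp * ctx$Ste1)
  mixing <- (ctx$Ste2 / (pr$cp * ctx$Ste1)) * theta * pr$chi * pr$dG
  out <- ctx$Le * cond - latent * Dphi_sl - mixing * Dphi_c - ctx$Om
  if (ctx$flow)
    out <- out - ctx$Pe * (state$vx * .fd_dx(state$T_tilde, dx) +
                             state$vy * .fd_dy(state$T_tilde, dx))
  out
}

#' Full spectral right-hand sides (explicit + implicit parts combined)
#'
#' Companion to the [fd_rhs] family: evaluates d(phi_sl)/dt~, d(phi_c)/dt~
#' and dT~/dt~ with the spectral operators, including the linear terms the
#' stepper treats implicitly, so the two routes are directly comparable.
#'
#' @inheritParams fd_rhs
#' @param Dphi_sl,Dphi_c material-derivative source fields (thermal only).
#' @return The full RHS field.
#' @export
spectral_rhs_phase <- function(state, ctx = model_context()) {
  pr <- eval_props(state, ctx)
  rhs_phase(state, pr, ctx)$expl + ctx$Ch2 * laplacian_spec(state$phi_sl,
                                                            state$grid)
}

#' @rdname spectral_rhs_phase
#' @export
spectral_rhs_solute <- function(state, ctx = model_context()) {
  pr <- eval_props(state, ctx)
  rhs_solute(state, pr, ctx)$expl
}

#' @rdname spectral_rhs_phase
#' @export
spectral_rhs_thermal <- function(state, ctx = model_context(), Dphi_sl,
                                 Dphi_c) {
  pr <- eval_props(state, ctx)
  rhs_thermal(state, pr, ctx, Dphi_sl, Dphi_c)$expl
}

#' Regression of derived scales and groups against their tabulated values
#'
#' Recomputes the interfacial energy, characteristic times, dimensionless
#' groups, the VTF reference viscosity and the volumetric heat sink from the
#' default material parameters and compares each against its reference
#' (tabulated/printed) value at the tolerance appropriate to how precisely
#' that value is reported.
#'
#' @param params a [material_params()] object.
#' @return data.frame with columns `name, computed, reference, tolerance,
#'   pass, runtime` (seconds).
#' @export
table_regression <- function(params = material_params()) {
  t0 <- proc.time()[["elapsed"]]
  s <- reference_scales(params)
  g <- dimensionless_groups(s, params)
  rows <- list(
    c("gamma_sl",    interfacial_energy(params), 0.0375,  0.005),
    c("tau_T",       s$tau_T,                    9.86e-5, 0.005),
    c("tau_phic",    s$tau_phic,                 0.4762,  0.005),
    c("tau_f",       s$tau_f,                    0.1,     0.005),
    c("Lambda_sl",   g$Lambda_sl,                312.88,  0.001),
    c("Le",          g$Le,                       4830.6,  0.005),
    c("Ste1",        g$Ste1,                     0.0621,  0.005),
    c("Ste2",        g$Ste2,                     0.0136,  0.005),
    c("Ch",          g$Ch,                       0.1,     0.001),
    c("Omega_tilde", g$Omega_tilde,              4.762,   0.001),
    c("Re",          g$Re,                       1.16e-4, 0.01),
    c("Sc",          g$Sc,                       8620.8,  0.01),
    c("Gr_coeff",    g$Gr_coefficient,           25.92,   0.01),
    c("eta0_VTF",    viscosity_liquid(params$T0, 0, params), 0.0018, 0.01),
    c("heat_sink",   params$rho0 * params$cp0 * params$beta_f, 2e8, 0.06)
  )
  out <- data.frame(
    name = vapply(rows, `[[`, "", 1),
    computed = as.numeric(vapply(rows, `[[`, "", 2)),
    reference = as.numeric(vapply(rows, `[[`, "", 3)),
    tolerance = as.numeric(vapply(rows, `[[`, "", 4))
  )
  out$pass <- abs(out$computed - out$reference) <= out$tolerance *
    abs(out$reference)
  out$runtime <- proc.time()[["elapsed"]] - t0
  out
}

#' One-dimensional planar-front benchmark
#'
#' Evolves a two-phase slab (fields uniform along y) at a prescribed uniform
#' scaled temperature with cooling switched off, and tracks the right-moving
#' interface. At `T~ = Teq~` the front is stationary and the profile relaxes
#' to the equilibrium tanh of width `sqrt(2)*Ch`; below the liquidus the
#' front advances into the liquid.
#'
#' @param n grid points per side.
#' @param T_tilde uniform scaled temperature.
#' @param phi_c0 bulk solute volume fraction.
#' @param t_end end time (scaled).
#' @param dt time step.
#' @param half_width initial slab half-width (scaled units).
#' @param width_factor initial interface width relative to equilibrium (use
#'   != 1 to exercise relaxation).
#' @param params a [material_params()] object.
#' @return list: `series` (data.frame t_tilde, front_x, velocity),
#'   `state` (final), `fitted_width`, `equilibrium_width`.
#' @export
planar_front_benchmark <- function(n = 128, T_tilde = 0, phi_c0 = 0,
                                   t_end = 0.5, dt = 2e-4, half_width = 1.5,
                                   width_factor = 1,
                                   params = material_params()) {
  g <- spectral_grid(n)
  ctx <- model_context(material_params_replace(params, beta_f = 1e-12),
                       flow = FALSE)
  Ch <- params$W_sl / params$L
  delta <- sqrt(2) * Ch
  st <- init_fields(g, seed_spec(0), phi_c0, T_tilde, params)
  prof <- tanh((half_width - abs(g$x - pi)) / (width_factor * delta))
  st$phi_sl <- matrix(prof, n, n, byrow = TRUE)
  st$phi_c <- phi_c0 * (1 - st$phi_sl) / 2
  n_chunk <- 10
  steps <- ceiling(t_end / dt / n_chunk)
  rows <- list(data.frame(t_tilde = 0, front_x = .front_x(st)))
  for (i in seq_len(n_chunk)) {
    st <- advance(st, steps, dt, ctx)$state
    rows[[i + 1]] <- data.frame(t_tilde = st$t_tilde, front_x = .front_x(st))
  }
  series <- do.call(rbind, rows)
  series$velocity <- c(NA, diff(series$front_x) / diff(series$t_tilde))
  # fit a tanh to the right-hand interface of the final mid-row profile
  prof <- st$phi_sl[1, ]
  fit <- .fit_tanh_width(g$x, prof, series$front_x[nrow(series)])
  list(series = series, state = st, fitted_width = fit,
       equilibrium_width = delta)
}

# replace fields of a material_params object, revalidating
material_params_replace <- function(params, ...) {
  p <- unclass(params)
  ov <- list(...)
  p[names(ov)] <- ov
  do.call(material_params, p)
}

# x-position of the right-hand zero crossing (descending) of the mid row
.front_x <- function(state) {
  prof <- state$phi_sl[1, ]
  x <- state$grid$x
  i <- which(prof[-length(prof)] > 0 & prof[-1] <= 0)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  x[i] + state$grid$dx * prof[i] / (prof[i] - prof[i + 1])
}

.fit_tanh_width <- function(x, prof, x0) {
  keep <- abs(x - x0) < 0.8
  df <- data.frame(x = x[keep], y = prof[keep])
  fit <- stats::nls(y ~ tanh((x0f - x) / w), data = df,
                    start = list(x0f = x0, w = 0.15))
  stats::coef(fit)[["w"]]
}

#' Run the base freeze-concentration scenario
#'
#' Five seed crystals in a quincunx, initial supercooling `T~ = -1`, bulk
#' solute `phi_c = 0.05`, rapid cooling at 100 K/s: the reference scenario
#' of the model. Returns the diagnostics time series and the final state.
#'
#' @param n grid points per side (>= 128; the late confinement stage leans
#'   on the stepper's limiters at this resolution, see the vignette).
#' @param t_end scaled end time (2.5 covers growth to near-confinement).
#' @param dt scaled time step.
#' @param diag_every_t diagnostics output interval (scaled time).
#' @param params a [material_params()] object.
#' @param flow,gravity run toggles.
#' @param verbose print progress.
#' @return An `icefield_run`: `list(state, diagnostics)`.
#' @export
fig_base_scenario <- function(n = 128, t_end = 2.5, dt = 2e-4,
                              diag_every_t = 0.1,
                              params = material_params(), flow = TRUE,
                              gravity = TRUE, verbose = FALSE) {
  g <- spectral_grid(n)
  ctx <- model_context(params, flow = flow, gravity = gravity)
  st <- init_fields(g, seeds_preset("base5"), phi_c0 = 0.05, T_tilde0 = -1,
                    params)
  advance(st, n_steps = round(t_end / dt), dt = dt, ctx = ctx,
          diag_every = max(1L, round(diag_every_t / dt)), verbose = verbose)
}
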