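#' Advance the coupled system in time
#'
#' Marches the coupled phase-field / solute / thermal / flow system with the
#' pseudo-spectral semi-implicit forward-Euler scheme at a uniform scaled
#' time step (default 2e-4). Per step: (1) properties from the current
#' state; (2) velocity update (potential blowing flux + relaxed solenoidal
#' momentum + projection); (3) explicit right-hand sides of `phi_sl`,
#' `phi_c`, `T~` with 2/3-dealiased nonlinear terms; (4) semi-implicit
#' solves of the stiff linear parts — exact for the constant-coefficient
#' `Ch^2 lap(phi_sl)`, max-coefficient stabilization for the solute's
#' second/fourth-order terms and for conduction; (5) optional diagnostics.
#' The update of each field is mean-preserving (the k = 0 mode passes all
#' filters unchanged), so solute is conserved to round-off in no-flow runs.
#'
#' The run is deterministic given the initial state and arguments. A
#' non-finite field aborts with an error of class `icefield_blowup` carrying
#' the last good state in `$state`.
#'
#' On coarse grids the truncated Fourier band cannot supply the interfacial
#' damping that stabilizes short waves on interface flanks at full
#' resolution (`Ch^2 k^2` evaluated at the paper-scale cutoff), so a small
#' fourth-order spectral stabilization `nu4 * k^4` is added implicitly to
#' the phase-field and solute updates. By default `nu4` adapts each step to
#' the instantaneous destabilizing rate of the thermodynamic driving force,
#' `sigma = 1.45 * Lambda_sl * max((1-phi_c)|T~-Teq~|/corr)` (1.45 is
#' max|P''|), as `nu4 = sigma/kc^4` with `kc = n/3`: damping at the cutoff
#' then matches the worst local growth rate, scales well below the cutoff
#' are barely touched, the stabilization vanishes at thermodynamic
#' equilibrium, and it vanishes as resolution grows.
#'
#' @param state a [init_fields()] state.
#' @param n_steps number of time steps.
#' @param dt scaled time step.
#' @param ctx a [model_context()] (carries parameters and toggles).
#' @param diag_every record diagnostics every this many steps (`NULL`: only
#'   initial and final).
#' @param nu4 fourth-order stabilization coefficient; `NULL` for the
#'   adaptive resolution-aware default above, a number to fix it, 0 to
#'   disable.
#' @param verbose print a log line at each diagnostics interval.
#' @return `list(state, diagnostics)` of class `icefield_run`.
#' @export
advance <- function(state, n_steps, dt = 2e-4, ctx = model_context(),
                    diag_every = NULL, nu4 = NULL, verbose = FALSE) {
  stopifnot(inherits(state, "field_state"), inherits(ctx, "model_context"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  g <- state$grid
  mask <- g$dealias
  adaptive_nu4 <- is.null(nu4)
  kc4 <- (g$n / 3)^4
  K4 <- g$K2^2
  phi_hat <- fft2(state$phi_sl)
  pc_hat <- fft2(state$phi_c)
  T_hat <- fft2(state$T_tilde)
  diag <- list(compute_diagnostics(state))
  t_wall <- Sys.time()
  for (istep in seq_len(n_steps)) {
    pr <- eval_props(state, ctx, phi_hat = phi_hat)
    if (adaptive_nu4) {
      sigma <- 1.45 * ctx$Lambda *
        max((1 - pr$pc) * abs(state$T_tilde - pr$Teq_tilde) /
              ((1 + ctx$eps_T * state$T_tilde) *
                 (1 + ctx$eps_T * pr$Teq_tilde)))
      nu4 <- sigma / kc4
    }
    denom_phi <- 1 + dt * (ctx$Ch2 * g$K2 + nu4 * K4)
    if (ctx$flow) {
      adv_phi_old <- state$vx * pr$gphi$x + state$vy * pr$gphi$y
      Dphi_prev <- state$ddt_phi + ctx$Pe * adv_phi_old
      vel <- update_velocity(state, pr, ctx, Dphi_prev, dt)
      state[c("vx", "vy", "vsx", "vsy", "p_tilde")] <-
        vel[c("vx", "vy", "vsx", "vsy", "p_tilde")]
    }
    # phase field: exact implicit treatment of Ch^2 lap
    rp <- rhs_phase(state, pr, ctx)
    phi_hat <- mask * (phi_hat + dt * fft2(rp$expl)) / denom_phi
    phi_new <- ifft2r(phi_hat)
    ddt_phi <- (phi_new - state$phi_sl) / dt
    # solute: filtered increment, 2nd+4th order max-coefficient split
    rs <- rhs_solute(state, pr, ctx, pc_hat = pc_hat)
    pc_hat <- mask * pc_hat +
      dt * mask * fft2(rs$expl) /
        (1 + dt * (rs$c2 * g$K2 + (rs$c4 + nu4) * K4))
    pc_new <- ifft2r(pc_hat)
    ddt_pc <- (pc_new - state$phi_c) / dt
    # thermal: sources use the material derivatives of the current step
    if (ctx$flow) {
      adv_phi <- state$vx * pr$gphi$x + state$vy * pr$gphi$y
      Dphi <- ddt_phi + ctx$Pe * adv_phi
      gc <- grad_spec(state$phi_c, g)
      Dpc <- ddt_pc + ctx$Pe * (state$vx * gc$x + state$vy * gc$y)
    } else {
      Dphi <- ddt_phi
      Dpc <- ddt_pc
    }
    rt <- rhs_thermal(state, pr, ctx, Dphi, Dpc, T_hat = T_hat)
    T_hat <- mask * T_hat + dt * mask * fft2(rt$expl) / (1 + dt * rt$c2 * g$K2)
    # limiters for the singular film-closure events of the late confinement
    # stage: clamp phase-field excursions; clamp solute ringing and restore
    # the clipped mass uniformly (exactly conservative)
    if (max(abs(phi_new)) > 1.15) {
      phi_new <- pmin(pmax(phi_new, -1.15), 1.15)
      phi_hat <- mask * fft2(phi_new)
      phi_new <- ifft2r(phi_hat)
      ddt_phi <- (phi_new - state$phi_sl) / dt
    }
    if (min(pc_new) < -0.05 || max(pc_new) > 0.95) {
      m0 <- mean(pc_new)
      pc_new <- pmin(pmax(pc_new, -0.05), 0.95)
      pc_new <- pc_new + (m0 - mean(pc_new))
      pc_hat <- mask * fft2(pc_new)
      pc_new <- ifft2r(pc_hat)
    }
    state$phi_sl <- phi_new
    state$phi_c <- pc_new
    state$T_tilde <- ifft2r(T_hat)
    state$ddt_phi <- ddt_phi
    state$t_tilde <- state$t_tilde + dt
    if (istep %% 25 == 0 || istep == n_steps) {
      if (!all(is.finite(phi_new)) || !all(is.finite(state$T_tilde)) ||
          max(abs(phi_new)) > 2 || min(pc_new) < -0.2 ||
          max(pc_new) > 1.2) {
        cond <- structure(
          class = c("icefield_blowup", "error", "condition"),
          list(message = sprintf(
            "solution left its admissible range at t~ = %.4g", state$t_tilde),
            call = sys.call(), state = state))
        stop(cond)
      }
    }
    if (!is.null(diag_every) && istep %% diag_every == 0) {
      diag[[length(diag) + 1]] <- compute_diagnostics(state)
      if (verbose) {
        d <- diag[[length(diag)]]
        cfl <- ctx$Pe * d$max_speed * dt / g$dx
        message(sprintf(
          "t~=%.3f  max phi_c=%.4f  T~ in [%.2f, %.2f]  area=%.3f  CFL=%.2g  wall=%.1fs",
          d$t_tilde, d$max_phi_c, d$min_T_tilde, d$max_T_tilde,
          d$crystal_area_fraction, cfl,
          as.numeric(difftime(Sys.time(), t_wall, units = "secs"))))
      }
    }
  }
  if (is.null(diag_every) || n_steps %% diag_every != 0)
    diag[[length(diag) + 1]] <- compute_diagnostics(state)
  out <- list(state = state, diagnostics = do.call(rbind, diag))
  class(out) <- "icefield_run"
  out
}
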