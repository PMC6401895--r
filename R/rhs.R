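#' Model context: all scaled coefficients of the governing equations
#'
#' Collects the dimensionless groups and derived constants used by the RHS
#' operators and the time stepper, together with the run toggles. This is the
#' single source of truth for the coefficients of the scaled PDE system.
#'
#' @param params a [material_params()] object.
#' @param tau_sl phase-transition time scale; `NULL` for the default
#'   (`L^2/D0`, the Pe = 1 convention).
#' @param flow logical: evolve the velocity field.
#' @param gravity logical: include the buoyancy force.
#' @return An object of class `model_context`.
#' @export
model_context <- function(params = material_params(), tau_sl = NULL,
                          flow = TRUE, gravity = TRUE) {
  scales <- if (is.null(tau_sl)) reference_scales(params) else
    reference_scales(params, tau_sl = tau_sl)
  gr <- dimensionless_groups(scales, params)
  ctx <- list(
    params = params, scales = scales, groups = gr,
    Pe = gr$Pe, Lambda = gr$Lambda_sl, Ch2 = gr$Ch^2, Le = gr$Le,
    Ste1 = gr$Ste1, Ste2 = gr$Ste2, Om = gr$Omega_tilde, Sc = gr$Sc,
    Gr = gr$Gr_coefficient,
    ratio_c = scales$tau_sl / scales$tau_phic,
    R_h = params$R_specific / params$h_sl,   # coefficient of chi' G in Eq. for phi_sl
    h_R = params$h_sl / params$R_specific,   # Cahn-Hilliard gradient coefficient
    eps_T = params$dT / params$T0,           # dT/T0, temperature nonlinearity
    T0_dT = params$T0 / params$dT,
    flow = flow, gravity = gravity
  )
  class(ctx) <- "model_context"
  ctx
}

#' Evaluate all thermophysical property fields on the current state
#'
#' Computes, on the grid, every property entering the scaled equations:
#' interpolation weights `P`, `dP`, Flory `chi`, `dchi`, double-well `G`,
#' `dG`, `d2G` (on the clipped solute fraction), scaled density `rho` and its
#' phase derivative `drho_dphi`, specific heat `cp`, conductivity `kT`,
#' viscosity `eta`, diffusivity `D`, the scaled liquidus `Teq_tilde`, the
#' dimensional temperature `T`, and the phase-field gradient `gphi`.
#'
#' The solute fraction is clipped to `[1e-6, 1 - 1e-6]` before the mobility,
#' double-well, and Mooney terms are formed, so spectral ringing cannot
#' produce negative mobilities.
#'
#' @param state a [init_fields()] state.
#' @param ctx a [model_context()].
#' @param phi_hat optional precomputed spectrum of `phi_sl`.
#' @return A list of property fields.
#' @export
eval_props <- function(state, ctx = model_context(), phi_hat = NULL) {
  p <- ctx$params
  g <- state$grid
  phi <- state$phi_sl
  pc <- .clip_phic(state$phi_c)
  T <- p$T0 + p$dT * state$T_tilde
  Pd <- interp_P(phi, deriv = TRUE)
  P <- Pd$P
  gw <- doublewell_G(pc)
  eta_l <- viscosity_liquid(T, pc, p, warn = FALSE)
  rho_l <- (p$rho0 - 0.017 * (T - p$T0)^2) / p$rho0
  rho_s <- (0.917 * p$rho0 + 0.15 * (p$T0 - T)) / p$rho0
  if (is.null(phi_hat)) phi_hat <- fft2(phi)
  list(
    P = P, dP = Pd$dP,
    chi = P * p$chi_l + (1 - P) * p$chi_s,
    dchi = Pd$dP * (p$chi_l - p$chi_s),
    G = gw$G, dG = gw$dG, d2G = gw$d2G,
    rho = pc * (p$rho_c / p$rho0) + (1 - pc) * (P * rho_l + (1 - P) * rho_s),
    drho_dphi = (1 - pc) * Pd$dP * (rho_l - rho_s),
    cp = specific_heat_scaled(T, phi, pc, p, warn = FALSE),
    kT = thermal_conductivity_scaled(T, phi, pc, p, warn = FALSE),
    eta = P * eta_l / p$eta0 + (1 - P) * p$eta_s_ratio,
    D = P * (T * p$eta0 / (p$T0 * eta_l)) + (1 - P) * p$D_s_ratio,
    Teq_tilde = -55 * pc^2 / p$dT,
    T = T, pc = pc,
    gphi = list(x = ifft2r(1i * g$KX * phi_hat),
                y = ifft2r(1i * g$KY * phi_hat))
  )
}

#' Right-hand side of the phase-field (crystal growth) equation
#'
#' Explicit part of the non-conserved order-parameter equation: advection,
#' the thermodynamic driving force `Lambda_sl (1-phi_c) P' (T~ - Teq~) /
#' ((1 + (dT/T0) T~)(1 + (dT/T0) Teq~))` (supercooling below the local,
#' concentration-depressed liquidus drives freezing), the double-well
#' restoring term `(1-phi_c)(phi - phi^3)`, and the solute-exclusion barrier
#' `-(R/h_sl) chi' G`. The stiff interfacial diffusion `Ch^2 lap(phi)` is
#' returned as the implicit coefficient.
#'
#' @param state a [init_fields()] state.
#' @param props [eval_props()] output for `state`.
#' @param ctx a [model_context()].
#' @return `list(expl = field, implicit_coeff = Ch^2)`.
#' @export
rhs_phase <- function(state, props = eval_props(state, ctx),
                      ctx = model_context()) {
  pc <- props$pc
  Tt <- state$T_tilde
  drive <- ctx$Lambda * (1 - pc) * props$dP * (Tt - props$Teq_tilde) /
    ((1 + ctx$eps_T * Tt) * (1 + ctx$eps_T * props$Teq_tilde))
  expl <- drive + (1 - pc) * (state$phi_sl - state$phi_sl^3) -
    ctx$R_h * props$dchi * props$G
  if (ctx$flow)
    expl <- expl - ctx$Pe * (state$vx * props$gphi$x + state$vy * props$gphi$y)
  if (any(!is.finite(expl)))
    stop("non-finite phase-field RHS: numerical blow-up")
  list(expl = expl, implicit_coeff = ctx$Ch2)
}

#' Right-hand side of the conserved solute (freeze-concentration) equation
#'
#' Explicit part of the Cahn-Hilliard-type solute equation in conservative
#' (divergence) form. The flux has a Fickian-plus-enthalpic part
#' `D~ [ (1-phi_c)/N + phi_c + (phi_c - phi_c^2) chi G'' ] grad(phi_c)
#'  + D~ (phi_c - phi_c^2) G' grad(chi)` — the `grad(chi)` drift is the
#' solute-exclusion flux at the moving front — and a fourth-order gradient
#' part `-Ch^2 (h_sl/R) D~ (phi_c - phi_c^2) grad(lap(phi_c))`. Both carry
#' the time-scale ratio `tau_sl/tau_phic`. The stabilization constants for
#' the semi-implicit step (the domain maxima of the second- and
#' fourth-order coefficients) are returned alongside.
#'
#' @inheritParams rhs_phase
#' @param pc_hat optional precomputed spectrum of `phi_c`.
#' @return `list(expl, c2, c4)`.
#' @export
rhs_solute <- function(state, props = eval_props(state, ctx),
                       ctx = model_context(), pc_hat = NULL) {
  g <- state$grid
  p <- ctx$params
  if (is.null(pc_hat)) pc_hat <- fft2(state$phi_c)
  gcx <- ifft2r(1i * g$KX * pc_hat)
  gcy <- ifft2r(1i * g$KY * pc_hat)
  lap_hat <- -g$K2 * pc_hat
  glx <- ifft2r(1i * g$KX * lap_hat)
  gly <- ifft2r(1i * g$KY * lap_hat)
  m <- props$pc - props$pc^2                 # degenerate mobility
  Deff <- (1 - props$pc) / p$N + props$pc + m * props$chi * props$d2G
  drift <- props$D * m * props$dG            # coefficient of grad(chi)
  c4coef <- ctx$Ch2 * ctx$h_R * props$D * m
  Fx <- ctx$ratio_c * (props$D * Deff * gcx + drift * props$dchi *
                         props$gphi$x - c4coef * glx)
  Fy <- ctx$ratio_c * (props$D * Deff * gcy + drift * props$dchi *
                         props$gphi$y - c4coef * gly)
  expl <- ifft2r(1i * g$KX * fft2(Fx) + 1i * g$KY * fft2(Fy))
  if (ctx$flow)
    expl <- expl - ctx$Pe * (state$vx * gcx + state$vy * gcy)
  if (any(!is.finite(expl)))
    stop("non-finite solute RHS: numerical blow-up")
  list(expl = expl,
       c2 = ctx$ratio_c * max(props$D * Deff),
       c4 = ctx$ratio_c * max(c4coef))
}

#' Right-hand side of the scaled thermal energy equation
#'
#' Advection, variable-coefficient conduction
#' `Le div( kT~/(rho~ cp~) grad(T~) )`, latent-heat and partition-energy
#' release proportional to the material derivative of the phase field,
#' `-(1/(cp~ Ste1)) [P' + Ste2 (T~ + T0/dT) chi' G] Dphi_sl/Dt~`, the mixing
#' term `-(Ste2/(cp~ Ste1)) (T~ + T0/dT) chi G' Dphi_c/Dt~`, and the uniform
#' volumetric cooling sink `-Omega~`. Freezing (`Dphi_sl/Dt~ > 0` where
#' `P' < 0`) heats the interface: the exothermic signature of the model.
#'
#' @inheritParams rhs_phase
#' @param Dphi_sl material derivative of `phi_sl` over the current step.
#' @param Dphi_c material derivative of `phi_c` over the current step.
#' @param T_hat optional precomputed spectrum of `T_tilde`.
#' @return `list(expl, c2)` with `c2 = Le * max(kT~/(rho~ cp~))`, the
#'   constant for the semi-implicit conduction split.
#' @export
rhs_thermal <- function(state, props = eval_props(state, ctx),
                        ctx = model_context(), Dphi_sl, Dphi_c,
                        T_hat = NULL) {
  g <- state$grid
  if (is.null(T_hat)) T_hat <- fft2(state$T_tilde)
  gTx <- ifft2r(1i * g$KX * T_hat)
  gTy <- ifft2r(1i * g$KY * T_hat)
  a <- props$kT / (props$rho * props$cp)
  cond <- ifft2r(1i * g$KX * fft2(a * gTx) + 1i * g$KY * fft2(a * gTy))
  theta <- state$T_tilde + ctx$T0_dT
  latent <- (props$dP + ctx$Ste2 * theta * props$dchi * props$G) /
    (props$cp * ctx$Ste1)
  mixing <- (ctx$Ste2 / (props$cp * ctx$Ste1)) * theta * props$chi * props$dG
  expl <- ctx$Le * cond - latent * Dphi_sl - mixing * Dphi_c - ctx$Om
  if (ctx$flow)
    expl <- expl - ctx$Pe * (state$vx * gTx + state$vy * gTy)
  if (any(!is.finite(expl)))
    stop("non-finite thermal RHS: numerical blow-up")
  list(expl = expl, c2 = ctx$Le * max(a))
}

#' Update the velocity and pressure fields
#'
#' The velocity is split into a potential part carrying the prescribed
#' divergence (the blowing mass flux of the quasi-incompressible continuity
#' equation, `div v~ = -(1/(Pe rho~)) (drho~/dphi_sl) Dphi_sl/Dt~`) and a
#' solenoidal part advanced one explicit-relaxation step of the
#' low-Reynolds-number momentum equation (inertia dropped, unsteady term
#' `(1/Sc) dv/dt~` retained, variable viscosity semi-implicitly stabilized
#' by its domain maximum, buoyancy `-Gr (1 - rho~) e_g`), followed by a
#' pressure-Poisson projection back onto divergence-free fields. The k = 0
#' mode of the momentum forcing is removed (zero net momentum gauge for the
#' fully periodic box).
#'
#' @inheritParams rhs_thermal
#' @param Dphi_sl material derivative of `phi_sl` (from the previous step at
#'   the start of a step; the fluid responds to the front motion just
#'   computed).
#' @param dt scaled time step.
#' @return `list(vx, vy, vsx, vsy, p_tilde, div_target)`.
#' @export
update_velocity <- function(state, props = eval_props(state, ctx),
                            ctx = model_context(), Dphi_sl, dt = 2e-4) {
  g <- state$grid
  n <- g$n
  # --- potential part: prescribed divergence from the density jump
  S <- -(1 / (ctx$Pe * props$rho)) * props$drho_dphi * Dphi_sl
  S_hat <- dealias_spec(fft2(S), g)
  S_hat[1, 1] <- 0                      # periodic box: remove net expansion
  pot_hat <- -S_hat * g$K2inv
  vpx <- ifft2r(1i * g$KX * pot_hat)
  vpy <- ifft2r(1i * g$KY * pot_hat)
  # --- solenoidal part: one relaxation step of the momentum equation
  vx_hat <- fft2(state$vx); vy_hat <- fft2(state$vy)
  ux <- ifft2r(1i * g$KX * vx_hat); uy <- ifft2r(1i * g$KY * vx_hat)
  wx <- ifft2r(1i * g$KX * vy_hat); wy <- ifft2r(1i * g$KY * vy_hat)
  sxx <- 2 * props$eta * ux
  sxy <- props$eta * (uy + wx)
  syy <- 2 * props$eta * wy
  sxy_hat <- fft2(sxy)
  Fx_hat <- 1i * g$KX * fft2(sxx) + 1i * g$KY * sxy_hat
  Fy_hat <- 1i * g$KX * sxy_hat + 1i * g$KY * fft2(syy)
  if (ctx$gravity)
    Fy_hat <- Fy_hat + fft2(ctx$Gr * (1 - props$rho))
  Fx_hat <- dealias_spec(Fx_hat, g); Fy_hat <- dealias_spec(Fy_hat, g)
  Fx_hat[1, 1] <- 0; Fy_hat[1, 1] <- 0  # zero net momentum gauge
  eta_bar <- max(props$eta)
  vsx_hat <- fft2(state$vsx); vsy_hat <- fft2(state$vsy)
  den <- 1 + dt * ctx$Sc * eta_bar * g$K2
  star_x <- (vsx_hat + dt * ctx$Sc * (Fx_hat + eta_bar * g$K2 * vsx_hat)) / den
  star_y <- (vsy_hat + dt * ctx$Sc * (Fy_hat + eta_bar * g$K2 * vsy_hat)) / den
  # --- pressure projection of the solenoidal part
  div_hat <- 1i * (g$KX * star_x + g$KY * star_y)
  p_hat <- -div_hat * g$K2inv / (dt * ctx$Sc)
  vsx_new <- star_x - g$KX * (g$KX * star_x + g$KY * star_y) * g$K2inv
  vsy_new <- star_y - g$KY * (g$KX * star_x + g$KY * star_y) * g$K2inv
  vsx <- ifft2r(dealias_spec(vsx_new, g))
  vsy <- ifft2r(dealias_spec(vsy_new, g))
  out <- list(vx = vpx + vsx, vy = vpy + vsy, vsx = vsx, vsy = vsy,
              p_tilde = ifft2r(p_hat), div_target = ifft2r(S_hat))
  if (any(!vapply(out[1:2], function(f) all(is.finite(f)), logical(1))))
    stop("non-finite velocity: numerical blow-up")
  out
}
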