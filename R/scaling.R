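#' Characteristic time and velocity scales
#'
#' The model has six characteristic times: solid-liquid phase transition
#' `tau_sl = 1/(rho0 h_sl M_sl)` (an input; the interfacial mobility `M_sl`
#' is back-computed from it), solute diffusion `tau_phic = L^2/D0`, thermal
#' diffusion `tau_T = rho0 cp0 L^2 / kT0`, viscous diffusion
#' `tau_vis = rho0 L^2 / eta0`, convection `tau_conv = L/U`, and cooling
#' `tau_f = dT / beta_f`. By default the characteristic velocity is tied to
#' the phase-transition scale, `U = L / tau_sl`, which sets the Peclet number
#' to 1.
#'
#' @param params a [material_params()] object.
#' @param tau_sl phase-transition time scale, s. Defaults to `L^2/D0` so that
#'   phase transition, solute diffusion, and convection share one scale.
#' @param U characteristic velocity, m/s; defaults to `L/tau_sl`.
#' @return An object of class `reference_scales` with fields `L, U, M_sl,
#'   tau_sl, tau_phic, tau_T, tau_vis, tau_conv, tau_f`.
#' @examples
#' reference_scales()        # tau_T ~ 9.86e-5 s, tau_f = 0.1 s
#' @export
reference_scales <- function(params = material_params(),
                             tau_sl = params$L^2 / params$D0,
                             U = params$L / tau_sl) {
  stopifnot(inherits(params, "material_params"))
  if (!is.finite(tau_sl) || tau_sl <= 0) stop("tau_sl must be positive")
  if (!is.finite(U) || U <= 0) stop("U must be positive")
  s <- list(
    L = params$L,
    U = U,
    M_sl = 1 / (params$rho0 * params$h_sl * tau_sl),
    tau_sl = tau_sl,
    tau_phic = params$L^2 / params$D0,
    tau_T = params$rho0 * params$cp0 * params$L^2 / params$kT0,
    tau_vis = params$rho0 * params$L^2 / params$eta0,
    tau_conv = params$L / U,
    tau_f = params$dT / params$beta_f
  )
  class(s) <- "reference_scales"
  s
}

#' @export
print.reference_scales <- function(x, ...) {
  cat("Reference scales\n")
  cat(sprintf("  L        %.4g m\n", x$L))
  cat(sprintf("  U        %.4g m/s\n", x$U))
  cat(sprintf("  M_sl     %.4g (kg K s/J)^-1\n", x$M_sl))
  for (nm in c("tau_sl", "tau_phic", "tau_T", "tau_vis", "tau_conv", "tau_f"))
    cat(sprintf("  %-8s %.4g s\n", nm, x[[nm]]))
  invisible(x)
}

#' Dimensionless groups of the scaled governing equations
#'
#' Computes the ten groups appearing in the scaled phase-field, solute,
#' thermal, and momentum equations:
#' `Pe = tau_sl/tau_conv` (convective vs. diffusive solute transport),
#' `Lambda_sl = La dT/(h_sl T0^2)` (phase-change number: latent heat vs.
#' interfacial energy barrier), `Ch = W_sl/L` (Cahn-Hilliard number:
#' interface thickness vs. domain scale), `Le = tau_sl/tau_T`,
#' `Ste1 = cp0 dT/La`, `Ste2 = R dT/La`, `Omega_tilde = tau_sl/tau_f`
#' (scaled cooling rate), `Sc = tau_sl/tau_vis`, `Re = tau_vis/tau_conv`,
#' and the Grashof coefficient `Gr = rho0 L^2 g/(eta0 U)` multiplying
#' `(1 - rho~)` in the buoyancy force.
#'
#' @param scales a [reference_scales()] object.
#' @param params a [material_params()] object.
#' @return An object of class `dimensionless_groups`.
#' @examples
#' dimensionless_groups()    # Lambda_sl ~ 313, Le ~ 4831, Ch = 0.1, ...
#' @export
dimensionless_groups <- function(scales = reference_scales(params),
                                 params = material_params()) {
  stopifnot(inherits(scales, "reference_scales"),
            inherits(params, "material_params"))
  gset <- list(
    Pe = scales$tau_sl / scales$tau_conv,
    Lambda_sl = params$La * params$dT / (params$h_sl * params$T0^2),
    Ch = params$W_sl / params$L,
    Le = scales$tau_sl / scales$tau_T,
    Ste1 = params$cp0 * params$dT / params$La,
    Ste2 = params$R_specific * params$dT / params$La,
    Omega_tilde = scales$tau_sl / scales$tau_f,
    Sc = scales$tau_sl / scales$tau_vis,
    Re = scales$tau_vis / scales$tau_conv,
    Gr_coefficient = params$rho0 * params$L^2 * params$g /
      (params$eta0 * scales$U)
  )
  class(gset) <- "dimensionless_groups"
  gset
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("Dimensionless groups\n")
  lab <- c(Pe = "Peclet", Lambda_sl = "phase-change", Ch = "Cahn-Hilliard",
           Le = "interfacial Lewis", Ste1 = "Stefan (sensible)",
           Ste2 = "Stefan (partition)", Omega_tilde = "scaled cooling rate",
           Sc = "Schmidt", Re = "Reynolds",
           Gr_coefficient = "Grashof coefficient of (1 - rho~)")
  for (nm in names(x))
    cat(sprintf("  %-15s %-34s %.6g\n", nm, lab[[nm]], x[[nm]]))
  invisible(x)
}

#' Scales and groups report as a data.frame
#'
#' Convenience accessor used by the CLI `groups` subcommand and the
#' benchmark suite.
#'
#' @inheritParams dimensionless_groups
#' @return data.frame with columns `name`, `value`.
#' @export
scaling_report <- function(params = material_params(),
                           scales = reference_scales(params)) {
  gr <- dimensionless_groups(scales, params)
  vals <- c(gamma_sl = interfacial_energy(params),
            unlist(scales[c("tau_sl", "tau_phic", "tau_T", "tau_vis",
                            "tau_conv", "tau_f")]),
            U = scales$U, unlist(unclass(gr)))
  data.frame(name = names(vals), value = unname(vals))
}
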