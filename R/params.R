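#' Material parameters for the freeze-concentration model
#'
#' Bundles every dimensional constant and correlation coefficient the model
#' needs: reference properties of water/ice at the equilibrium freezing point
#' `T0`, the interfacial-energy parameters of the phase field, Flory
#' interaction parameters controlling solute exclusion, and process settings
#' (cooling rate, domain length scale).
#'
#' Defaults are the sucrose/water values used throughout the package:
#' \describe{
#'   \item{rho0}{reference density of water at `T0`, 999.8 kg/m^3}
#'   \item{cp0}{reference specific heat (ice branch at `T0`), 2110 J/(kg K)}
#'   \item{kT0}{reference thermal conductivity (ice branch at `T0`), 2.14 W/(m K)}
#'   \item{D0}{reference solute diffusivity in dilute solution at `T0`,
#'     2.1e-10 m^2/s}
#'   \item{eta0}{reference dynamic viscosity of water at `T0`, 1.8e-3 Pa s}
#'   \item{La}{latent heat of fusion, 3.4e5 J/kg}
#'   \item{h_sl}{solid-liquid energy-barrier coefficient, 0.1456 J/(kg K)}
#'   \item{W_sl}{interfacial thickness, 1e-6 m}
#'   \item{chi_s, chi_l}{Flory interaction parameters in the crystal and
#'     liquid phase; `chi_s > chi_l` drives solute exclusion from ice}
#'   \item{N}{solute-to-water ratio of partial molar volume (~11.5 for sucrose)}
#'   \item{T0}{equilibrium freezing temperature of pure water, 273.15 K}
#'   \item{dT}{characteristic subcooled temperature used for temperature
#'     scaling, 10 K}
#'   \item{beta_f}{bulk cooling rate, K/s}
#'   \item{g}{gravitational acceleration, m/s^2}
#'   \item{R_specific}{specific gas constant of water, 461.5 J/(kg K)}
#'   \item{rho_c}{solute (sucrose) density, 1587 kg/m^3}
#'   \item{eta_s_ratio}{crystal-to-reference viscosity ratio (>= 1e4; the
#'     crystal is treated as a highly viscous fluid)}
#'   \item{D_s_ratio}{crystal-to-reference diffusivity ratio (<< 1)}
#'   \item{L}{mesoscale length scale; the periodic domain is 2*pi*L square}
#' }
#'
#' The phase-field gradient coefficient is derived, not free:
#' `xi_sl^2 = rho0 * h_sl * W_sl^2` (and the solute gradient coefficient is
#' taken equal to it).
#'
#' @param ... named overrides of any default listed above.
#' @return An object of class `material_params` (a named list).
#' @examples
#' p <- material_params()
#' interfacial_energy(p)         # ~0.0375 J/m^2
#' material_params(beta_f = 50)  # slower cooling
#' @export
material_params <- function(...) {
  p <- list(
    rho0 = 999.8, cp0 = 2110, kT0 = 2.14, D0 = 2.1e-10, eta0 = 1.8e-3,
    La = 3.4e5, h_sl = 0.1456, W_sl = 1e-6, chi_s = 2.5, chi_l = 0.5,
    N = 11.5, T0 = 273.15, dT = 10, beta_f = 100, g = 9.81,
    R_specific = 461.5, rho_c = 1587, eta_s_ratio = 1e4, D_s_ratio = 1e-4,
    L = 1e-5
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("all overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown material parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_material_params(p)
  class(p) <- "material_params"
  p
}

validate_material_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-finite or non-scalar material parameter(s): ",
         paste(names(p)[!num], collapse = ", "))
  pos <- setdiff(names(p), c("chi_s", "chi_l"))  # chi need only be > 0 too
  bad <- vapply(p[pos], function(x) x <= 0, logical(1))
  if (any(bad))
    stop("material parameter(s) must be strictly positive: ",
         paste(pos[bad], collapse = ", "))
  if (p$chi_s <= p$chi_l)
    stop("chi_s must exceed chi_l (solute exclusion from the crystal)")
  if (p$eta_s_ratio < 1e4)
    stop("eta_s_ratio must be at least 1e4 (rigid-crystal limit)")
  if (p$D_s_ratio >= 1)
    stop("D_s_ratio must be << 1 (negligible solute mobility in ice)")
  invisible(p)
}

#' @export
print.material_params <- function(x, ...) {
  cat("Material parameters (SI units)\n")
  nm <- names(x)
  for (i in seq_along(x))
    cat(sprintf("  %-12s %g\n", nm[i], x[[i]]))
  cat(sprintf("  derived xi_sl^2 = rho0*h_sl*W_sl^2 = %.4g\n",
              x$rho0 * x$h_sl * x$W_sl^2))
  invisible(x)
}

#' Solid-liquid interfacial energy implied by the phase-field parameters
#'
#' For the equilibrium tanh interface profile the excess free energy per unit
#' area is `gamma_sl = (2*sqrt(2)/3) * rho0 * h_sl * W_sl * T0`. With the
#' default parameters this gives ~0.0375 J/m^2, half the free-surface tension
#' of water at 0 degC.
#'
#' @param params a [material_params()] object.
#' @return Interfacial energy in J/m^2.
#' @export
interfacial_energy <- function(params) {
  stopifnot(inherits(params, "material_params"))
  (2 * sqrt(2) / 3) * params$rho0 * params$h_sl * params$W_sl * params$T0
}
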