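#' Phase interpolation polynomial P
#'
#' Fifth-order interpolation polynomial weighting the liquid branch of a
#' two-phase property: `P(-1) = 1` (liquid), `P(1) = 0` (solid), with
#' `P' = P'' = 0` at both pure phases so that bulk phases feel no spurious
#' thermodynamic force. Spectral solutions overshoot slightly near
#' interfaces; overshooting inputs are clamped to \[-1, 1\]. Outside the
#' wells the polynomial tail would re-activate the (large) thermodynamic
#' driving force in the bulk and amplify ringing, while the clamped
#' continuation is C1 (`P' = P'' = 0` at the wells) and keeps the pure
#' phases exact fixed points.
#'
#' @param phi_sl phase field value(s) in about \[-1, 1\].
#' @param deriv if `TRUE`, also return the derivative.
#' @return `P` (numeric like `phi_sl`), or `list(P, dP)` when `deriv = TRUE`.
#' @examples
#' interp_P(c(-1, 0, 1))     # 1, 0.5, 0
#' @export
interp_P <- function(phi_sl, deriv = FALSE) {
  if (any(!is.finite(phi_sl)))
    stop("non-finite phase field value: corrupted field")
  x <- pmin(pmax(phi_sl, -1), 1)
  P <- 0.5 - (15 / 16) * (x^5 / 5 - 2 * x^3 / 3 + x)
  if (!deriv) return(P)
  dP <- -(15 / 16) * (x^2 - 1)^2
  list(P = P, dP = dP)
}

#' Double-well mixing function G and derivatives
#'
#' `G(phi_c) = 4 phi_c^2 (1 - phi_c)^2` replaces the ideal `phi_c(1-phi_c)`
#' mixing form so the solute volume fraction is kept inside \[0, 1\] during
#' the computation.
#'
#' @param phi_c solute volume fraction(s).
#' @return `list(G, dG, d2G)`.
#' @export
doublewell_G <- function(phi_c) {
  if (any(!is.finite(phi_c)))
    stop("non-finite solute volume fraction")
  G <- 4 * phi_c^2 * (1 - phi_c)^2
  dG <- 8 * phi_c * (1 - phi_c) * (1 - 2 * phi_c)
  d2G <- 8 * (1 - 6 * phi_c + 6 * phi_c^2)
  list(G = G, dG = dG, d2G = d2G)
}

#' Phase-interpolated Flory interaction parameter
#'
#' `chi(phi_sl) = P * chi_l + (1 - P) * chi_s`: the liquid value in solution,
#' the (larger) solid value inside the crystal. The jump `chi_s > chi_l`
#' raises the mixing energy of solute inside ice and is what drives solute
#' exclusion at the freezing front.
#'
#' @inheritParams interp_P
#' @param params a [material_params()] object.
#' @return `list(chi, dchi)` with `dchi = dP * (chi_l - chi_s)`.
#' @export
chi_mix <- function(phi_sl, params = material_params()) {
  Pd <- interp_P(phi_sl, deriv = TRUE)
  list(chi = Pd$P * params$chi_l + (1 - Pd$P) * params$chi_s,
       dchi = Pd$dP * (params$chi_l - params$chi_s))
}

.check_T_range <- function(T, warn) {
  if (warn && (any(T < 230) || any(T > 280)))
    warning("temperature outside the 230-280 K correlation range; ",
            "extrapolating", call. = FALSE)
}

# clip policy for phi_c ahead of G / mobility / Mooney evaluation
.clip_phic <- function(phi_c, eps = 1e-6) pmin(pmax(phi_c, eps), 1 - eps)

#' Scaled local density
#'
#' Mixture density scaled by `rho0`:
#' `rho~ = phi_c*rho_c~ + (1-phi_c)*(P*rho_l~(T) + (1-P)*rho_s~(T))`,
#' with supercooled-water and ice correlations
#' `rho_l(T) = rho0 - 0.017 (T-T0)^2` and
#' `rho_s(T) = 0.917 rho0 + 0.15 (T0-T)` (kg/m^3), and constant sucrose
#' density `rho_c`. Ice is lighter than the solution, which both blows mass
#' off a growing crystal and makes it buoyant.
#'
#' @param T absolute temperature(s), K.
#' @param phi_sl phase field.
#' @param phi_c solute volume fraction.
#' @param params a [material_params()] object.
#' @param warn warn when `T` leaves the 230-280 K correlation range.
#' @return Scaled density (dimensionless).
#' @export
density_scaled <- function(T, phi_sl, phi_c, params = material_params(),
                           warn = TRUE) {
  .check_T_range(T, warn)
  P <- interp_P(phi_sl)
  rho_l <- (params$rho0 - 0.017 * (T - params$T0)^2) / params$rho0
  rho_s <- (0.917 * params$rho0 + 0.15 * (params$T0 - T)) / params$rho0
  rho <- phi_c * (params$rho_c / params$rho0) +
    (1 - phi_c) * (P * rho_l + (1 - P) * rho_s)
  if (any(rho <= 0)) stop("non-physical (<= 0) scaled density")
  rho
}

#' Scaled specific heat
#'
#' `cp~ = (P*cp_l(T,phi_c) + (1-P)*cp_s(T)) / cp0` with the ice branch
#' `cp_s = cp0 + 8 (T - T0)` (independent of solute, which is excluded from
#' ice) and the supercooled-solution branch
#' `cp_l = 4180 * (1 - 0.953*phi_c*(1 - 0.588*phi_c) + 1e-3 (T - T0))`.
#'
#' @inheritParams density_scaled
#' @return Scaled specific heat (dimensionless; 1 for ice at `T0`).
#' @export
specific_heat_scaled <- function(T, phi_sl, phi_c, params = material_params(),
                                 warn = TRUE) {
  .check_T_range(T, warn)
  P <- interp_P(phi_sl)
  cp_s <- params$cp0 + 8 * (T - params$T0)
  cp_l <- 4180 * (1 - 0.953 * phi_c * (1 - 0.588 * phi_c) +
                    1e-3 * (T - params$T0))
  cp <- (P * cp_l + (1 - P) * cp_s) / params$cp0
  if (any(cp <= 0)) stop("non-physical (<= 0) scaled specific heat")
  cp
}

#' Scaled thermal conductivity
#'
#' `kT~ = (P*kT_l(T,phi_c) + (1-P)*kT_s(T)) / kT0` with the ice branch
#' `kT_s = kT0 + 0.013 (T0 - T)` (ice conducts better as it cools) and
#' `kT_l = 0.58 * (1 - 0.905*phi_c*(1 - 0.588*phi_c) + 2.6e-3 (T - T0))`.
#'
#' @inheritParams density_scaled
#' @return Scaled thermal conductivity (dimensionless; 1 for ice at `T0`).
#' @export
thermal_conductivity_scaled <- function(T, phi_sl, phi_c,
                                        params = material_params(),
                                        warn = TRUE) {
  .check_T_range(T, warn)
  P <- interp_P(phi_sl)
  kT_s <- params$kT0 + 0.013 * (params$T0 - T)
  kT_l <- 0.58 * (1 - 0.905 * phi_c * (1 - 0.588 * phi_c) +
                    2.6e-3 * (T - params$T0))
  kT <- (P * kT_l + (1 - P) * kT_s) / params$kT0
  if (any(kT <= 0)) stop("non-physical (<= 0) scaled thermal conductivity")
  kT
}

#' Liquid-branch dynamic viscosity (dimensional)
#'
#' Vogel-Fulcher-Tammann law for supercooled water,
#' `eta_l(T) = 4.442e-5 * exp(2.288 * 168.9 / (T - 168.9))` Pa s (the
#' prefactor is the extrapolated viscosity at the VTF singular temperature
#' 168.9 K), multiplied by Mooney's concentration factor
#' `exp(6.3 phi_c / (1 - 0.85 phi_c))` fitted to sucrose solutions at 0 degC.
#'
#' @inheritParams density_scaled
#' @return Dynamic viscosity in Pa s.
#' @export
viscosity_liquid <- function(T, phi_c = 0, params = material_params(),
                             warn = TRUE) {
  if (any(!is.finite(T))) stop("non-finite temperature")
  if (any(T <= 168.9))
    stop("temperature at or below the VTF singular temperature 168.9 K")
  .check_T_range(T, warn)
  pc <- .clip_phic(phi_c)
  4.442e-5 * exp(2.288 * 168.9 / (T - 168.9)) * exp(6.3 * pc / (1 - 0.85 * pc))
}

#' Scaled dynamic viscosity
#'
#' `eta~ = P * eta_l(T, phi_c)/eta0 + (1 - P) * eta_s_ratio`; the crystal is
#' treated as a Newtonian fluid 1e4 times more viscous than water, which makes
#' it effectively rigid (no-slip at the interface is emergent).
#'
#' @inheritParams density_scaled
#' @return Scaled viscosity (dimensionless).
#' @export
viscosity_scaled <- function(T, phi_sl, phi_c, params = material_params(),
                             warn = TRUE) {
  P <- interp_P(phi_sl)
  eta_l <- viscosity_liquid(T, phi_c, params, warn = warn) / params$eta0
  P * eta_l + (1 - P) * params$eta_s_ratio
}

#' Scaled solute diffusivity
#'
#' Stokes-Einstein scaling of the liquid-branch diffusivity,
#' `D_l~ = T * eta0 / (T0 * eta_l(T, phi_c))`, interpolated with the constant
#' crystal value `D_s~ = D_s_ratio` (1e-4 by default):
#' `D~ = P * D_l~ + (1 - P) * D_s~`. Crowding (via the Mooney viscosity rise)
#' sharply reduces solute mobility in concentrated interstitial liquid.
#'
#' @inheritParams density_scaled
#' @return Scaled diffusivity (dimensionless).
#' @export
diffusivity_scaled <- function(T, phi_sl, phi_c, params = material_params(),
                               warn = TRUE) {
  P <- interp_P(phi_sl)
  eta_l <- viscosity_liquid(T, phi_c, params, warn = warn)
  D_l <- T * params$eta0 / (params$T0 * eta_l)
  P * D_l + (1 - P) * params$D_s_ratio
}

#' Liquidus temperature of the sucrose-water system
#'
#' Freezing-point depression correlated from the sucrose-water phase diagram:
#' `Teq(phi_c) = T0 - 55 phi_c^2` (K). Also returned in scaled form
#' `Teq~ = (Teq - T0)/dT`.
#'
#' @param phi_c solute volume fraction(s) in \[0, 1\].
#' @param params a [material_params()] object.
#' @return `list(Teq, Teq_tilde)`.
#' @examples
#' liquidus_temperature(0.05)$Teq    # 273.0125 K
#' @export
liquidus_temperature <- function(phi_c, params = material_params()) {
  if (any(!is.finite(phi_c)) || any(phi_c < 0) || any(phi_c > 1))
    stop("phi_c must lie in [0, 1]")
  Teq <- params$T0 - 55 * phi_c^2
  list(Teq = Teq, Teq_tilde = (Teq - params$T0) / params$dT)
}

#' Tabulate the property correlations
#'
#' Evaluates the pure-branch correlations on a grid of temperature and
#' solute volume fraction, for plotting or export to CSV.
#'
#' @param T temperatures, K.
#' @param phi_c solute volume fractions.
#' @param params a [material_params()] object.
#' @return A data.frame with columns `T, phi_c, rho_l, rho_s, cp_l, cp_s,
#'   kT_l, kT_s, eta_l, D_l, Teq` (all dimensional, SI).
#' @export
property_table <- function(T = seq(230, 275, by = 5),
                           phi_c = c(0, 0.05, 0.1, 0.2, 0.35),
                           params = material_params()) {
  g <- expand.grid(T = T, phi_c = phi_c)
  eta_l <- viscosity_liquid(g$T, g$phi_c, params, warn = FALSE)
  data.frame(
    T = g$T, phi_c = g$phi_c,
    rho_l = params$rho0 - 0.017 * (g$T - params$T0)^2,
    rho_s = 0.917 * params$rho0 + 0.15 * (params$T0 - g$T),
    cp_l = 4180 * (1 - 0.953 * g$phi_c * (1 - 0.588 * g$phi_c) +
                     1e-3 * (g$T - params$T0)),
    cp_s = params$cp0 + 8 * (g$T - params$T0),
    kT_l = 0.58 * (1 - 0.905 * g$phi_c * (1 - 0.588 * g$phi_c) +
                     2.6e-3 * (g$T - params$T0)),
    kT_s = params$kT0 + 0.013 * (params$T0 - g$T),
    eta_l = eta_l,
    D_l = params$D0 * g$T * params$eta0 / (params$T0 * eta_l),
    Teq = params$T0 - 55 * g$phi_c^2
  )
}
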