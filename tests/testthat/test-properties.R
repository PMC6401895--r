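p <- material_params()

test_that("interpolation polynomial pins the pure phases", {
  Pd <- interp_P(c(-1, 0, 1), deriv = TRUE)
  expect_equal(Pd$P, c(1, 0.5, 0))
  expect_equal(Pd$dP[c(1, 3)], c(0, 0))
  # second derivative also vanishes at the wells (finite-difference probe)
  h <- 1e-4
  d2 <- (interp_P(1) - 2 * interp_P(1 - h) + interp_P(1 - 2 * h)) / h^2
  expect_lt(abs(d2), 1e-2)
  expect_error(interp_P(c(0, NaN)), "non-finite")
  # overshoots are clamped onto the wells, where P' = 0: the driving force
  # stays switched off in the bulk
  expect_equal(interp_P(1.2), 0)
  expect_equal(interp_P(c(1.01, -1.3), deriv = TRUE)$dP, c(0, 0))
})

test_that("double well vanishes at pure states and is symmetric", {
  g <- doublewell_G(c(0, 0.5, 1))
  expect_equal(g$G, c(0, 0.25, 0))
  expect_equal(g$dG[2], 0)
  expect_true(all(doublewell_G(seq(0, 1, 0.05))$G >= 0))
})

test_that("Flory parameter interpolates between liquid and solid values", {
  cm <- chi_mix(c(-1, 0, 1), p)
  expect_equal(cm$chi, c(0.5, 1.5, 2.5))
  expect_equal(cm$dchi[c(1, 3)], c(0, 0))
})

test_that("analytic derivatives match central differences", {
  set.seed(42)
  h <- 1e-5
  x <- runif(50, -1, 1)
  Pd <- interp_P(x, deriv = TRUE)
  expect_equal(Pd$dP, (interp_P(x + h) - interp_P(x - h)) / (2 * h),
               tolerance = 1e-6)
  pc <- runif(50, 0.02, 0.98)
  g <- doublewell_G(pc)
  gp <- doublewell_G(pc + h); gm <- doublewell_G(pc - h)
  expect_equal(g$dG, (gp$G - gm$G) / (2 * h), tolerance = 1e-6)
  expect_equal(g$d2G, (gp$G - 2 * g$G + gm$G) / h^2, tolerance = 1e-4)
  cm <- chi_mix(x, p)
  expect_equal(cm$dchi,
               (chi_mix(x + h, p)$chi - chi_mix(x - h, p)$chi) / (2 * h),
               tolerance = 1e-6)
})

test_that("density reproduces reference states and the ice branch", {
  expect_equal(density_scaled(p$T0, -1, 0, p), 1)
  expect_equal(density_scaled(p$T0, 1, 0, p), 0.917)
  # direct evaluation of the ice correlation at T0 - 10 K
  expect_equal(density_scaled(p$T0 - 10, 1, 0, p),
               (0.917 * 999.8 + 1.5) / 999.8, tolerance = 1e-12)
  expect_warning(density_scaled(200, -1, 0, p), "correlation range")
  expect_silent(density_scaled(200, -1, 0, p, warn = FALSE))
})

test_that("specific heat and conductivity hit their anchors", {
  expect_equal(specific_heat_scaled(p$T0, 1, 0, p), 1)
  expect_equal(specific_heat_scaled(p$T0, -1, 0, p), 4180 / 2110)
  expect_equal(specific_heat_scaled(p$T0 - 10, 1, 0, p), 2030 / 2110)
  expect_equal(thermal_conductivity_scaled(p$T0, 1, 0, p), 1)
  expect_equal(thermal_conductivity_scaled(p$T0, -1, 0, p), 0.58 / 2.14)
  expect_equal(thermal_conductivity_scaled(p$T0 - 10, 1, 0, p), 2.27 / 2.14)
})

test_that("VTF viscosity anchors and monotonicity", {
  expect_equal(viscosity_liquid(p$T0, 0, p), 1.8e-3, tolerance = 0.01)
  # prefactor is the viscosity in the VTF singular limit
  expect_equal(viscosity_liquid(1e6, 0, p, warn = FALSE), 4.442e-5,
               tolerance = 1e-3)
  Ts <- seq(240, 273, by = 1)
  expect_true(all(diff(viscosity_liquid(Ts, 0, p, warn = FALSE)) < 0))
  pcs <- seq(0, 0.6, by = 0.05)
  expect_true(all(diff(viscosity_liquid(p$T0, pcs, p)) > 0))
  expect_error(viscosity_liquid(160, 0, p), "VTF")
  # Mooney factor is 1 at zero concentration
  expect_equal(viscosity_liquid(p$T0, 0, p) * exp(6.3 * 0.2 / (1 - 0.17)),
               viscosity_liquid(p$T0, 0.2, p), tolerance = 1e-4)
})

test_that("diffusivity follows Stokes-Einstein and the crystal floor", {
  expect_equal(diffusivity_scaled(p$T0, -1, 0, p), 1, tolerance = 0.01)
  expect_equal(diffusivity_scaled(p$T0, 1, 0.3, p), 1e-4, tolerance = 1e-8)
  # direct evaluation at phi_c = 0.3 (Mooney suppression)
  d <- p$eta0 / viscosity_liquid(p$T0, 0.3, p)
  expect_equal(diffusivity_scaled(p$T0, -1, 0.3, p), d, tolerance = 1e-10)
  expect_equal(d, 0.0787, tolerance = 0.01)
})

test_that("liquidus depression follows the phase-diagram correlation", {
  lt <- liquidus_temperature(c(0, 0.05, 0.35), p)
  expect_equal(lt$Teq, c(273.15, 273.0125, 273.15 - 6.7375))
  expect_equal(lt$Teq_tilde[1], 0)
  expect_true(all(diff(liquidus_temperature(seq(0, 1, 0.1), p)$Teq) < 0))
  expect_error(liquidus_temperature(1.2, p), "0, 1")
})

test_that("interpolated properties equal pure branches at phi_sl = +/-1", {
  T <- 265
  for (f in list(density_scaled, specific_heat_scaled,
                 thermal_conductivity_scaled, viscosity_scaled,
                 diffusivity_scaled)) {
    mid <- f(T, 0, 0.1, p)
    expect_false(isTRUE(all.equal(mid, f(T, 1, 0.1, p))))
    # overshoot beyond +/-1 changes nothing (clamped onto the well)
    expect_equal(f(T, 1.01, 0.1, p), f(T, 1, 0.1, p))
  }
  expect_equal(viscosity_scaled(T, 1, 0, p), 1e4)
})

test_that("interfacial energy matches the tanh-profile closed form", {
  expect_equal(interfacial_energy(p),
               (2 * sqrt(2) / 3) * 999.8 * 0.1456 * 1e-6 * 273.15)
  p2 <- material_params(W_sl = 2e-6)
  expect_equal(interfacial_energy(p2), 2 * interfacial_energy(p))
})

test_that("material parameter validation enforces the physics constraints", {
  expect_error(material_params(chi_s = 0.4), "chi_s")
  expect_error(material_params(rho0 = -1), "positive")
  expect_error(material_params(eta_s_ratio = 10), "1e4")
  expect_error(material_params(bogus = 1), "unknown")
  expect_error(material_params(D_s_ratio = 2), "D_s_ratio")
})

test_that("property table is consistent with the scalar correlations", {
  tab <- property_table(T = c(260, 273.15), phi_c = c(0, 0.1), params = p)
  expect_equal(nrow(tab), 4)
  i <- which(tab$T == 273.15 & tab$phi_c == 0)
  expect_equal(tab$rho_l[i], p$rho0)
  expect_equal(tab$eta_l[i], viscosity_liquid(273.15, 0, p))
  expect_equal(tab$Teq[i], 273.15)
})
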