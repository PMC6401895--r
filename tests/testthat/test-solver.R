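p <- material_params()
p_nocool <- material_params(beta_f = 1e-12)
g <- spectral_grid(64)
n <- 64

# smooth random periodic fields for property-style checks
smooth2 <- function(seed, lo, hi, kmax = 4) {
  set.seed(seed)
  f <- matrix(0, n, n)
  X <- spectral_grid(n)$X; Y <- spectral_grid(n)$Y
  for (i in 1:3)
    f <- f + rnorm(1) * cos(sample(0:kmax, 1) * X + sample(0:kmax, 1) * Y +
                              runif(1, 0, 2 * pi))
  lo + (hi - lo) * (f - min(f)) / (max(f) - min(f))
}

test_that("uniform pure phases at equilibrium are exact fixed points", {
  ctx <- model_context(p_nocool, flow = FALSE)
  for (phi0 in c(-1, 1)) {
    st <- init_fields(g, seed_spec(0), 0, 0, p_nocool)
    st$phi_sl[] <- phi0
    pr <- eval_props(st, ctx)
    expect_equal(max(abs(rhs_phase(st, pr, ctx)$expl)), 0)
    expect_equal(max(abs(rhs_solute(st, pr, ctx)$expl)), 0, tolerance = 1e-12)
    z <- matrix(0, n, n)
    expect_lt(max(abs(rhs_thermal(st, pr, ctx, z, z)$expl)), 1e-10)
    r <- advance(st, 100, 2e-4, ctx)
    expect_equal(r$state$phi_sl, st$phi_sl, tolerance = 1e-12)
    expect_equal(r$state$T_tilde, st$T_tilde, tolerance = 1e-9)
  }
})

test_that("uniform liquid under cooling loses heat at exactly Omega~", {
  ctx <- model_context(p, flow = FALSE)
  st <- init_fields(g, seed_spec(0), 0, -0.5, p)
  n_steps <- 100
  r <- advance(st, n_steps, 2e-4, ctx)
  expect_equal(unique(round(as.vector(r$state$T_tilde), 10)),
               -0.5 - ctx$Om * n_steps * 2e-4, tolerance = 1e-8)
  # phase field untouched: no spurious freezing without a seed
  expect_equal(r$state$phi_sl, st$phi_sl, tolerance = 1e-12)
})

test_that("solute RHS vanishes for uniform fields and degenerate mobility", {
  ctx <- model_context(p, flow = FALSE)
  st <- init_fields(g, seed_spec(0), 0.3, -1, p)
  pr <- eval_props(st, ctx)
  expect_equal(max(abs(rhs_solute(st, pr, ctx)$expl)), 0, tolerance = 1e-12)
  # phi_c = 0 and 1: mobility phi_c - phi_c^2 kills the gradient fluxes
  st2 <- init_fields(g, seeds_preset("base5"), 0, -1, p)
  st2$phi_c[] <- 0
  pr2 <- eval_props(st2, ctx)
  r2 <- rhs_solute(st2, pr2, ctx)
  expect_lt(max(abs(r2$expl)), 1e-6)
  st2$phi_c[] <- 1
  pr3 <- eval_props(st2, ctx)
  expect_lt(max(abs(rhs_solute(st2, pr3, ctx)$expl)), 1e-6)
})

test_that("solute RHS is conservative for arbitrary smooth fields", {
  ctx <- model_context(p, flow = FALSE)
  st <- init_fields(g, seed_spec(0), 0.05, -1, p)
  st$phi_sl <- smooth2(1, -1, 1)
  st$phi_c <- smooth2(2, 0.02, 0.4)
  st$T_tilde <- smooth2(3, -1.5, -0.2)
  r <- rhs_solute(st, eval_props(st, ctx), ctx)
  # divergence form: the domain integral (quadrature oracle) is zero
  expect_lt(abs(sum(r$expl) * g$dx^2), 1e-10)
})

test_that("mean solute is conserved to round-off in a no-flow run", {
  ctx <- model_context(p, flow = FALSE)
  st <- init_fields(g, seeds_preset("base5"), 0.05, -1, p)
  m0 <- mean(st$phi_c)
  r <- advance(st, 1000, 2e-4, ctx)
  expect_lt(abs(mean(r$state$phi_c) - m0), 1e-10)
})

test_that("supercooling drives freezing at the interface", {
  ctx <- model_context(p, flow = FALSE)
  st <- init_fields(g, seeds_preset("base5"), 0.05, -1, p)
  pr <- eval_props(st, ctx)
  r <- rhs_phase(st, pr, ctx)
  band <- abs(st$phi_sl) < 0.5
  # the thermodynamic drive dominates at mid-interface and is positive
  # (P' < 0 there and T~ < Teq~): the crystal grows
  expect_true(all(r$expl[band] > 0))
  expect_equal(r$implicit_coeff, ctx$Ch2)
})

test_that("freezing releases latent heat at the front", {
  ctx <- model_context(material_params(beta_f = 1e-12), flow = FALSE)
  st <- init_fields(g, seeds_preset("base5"), 0, -1, p_nocool)
  pr <- eval_props(st, ctx)
  Dphi <- rhs_phase(st, pr, ctx)$expl       # front advancing
  z <- matrix(0, n, n)
  rt <- rhs_thermal(st, pr, ctx, Dphi, z)
  band <- abs(st$phi_sl) < 0.9
  far_liquid <- st$phi_sl < -0.999
  expect_gt(max(rt$expl[band]), 0)
  expect_lt(max(abs(rt$expl[far_liquid])), 1e-6)
})

test_that("exothermic signature: domain-max temperature sits at the front", {
  ctx <- model_context(p, flow = FALSE)
  st <- init_fields(g, seeds_preset("base5"), 0.05, -1, p)
  r <- advance(st, 500, 2e-4, ctx)
  s <- r$state
  i <- which(s$T_tilde == max(s$T_tilde), arr.ind = TRUE)[1, ]
  # the hottest point lies on or adjacent to the interface band
  nb <- s$phi_sl[max(1, i[1] - 1):min(n, i[1] + 1),
                 max(1, i[2] - 1):min(n, i[2] + 1)]
  expect_true(any(abs(nb) < 0.9))
})

test_that("no forcing means no flow; blowing flux is radially outward", {
  ctx <- model_context(p, flow = TRUE, gravity = FALSE)
  st <- init_fields(g, seed_spec(0), 0, -1, p)
  pr <- eval_props(st, ctx)
  vel <- update_velocity(st, pr, ctx, matrix(0, n, n))
  expect_equal(max(abs(vel$vx)), 0, tolerance = 1e-12)
  expect_equal(max(abs(vel$vy)), 0, tolerance = 1e-12)
  # one growing crystal, gravity off: velocity points away from the seed
  st2 <- init_fields(g, seed_spec(1, matrix(c(pi, pi), 1)), 0.05, -1, p)
  r2 <- advance(st2, 200, 2e-4, ctx)
  s2 <- r2$state
  # ring in the liquid, clear of the (grown) crystal
  r_eff <- sqrt(mean(s2$phi_sl > 0) * 4 * pi)
  ring <- abs(sqrt((g$X - pi)^2 + (g$Y - pi)^2) - (r_eff + 0.4)) < 0.12
  vr <- ((g$X - pi) * s2$vx + (g$Y - pi) * s2$vy)[ring]
  expect_gt(mean(vr > 0), 0.95)
  # divergence of the returned velocity matches the continuity source
  pr2 <- eval_props(s2, ctx)
  Dphi <- s2$ddt_phi + ctx$Pe * (s2$vx * pr2$gphi$x + s2$vy * pr2$gphi$y)
  vel2 <- update_velocity(s2, pr2, ctx, Dphi)
  dv <- div_spec(vel2$vx, vel2$vy, g)
  expect_lt(max(abs(dv - vel2$div_target)), 1e-8)
  expect_gt(max(vel2$div_target), 0)   # blowing (positive) at freezing fronts
})

test_that("time stepping is deterministic", {
  ctx <- model_context(p)
  st <- init_fields(g, seeds_preset("base5"), 0.05, -1, p)
  r1 <- advance(st, 50, 2e-4, ctx)
  r2 <- advance(st, 50, 2e-4, ctx)
  expect_identical(r1$state$phi_sl, r2$state$phi_sl)
  expect_identical(r1$state$vx, r2$state$vx)
})

test_that("corrupted or inadmissible states abort instead of propagating", {
  ctx <- model_context(p, flow = FALSE)
  st <- init_fields(g, seed_spec(0), 0.05, -1, p)
  st$T_tilde[1, 1] <- NaN     # corrupted temperature field
  expect_error(advance(st, 30, 2e-4, ctx), "non-finite")
  # an out-of-range solute spike is clamped by the limiter, conserving mean
  st2 <- init_fields(g, seed_spec(0), 0.05, -1, p)
  st2$phi_c[1, 1] <- 5
  m0 <- mean(st2$phi_c)
  r2 <- advance(st2, 10, 2e-4, ctx)
  expect_lt(max(r2$state$phi_c), 1.1)
  expect_equal(mean(r2$state$phi_c), m0, tolerance = 1e-10)
})

test_that("spectral and finite-difference RHS agree on smooth fields", {
  ctx <- model_context(p, flow = FALSE)
  errs <- sapply(c(32, 64), function(nn) {
    gg <- spectral_grid(nn)
    st <- init_fields(gg, seed_spec(0), 0.05, -1, p)
    st$phi_sl <- 0.9 * cos(2 * gg$X + gg$Y)
    st$phi_c <- 0.1 + 0.05 * sin(gg$X) * cos(2 * gg$Y)
    st$T_tilde <- -1 + 0.3 * sin(gg$X + gg$Y)
    max(abs(fd_rhs_phase(st, ctx) - spectral_rhs_phase(st, ctx)))
  })
  # second-order convergence of the FD route towards the spectral one
  expect_gt(errs[1] / errs[2], 3)
})
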