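g <- spectral_grid(64)

# random smooth band-limited real field, reproducible
smooth_field <- function(grid, kmax = 5, seed = 1) {
  set.seed(seed)
  f <- matrix(0, grid$n, grid$n)
  for (i in 1:4) {
    kx <- sample(0:kmax, 1); ky <- sample(0:kmax, 1)
    f <- f + rnorm(1) * cos(kx * grid$X + ky * grid$Y + runif(1, 0, 2 * pi))
  }
  f
}

test_that("first derivatives are spectrally exact on resolved modes", {
  f <- sin(3 * g$X)
  d <- grad_spec(f, g)
  expect_equal(d$x, 3 * cos(3 * g$X), tolerance = 1e-10)
  expect_equal(max(abs(d$y)), 0, tolerance = 1e-10)
  fy <- sin(2 * g$Y)
  expect_equal(grad_spec(fy, g)$y, 2 * cos(2 * g$Y), tolerance = 1e-10)
})

test_that("Laplacian of a constant vanishes and operators are linear", {
  expect_equal(max(abs(laplacian_spec(matrix(2.5, 64, 64), g))), 0,
               tolerance = 1e-12)
  f1 <- smooth_field(g, seed = 1); f2 <- smooth_field(g, seed = 2)
  expect_equal(laplacian_spec(2 * f1 + 3 * f2, g),
               2 * laplacian_spec(f1, g) + 3 * laplacian_spec(f2, g),
               tolerance = 1e-10)
})

test_that("biharmonic equals the composed Laplacian", {
  f <- smooth_field(g, seed = 3)
  expect_equal(biharmonic_spec(f, g),
               laplacian_spec(laplacian_spec(f, g), g), tolerance = 1e-12)
})

test_that("derivatives of real fields are real with zero mean", {
  f <- smooth_field(g, seed = 4)
  d <- grad_spec(f, g)
  expect_true(is.numeric(d$x) && is.numeric(d$y))
  expect_equal(mean(d$x), 0, tolerance = 1e-12)
  expect_equal(mean(div_spec(d$x, d$y, g)), 0, tolerance = 1e-12)
})

test_that("2/3-rule dealiasing removes high modes and is idempotent", {
  Fc <- fft2(matrix(1.7, 64, 64))
  expect_equal(dealias_spec(Fc, g), Fc)           # constant untouched
  nyq <- cos(32 * g$X)                            # pure Nyquist mode
  expect_equal(max(abs(ifft2r(dealias_spec(fft2(nyq), g)))), 0,
               tolerance = 1e-10)
  F2 <- fft2(smooth_field(g, kmax = 30, seed = 5))
  expect_equal(dealias_spec(dealias_spec(F2, g), g), dealias_spec(F2, g))
  # self-product of a truncated high mode leaves no spurious low-k energy:
  # k > n/3 is removed before the product is formed, so nothing aliases down
  k <- 25                                          # 2k would alias onto k = 14
  u <- ifft2r(dealias_spec(fft2(sin(k * g$X)), g))
  prod_hat <- dealias_spec(fft2(u^2), g)
  expect_lt(max(Mod(prod_hat)) / 64^2, 1e-12)
  # without the input truncation the aliased mode would be O(1)
  raw <- fft2(sin(k * g$X)^2)
  expect_gt(max(Mod(raw[1, ])) / 64^2, 0.1)
})

test_that("Poisson solver round-trips and fixes the gauge", {
  u <- solve_poisson(-sin(g$X), g)
  expect_equal(u, sin(g$X), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(max(abs(solve_poisson(matrix(0, 64, 64), g))), 0)
  rhs <- smooth_field(g, seed = 6); rhs <- rhs - mean(rhs)
  sol <- solve_poisson(rhs, g)
  expect_equal(laplacian_spec(sol, g), rhs, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mean(sol), 0, tolerance = 1e-12)
  # non-zero-mean rhs: mean is subtracted and reported
  sol2 <- solve_poisson(rhs + 1, g)
  expect_equal(attr(sol2, "mean_removed"), 1, tolerance = 1e-10)
})

test_that("implicit diffusion step is the exact low-pass filter", {
  f <- smooth_field(g, seed = 7)
  expect_equal(implicit_diffusion_step(f, 3, 0, 2, g), f, tolerance = 1e-12)
  cst <- matrix(4.2, 64, 64)
  expect_equal(implicit_diffusion_step(cst, 10, 0.5, 4, g), cst,
               tolerance = 1e-12)
  mode <- sin(5 * g$X)
  out <- implicit_diffusion_step(mode, 2, 0.1, 2, g)
  expect_equal(out, mode / (1 + 0.1 * 2 * 25), tolerance = 1e-12)
  out4 <- implicit_diffusion_step(mode, 2, 0.1, 4, g)
  expect_equal(out4, mode / (1 + 0.1 * 2 * 25^2), tolerance = 1e-12)
  expect_error(implicit_diffusion_step(f, -1, 0.1, 2, g), "non-negative")
})

test_that("shape mismatches are rejected", {
  expect_error(grad_spec(matrix(0, 32, 32), g), "shape")
  expect_error(spectral_grid(33), "even")
  expect_error(spectral_grid(16), "32")
})
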