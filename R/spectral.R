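#' Periodic pseudo-spectral grid
#'
#' Collocation grid for the scaled periodic square domain \[0, 2*pi)^2 with
#' integer Fourier wavenumbers. Fields are stored as n x n matrices indexed
#' `[iy, ix]` (row = y, column = x; x rightward, y upward, gravity along -y).
#' First-derivative operators zero the Nyquist mode; nonlinear products are
#' dealiased by the 2/3 rule.
#'
#' @param n points per side; even, >= 32.
#' @return An object of class `spectral_grid`: `n`, `dx`, coordinate vectors
#'   `x`, `y`, coordinate matrices `X`, `Y`, wavenumber matrices `KX`, `KY`
#'   (Nyquist zeroed, for derivatives), `K2` (full, for Laplacians),
#'   `K2inv` (with the zero mode mapped to 0), and logical `dealias` mask.
#' @export
spectral_grid <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n < 32 || n %% 2 != 0)
    stop("n must be a single even integer >= 32")
  n <- as.integer(n)
  dx <- 2 * pi / n
  x <- seq(0, 2 * pi - dx, by = dx)
  # FFT ordering 0,1,...,n/2-1, -n/2, ..., -1; Nyquist zeroed for odd
  # derivatives (it carries no sign information)
  kfull <- c(0:(n / 2 - 1), -n / 2, -(n / 2 - 1):-1)
  kd <- kfull
  kd[n / 2 + 1] <- 0
  KXd <- matrix(kd, n, n, byrow = TRUE)   # varies along columns (x)
  KYd <- matrix(kd, n, n)                 # varies along rows (y)
  KXf <- matrix(kfull, n, n, byrow = TRUE)
  KYf <- matrix(kfull, n, n)
  K2 <- KXf^2 + KYf^2
  K2inv <- 1 / K2
  K2inv[1, 1] <- 0
  kcut <- n / 3
  dealias <- (abs(KXf) <= kcut) & (abs(KYf) <= kcut)
  g <- list(n = n, dx = dx, x = x, y = x,
            X = matrix(x, n, n, byrow = TRUE), Y = matrix(x, n, n),
            KX = KXd, KY = KYd, K2 = K2, K2inv = K2inv, dealias = dealias)
  class(g) <- "spectral_grid"
  g
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("Periodic spectral grid: %d x %d, domain [0, 2pi)^2, dx = %.4g\n",
              x$n, x$n, x$dx))
  invisible(x)
}

# 2-D transforms. Forward is unnormalized; inverse carries 1/n^2. Real part
# is taken on the way back (inputs are real fields).
fft2 <- function(f) stats::fft(f)
ifft2r <- function(F) Re(stats::fft(F, inverse = TRUE)) / length(F)

.check_field <- function(f, grid) {
  if (!is.matrix(f) || nrow(f) != grid$n || ncol(f) != grid$n)
    stop("field shape does not match grid")
}

#' Spectral differential operators
#'
#' Gradient, divergence, Laplacian and biharmonic of real periodic fields,
#' computed in Fourier space with spectral accuracy. Outputs are real
#' (conjugate symmetry is enforced by taking the real part of the inverse
#' transform).
#'
#' @param f real field matrix matching `grid`.
#' @param fx,fy components of a vector field.
#' @param grid a [spectral_grid()].
#' @return `grad_spec` returns `list(x, y)`; the others return a field.
#' @export
grad_spec <- function(f, grid) {
  .check_field(f, grid)
  F <- fft2(f)
  list(x = ifft2r(1i * grid$KX * F), y = ifft2r(1i * grid$KY * F))
}

#' @rdname grad_spec
#' @export
div_spec <- function(fx, fy, grid) {
  .check_field(fx, grid); .check_field(fy, grid)
  ifft2r(1i * grid$KX * fft2(fx) + 1i * grid$KY * fft2(fy))
}

#' @rdname grad_spec
#' @export
laplacian_spec <- function(f, grid) {
  .check_field(f, grid)
  ifft2r(-grid$K2 * fft2(f))
}

#' @rdname grad_spec
#' @export
biharmonic_spec <- function(f, grid) {
  .check_field(f, grid)
  ifft2r(grid$K2^2 * fft2(f))
}

#' Dealias a spectrum by the 2/3 rule
#'
#' Zeroes all modes with |kx| or |ky| beyond n/3. Applied to the transforms
#' of nonlinear products before they enter the time update; idempotent.
#'
#' @param F complex spectrum matrix.
#' @param grid a [spectral_grid()].
#' @return Filtered spectrum.
#' @export
dealias_spec <- function(F, grid) {
  .check_field(F, grid)
  F * grid$dealias
}

#' Solve the periodic Poisson equation
#'
#' Returns the zero-mean field `u` with `laplacian(u) = rhs - mean(rhs)`.
#' A non-zero mean right-hand side is incompatible with periodicity; it is
#' subtracted (and reported via `attr(, "mean_removed")`).
#'
#' @param rhs right-hand-side field.
#' @param grid a [spectral_grid()].
#' @return Solution field, zero mean.
#' @export
solve_poisson <- function(rhs, grid) {
  .check_field(rhs, grid)
  F <- fft2(rhs)
  m <- Re(F[1, 1]) / grid$n^2
  out <- ifft2r(-F * grid$K2inv)
  attr(out, "mean_removed") <- m
  out
}

#' Semi-implicit constant-coefficient diffusion step
#'
#' Applies the unconditionally stable filter `(1 + dt*coeff*k^2)^-1`
#' (order 2) or `(1 + dt*coeff*k^4)^-1` (order 4) to a field: one backward
#' Euler step of `u_t = -coeff * (-lap)^(order/2) u`. Constant fields pass
#' through unchanged (k = 0 mode), so the step preserves the domain mean.
#'
#' @param f real field.
#' @param coeff non-negative diffusion coefficient (scaled units).
#' @param dt time step (scaled units).
#' @param order 2 (Laplacian) or 4 (biharmonic).
#' @param grid a [spectral_grid()].
#' @return Filtered field.
#' @export
implicit_diffusion_step <- function(f, coeff, dt, order = 2, grid) {
  .check_field(f, grid)
  if (!is.finite(coeff) || coeff < 0) stop("coeff must be non-negative")
  if (!order %in% c(2, 4)) stop("order must be 2 or 4")
  kpow <- if (order == 2) grid$K2 else grid$K2^2
  ifft2r(fft2(f) / (1 + dt * coeff * kpow))
}
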