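#' Seed specification for prescribed nucleation sites
#'
#' Nucleation is not modelled: crystals start from prescribed seed discs at a
#' supercooled temperature. Positions are given explicitly (reproducible), or
#' drawn uniformly with a minimum separation from a recorded RNG seed.
#'
#' @param count number of seeds (0 allowed: uniform liquid).
#' @param positions `count` x 2 matrix of scaled coordinates in \[0, 2*pi);
#'   if `NULL`, positions are drawn randomly.
#' @param radius seed radius in scaled units; default `3 * Ch = 0.3`, small
#'   against the domain but resolvable (must be at least `2 * Ch`).
#' @param min_separation minimum centre-to-centre distance (periodic metric).
#' @param rng_seed integer seed used when drawing random positions.
#' @param Ch Cahn-Hilliard number (interface thickness / length scale).
#' @return An object of class `seed_spec`.
#' @examples
#' seeds_preset("base5")    # the 5-seed quincunx scenario
#' @export
seed_spec <- function(count, positions = NULL, radius = 0.3,
                      min_separation = 2 * radius + 0.4, rng_seed = 1L,
                      Ch = 0.1) {
  count <- as.integer(count)
  stopifnot(count >= 0, radius > 0)
  if (radius < 2 * Ch)
    stop("seed radius must be at least 2*Ch for a resolvable interface")
  if (count > 0 && is.null(positions)) {
    set.seed(rng_seed)
    positions <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(positions) < count) {
      cand <- runif(2, 0, 2 * pi)
      ok <- nrow(positions) == 0 ||
        all(.periodic_dist(positions, cand) >= min_separation)
      if (ok) positions <- rbind(positions, cand)
      tries <- tries + 1
      if (tries > 10000 * count)
        stop("could not place ", count, " seeds with min_separation ",
             min_separation)
    }
  }
  if (count > 0) {
    positions <- matrix(as.numeric(positions), ncol = 2)
    if (nrow(positions) != count) stop("positions must be a count x 2 matrix")
    if (any(positions < 0) || any(positions >= 2 * pi))
      stop("seed positions must lie in [0, 2*pi)")
    if (count > 1) {
      for (i in seq_len(count - 1)) {
        d <- .periodic_dist(positions[(i + 1):count, , drop = FALSE],
                            positions[i, ])
        if (any(d < min_separation))
          stop("seeds closer than min_separation (overlapping nuclei)")
      }
    }
  }
  structure(list(count = count, positions = positions, radius = radius,
                 min_separation = min_separation, rng_seed = rng_seed),
            class = "seed_spec")
}

# minimum-image distance from rows of `mat` to point `pt` on [0, 2*pi)^2
.periodic_dist <- function(mat, pt) {
  d <- abs(sweep(mat, 2, pt))
  d <- pmin(d, 2 * pi - d)
  sqrt(rowSums(d^2))
}

#' Preset seed layouts for the reference scenarios
#'
#' `"base5"`: five seeds in a quincunx (four at the quarter points, one at
#' the centre) — the base freeze-concentration scenario. `"dense25"`:
#' twenty-five seeds with higher density on the left half of the domain
#' (a 3x5 block on the left, 2x5 on the right), the uneven-seeding scenario.
#'
#' @param name `"base5"` or `"dense25"`.
#' @param radius seed radius, scaled units.
#' @return A [seed_spec()].
#' @export
seeds_preset <- function(name = c("base5", "dense25"), radius = 0.3) {
  name <- match.arg(name)
  if (name == "base5") {
    q <- pi / 2
    pos <- rbind(c(q, q), c(3 * q, q), c(q, 3 * q), c(3 * q, 3 * q),
                 c(pi, pi))
    return(seed_spec(5, pos, radius = radius))
  }
  # 15 seeds on the left half (3 columns x 5 rows), 10 on the right (2 x 5)
  yl <- (seq_len(5) - 0.5) * 2 * pi / 5
  xl <- (seq_len(3) - 0.5) * pi / 3
  xr <- pi + (seq_len(2) - 0.5) * pi / 2
  left <- as.matrix(expand.grid(x = xl, y = yl))
  right <- as.matrix(expand.grid(x = xr, y = yl + 0.2))
  pos <- rbind(left, right)
  seed_spec(25, pos, radius = radius, min_separation = 2 * radius + 0.2)
}

#' Initialize the coupled field state
#'
#' Builds the initial condition of a run: tanh-profile crystal discs
#' (`phi_sl = +1` inside, `-1` outside, interface width `sqrt(2)*Ch`),
#' solute at the bulk value `phi_c0` in the liquid and 0 inside the seeds,
#' a uniform supercooled temperature, and fluid at rest.
#'
#' @param grid a [spectral_grid()].
#' @param seeds a [seed_spec()].
#' @param phi_c0 initial bulk solute volume fraction.
#' @param T_tilde0 initial scaled temperature `(T - T0)/dT` (e.g. -1 for
#'   10 K of supercooling).
#' @param params a [material_params()] object (sets `Ch = W_sl/L`).
#' @return An object of class `field_state` with matrices `phi_sl`, `phi_c`,
#'   `T_tilde`, `vx`, `vy`, `p_tilde` and scalar `t_tilde`.
#' @export
init_fields <- function(grid, seeds, phi_c0, T_tilde0,
                        params = material_params()) {
  stopifnot(inherits(grid, "spectral_grid"), inherits(seeds, "seed_spec"))
  if (phi_c0 < 0 || phi_c0 > 1) stop("phi_c0 must lie in [0, 1]")
  Ch <- params$W_sl / params$L
  delta <- sqrt(2) * Ch
  n <- grid$n
  phi <- matrix(-1, n, n)
  if (seeds$count > 0) {
    for (i in seq_len(seeds$count)) {
      dxm <- abs(grid$X - seeds$positions[i, 1])
      dym <- abs(grid$Y - seeds$positions[i, 2])
      dxm <- pmin(dxm, 2 * pi - dxm)
      dym <- pmin(dym, 2 * pi - dym)
      d <- sqrt(dxm^2 + dym^2)
      phi <- phi + (tanh((seeds$radius - d) / delta) + 1)
    }
    phi <- pmin(pmax(phi, -1), 1)
  }
  st <- list(
    grid = grid,
    phi_sl = phi,
    phi_c = phi_c0 * (1 - phi) / 2,
    T_tilde = matrix(T_tilde0, n, n),
    vx = matrix(0, n, n), vy = matrix(0, n, n),
    vsx = matrix(0, n, n), vsy = matrix(0, n, n),
    p_tilde = matrix(0, n, n),
    ddt_phi = matrix(0, n, n),
    t_tilde = 0
  )
  class(st) <- "field_state"
  st
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf(
    "field_state: %d x %d grid, t~ = %.4g\n", x$grid$n, x$grid$n, x$t_tilde))
  cat(sprintf("  phi_sl in [%.3f, %.3f], max phi_c = %.4f, T~ in [%.3f, %.3f]\n",
              min(x$phi_sl), max(x$phi_sl), max(x$phi_c),
              min(x$T_tilde), max(x$T_tilde)))
  invisible(x)
}

#' Scalar diagnostics of a field state
#'
#' Summarizes a state into the observables tracked over a run: domain-max
#' solute volume fraction, temperature extremes and mean, crystal area
#' fraction (area with `phi_sl > 0`), total solute (grid quadrature of
#' `phi_c`), maximum flow speed and maximum vorticity magnitude (spectral
#' curl).
#'
#' @param state a [init_fields()] state.
#' @return A one-row data.frame.
#' @export
compute_diagnostics <- function(state) {
  g <- state$grid
  speed <- sqrt(state$vx^2 + state$vy^2)
  vort <- if (max(speed) > 0) {
    ifft2r(1i * g$KX * fft2(state$vy) - 1i * g$KY * fft2(state$vx))
  } else matrix(0, g$n, g$n)
  data.frame(
    t_tilde = state$t_tilde,
    max_phi_c = max(state$phi_c),
    min_T_tilde = min(state$T_tilde),
    max_T_tilde = max(state$T_tilde),
    mean_T_tilde = mean(state$T_tilde),
    crystal_area_fraction = mean(state$phi_sl > 0),
    total_solute = sum(state$phi_c) * g$dx^2,
    mean_phi_c = mean(state$phi_c),
    max_speed = max(speed),
    max_vorticity = max(abs(vort)),
    mean_vy_crystal = if (any(state$phi_sl > 0))
      mean(state$vy[state$phi_sl > 0]) else 0
  )
}
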