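# Synthetic field generators: stream-function flows, planted director
# dynamics, defect configurations, band-limited random probe fields, noise.
# These define the validation conditions for the discovery pipeline; every
# generator is deterministic given its seed.

#' Default fixture grid
#'
#' 64 x 64 x 64 periodic box of side 2*pi in space; the time step is chosen
#' so that an order-one flow satisfies max|u| dt / dx of about 0.2 (stable,
#' accurate advection for the director integrator).
#'
#' @param n points per axis (default 64).
#' @param umax characteristic peak speed used to set dt (default 1).
#' @return a [field_grid()].
#' @export
default_fixture_grid <- function(n = 64L, umax = 1) {
  dx <- 2 * pi / n
  field_grid(n, n, n, dx, dx, 0.2 * dx / umax)
}

poly_eval <- function(coef, x) {
  # coef[k] multiplies x^(k-1)
  out <- array(0, dim(x) %||% length(x))
  for (k in seq_along(coef)) out <- out + coef[k] * x^(k - 1)
  out
}

poly_deriv <- function(coef) {
  if (length(coef) <= 1L) return(0)
  coef[-1L] * seq_len(length(coef) - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extensional stream-function flow with uniform director
#'
#' Velocity from the stream function `psi(x, y) = E x y + f(x) + g(y)`:
#' `u = (E x + g'(y), -E y - f'(x))`, exactly divergence-free by
#' construction.  The director is uniform along x, so the traceless nematic
#' tensor is `diag(1/2, -1/2)` and the extension rate along the director is
#' the constant `E`.  `f` and `g` model an arbitrary mean flow; cubic or
#' higher polynomials give the flow nonzero vorticity.
#'
#' @param grid a [field_grid()]; coordinates are centered on the domain.
#' @param E extension rate.
#' @param f,g polynomial coefficients (constant first) of the mean-flow
#'   profiles f(x), g(y).
#' @param t_mod optional amplitude modulation `a(t)` applied to the
#'   mean-flow part only (function of time); keeps `d2 psi / dx dy = E`.
#' @return a [field_sequence()].
#' @export
extensional_flow <- function(grid, E, f = 0, g = 0, t_mod = NULL) {
  d <- grid_dims(grid)
  co <- grid_coords(grid)
  x <- co$x - mean(co$x)
  y <- co$y - mean(co$y)
  fp <- poly_deriv(f); gp <- poly_deriv(g)
  u <- array(0, c(d, 2L))
  gpy <- poly_eval(gp, y)   # g'(y), length ny
  fpx <- poly_eval(fp, x)   # f'(x), length nx
  for (k in seq_len(d[3])) {
    a <- if (is.null(t_mod)) 1 else t_mod(co$t[k])
    u[, , k, 1] <- outer(E * x, rep(1, d[2])) + outer(rep(a, d[1]), gpy)
    u[, , k, 2] <- outer(rep(1, d[1]), -E * y) - outer(a * fpx, rep(1, d[2]))
  }
  n <- array(0, c(d, 2L))
  n[, , , 1] <- 1
  field_sequence(grid, u, n)
}

#' Cellular (vortex-array) flow
#'
#' Periodic divergence-free test flow from the stream function
#' `psi = (a/k) sin(kx) sin(ky)`, i.e.
#' `u = (a sin(kx) cos(ky), -a cos(kx) sin(ky))` with peak speed `a`.
#' Exercises both the strain and the rotation couplings of the director
#' equation.  `t_mod(t)` optionally modulates the amplitude in time.
#'
#' @param amplitude peak speed `a`.
#' @param wavenumber integer number of cells per domain period.
#' @param grid a [field_grid()] whose spatial extent `nx * dx` is the period.
#' @param t_mod optional function of time multiplying the amplitude.
#' @return velocity array `(nx, ny, nt, 2)`.
#' @export
cellular_flow <- function(amplitude, wavenumber, grid, t_mod = NULL) {
  d <- grid_dims(grid)
  co <- grid_coords(grid)
  k <- 2 * pi * wavenumber / (d[1] * grid$dx)
  sx <- sin(k * co$x); cx <- cos(k * co$x)
  sy <- sin(k * co$y); cy <- cos(k * co$y)
  u <- array(0, c(d, 2L))
  for (kk in seq_len(d[3])) {
    a <- amplitude * (if (is.null(t_mod)) 1 else t_mod(co$t[kk]))
    u[, , kk, 1] <- a * outer(sx, cy)
    u[, , kk, 2] <- -a * outer(cx, sy)
  }
  u
}

#' Random band-limited stream-function flow
#'
#' A divergence-free flow with many active modes: the stream function is a
#' real random Fourier series over integer wavevectors `|m| <= cutoff` in
#' x, y and t with a decaying Gaussian spectrum, and the velocity is its
#' analytic curl, mode by mode.  Unlike a single-mode vortex lattice the
#' resulting data manifold is high-dimensional, so no accidental algebraic
#' near-relations among velocity monomials survive — the only planted
#' relation is incompressibility itself.
#'
#' @param grid a [field_grid()] (periodic box).
#' @param cutoff highest integer mode per axis.
#' @param seed RNG seed.
#' @param amp target RMS speed.
#' @return velocity array `(nx, ny, nt, 2)`.
#' @export
random_stream_flow <- function(grid, cutoff = 3L, seed = 1L, amp = 1) {
  d <- grid_dims(grid)
  Lx <- d[1] * grid$dx; Ly <- d[2] * grid$dy; Lt <- d[3] * grid$dt
  xi <- list((0:(d[1] - 1L)) / d[1], (0:(d[2] - 1L)) / d[2], (0:(d[3] - 1L)) / d[3])
  modes <- as.matrix(expand.grid(mx = -cutoff:cutoff, my = -cutoff:cutoff,
                                 mt = -cutoff:cutoff))
  modes <- modes[rowSums(modes[, 1:2]^2) > 0, , drop = FALSE]  # need spatial structure
  first_nonzero <- apply(modes, 1, function(m) m[which(m != 0)[1]])
  modes <- modes[first_nonzero > 0, , drop = FALSE]
  u <- array(0, c(d, 2L))
  with_seed(seed, {
    a <- exp(-rowSums(modes^2) / (2 * 1.5^2))
    ph <- stats::runif(nrow(modes), 0, 2 * pi)
    for (r in seq_len(nrow(modes))) {
      kx <- 2 * pi * modes[r, 1] / Lx
      ky <- 2 * pi * modes[r, 2] / Ly
      px <- 2 * pi * modes[r, 1] * xi[[1]]
      py <- 2 * pi * modes[r, 2] * xi[[2]]
      pt <- 2 * pi * modes[r, 3] * xi[[3]]
      sxy <- outer(px, py, `+`)
      for (k in seq_len(d[3])) {
        s <- sin(sxy + pt[k] + ph[r])
        # u = (d psi / dy, -d psi / dx) for psi = a cos(k . x + phase)
        u[, , k, 1] <- u[, , k, 1] + a[r] * ky * s
        u[, , k, 2] <- u[, , k, 2] - a[r] * kx * s
      }
    }
  })
  rms <- sqrt(mean(u^2))
  u * amp / rms
}

# Spectral spatial derivative of a 2D periodic slice (matrix nx x ny).
spec_d2 <- function(M, axis, L) {
  n <- dim(M)[axis]
  m <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1L):-1L)[1:n]
  if (n %% 2L == 0L) m[n / 2 + 1L] <- 0
  ik <- 2i * pi * m / L
  if (axis == 1L) Re(stats::mvfft(stats::mvfft(M) * ik, inverse = TRUE)) / n
  else t(Re(stats::mvfft(stats::mvfft(t(M)) * ik, inverse = TRUE)) / n)
}

#' Integrate planted director dynamics on a periodic domain
#'
#' Advances the director angle field theta(x, y, t) under
#' `dn/dt = -(c1 (u . grad) n + c2 Omega n + c3 Pperp Abar n)` with a
#' 4th-order Runge-Kutta stepper; in angle form the right-hand side is
#' `-theta_t = c1 u . grad(theta) - c2 Omega_xy + c3 (A12 cos 2theta - Abar11 sin 2theta)`.
#' Spatial derivatives (of theta and u) are spectral, so the output
#' satisfies the planted relation to stepper accuracy.  The velocity must be
#' periodic over the grid.
#'
#' @param u velocity array `(nx, ny, nt, 2)` (frames at the grid times).
#' @param theta0 initial director angle, matrix `(nx, ny)`.
#' @param coef planted coefficients `c(c1, c2, c3)`.
#' @param grid a [field_grid()].
#' @param substeps RK4 substeps per output frame (default 1).
#' @return a [field_sequence()] whose `n` is `(cos theta, sin theta)` and
#'   whose `u` is the input velocity.
#' @export
director_dynamics <- function(u, theta0, coef, grid, substeps = 1L) {
  d <- grid_dims(grid)
  stopifnot(identical(dim(u), c(d, 2L)))
  Lx <- d[1] * grid$dx; Ly <- d[2] * grid$dy
  umax <- max(sqrt(u[, , , 1]^2 + u[, , , 2]^2))
  dt_sub <- grid$dt / substeps
  if (umax * dt_sub / min(grid$dx, grid$dy) > 0.5) {
    stop("CFL violation: max|u| dt / dx > 0.5; increase substeps")
  }
  c1 <- coef[1]; c2 <- coef[2]; c3 <- coef[3]
  rate <- function(theta, ux, uy) {
    dux_x <- spec_d2(ux, 1, Lx); dux_y <- spec_d2(ux, 2, Ly)
    duy_x <- spec_d2(uy, 1, Lx); duy_y <- spec_d2(uy, 2, Ly)
    om12 <- (duy_x - dux_y) / 2                 # Omega_xy
    a12 <- (duy_x + dux_y) / 2
    a11d <- (dux_x - duy_y) / 2                 # Abar_11
    tx <- spec_d2(theta, 1, Lx); ty <- spec_d2(theta, 2, Ly)
    -(c1 * (ux * tx + uy * ty) - c2 * om12 +
        c3 * (a12 * cos(2 * theta) - a11d * sin(2 * theta)))
  }
  theta <- theta0
  th_out <- array(0, d)
  th_out[, , 1] <- theta
  for (k in 2:d[3]) {
    # velocity interpolated linearly between stored frames for substeps
    u0x <- u[, , k - 1L, 1]; u0y <- u[, , k - 1L, 2]
    u1x <- u[, , k, 1]; u1y <- u[, , k, 2]
    for (s in seq_len(substeps)) {
      f0 <- (s - 1) / substeps; f1 <- s / substeps; fm <- (f0 + f1) / 2
      uxa <- u0x * (1 - f0) + u1x * f0; uya <- u0y * (1 - f0) + u1y * f0
      uxm <- u0x * (1 - fm) + u1x * fm; uym <- u0y * (1 - fm) + u1y * fm
      uxb <- u0x * (1 - f1) + u1x * f1; uyb <- u0y * (1 - f1) + u1y * f1
      k1 <- rate(theta, uxa, uya)
      k2 <- rate(theta + dt_sub / 2 * k1, uxm, uym)
      k3 <- rate(theta + dt_sub / 2 * k2, uxm, uym)
      k4 <- rate(theta + dt_sub * k3, uxb, uyb)
      theta <- theta + dt_sub / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    th_out[, , k] <- theta
  }
  n <- array(0, c(d, 2L))
  n[, , , 1] <- cos(th_out)
  n[, , , 2] <- sin(th_out)
  field_sequence(grid, u, n)
}

#' Director field of an isolated half-integer topological defect
#'
#' Director angle `theta_n = m atan2(y - y0, x - x0) + theta0` for charge
#' `m` in {+1/2, -1/2}.  The nematic tensor is continuous away from the
#' core and the director gradient norm scales as `|m| / r`.
#'
#' @param charge defect charge, +1/2 or -1/2.
#' @param position core coordinates `c(x0, y0)`.
#' @param grid a [field_grid()].
#' @param theta0 global phase offset.
#' @return list with `n` (`(nx, ny, nt, 2)`, constant in t) and `valid`
#'   (logical array, FALSE at a grid point coinciding with the core).
#' @export
defect_director <- function(charge, position, grid, theta0 = 0) {
  if (!charge %in% c(0.5, -0.5)) stop("charge must be +1/2 or -1/2")
  d <- grid_dims(grid)
  co <- grid_coords(grid)
  X <- outer(co$x - position[1], rep(1, d[2]))
  Y <- outer(rep(1, d[1]), co$y - position[2])
  ang <- charge * atan2(Y, X) + theta0
  core <- (X == 0 & Y == 0)
  n <- array(0, c(d, 2L))
  valid <- array(TRUE, d)
  for (k in seq_len(d[3])) {
    n[, , k, 1] <- cos(ang)
    n[, , k, 2] <- sin(ang)
    valid[, , k] <- !core
  }
  list(n = n, valid = valid)
}

#' Band-limited random periodic fields
#'
#' Velocity components and the director angle are sampled as real random
#' Fourier series over integer wavevectors `|m_i| <= cutoff` in x, y and t
#' with a decaying Gaussian spectrum and uniform phases, so all derivatives
#' are spectrally exact on the grid.  The flow is generically compressible,
#' which is what makes these fields suitable probes: physical relations of
#' the nematic fail on them while identities survive.
#'
#' @param grid a [field_grid()].
#' @param cutoff highest integer mode per axis (must be below Nyquist).
#' @param seed RNG seed.
#' @param u_amp,theta_amp RMS-scale amplitudes of velocity and director
#'   angle.  The angle default is modest so that cos/sin of the angle stay
#'   effectively band limited on the grid.
#' @return a [field_sequence()].
#' @export
random_smooth_fields <- function(grid, cutoff = 3L, seed = 1L,
                                 u_amp = 1, theta_amp = 0.5) {
  d <- grid_dims(grid)
  if (cutoff >= min(d) / 2) stop("cutoff must be below the grid Nyquist mode")
  co <- grid_coords(grid)
  xi <- list((0:(d[1] - 1L)) / d[1], (0:(d[2] - 1L)) / d[2], (0:(d[3] - 1L)) / d[3])
  modes <- as.matrix(expand.grid(mx = -cutoff:cutoff, my = -cutoff:cutoff,
                                 mt = -cutoff:cutoff))
  keep <- rowSums(modes^2) > 0
  modes <- modes[keep, , drop = FALSE]
  # one representative per +-m pair (real field built from cosines)
  first_nonzero <- apply(modes, 1, function(m) m[which(m != 0)[1]])
  modes <- modes[first_nonzero > 0, , drop = FALSE]
  gen <- function(amp) {
    a <- amp * exp(-rowSums(modes^2) / (2 * 1.5^2))
    ph <- stats::runif(nrow(modes), 0, 2 * pi)
    f <- array(0, d)
    for (r in seq_len(nrow(modes))) {
      px <- 2 * pi * modes[r, 1] * xi[[1]]
      py <- 2 * pi * modes[r, 2] * xi[[2]]
      pt <- 2 * pi * modes[r, 3] * xi[[3]]
      # cos(px+py+pt+ph) expanded as separable products
      cxy <- outer(px, py, `+`)
      for (k in seq_len(d[3])) {
        f[, , k] <- f[, , k] + a[r] * cos(cxy + pt[k] + ph[r])
      }
    }
    f / stats::sd(f) * amp
  }
  with_seed(seed, {
    ux <- gen(u_amp); uy <- gen(u_amp); th <- gen(theta_amp)
    u <- array(0, c(d, 2L))
    u[, , , 1] <- ux; u[, , , 2] <- uy
    n <- array(0, c(d, 2L))
    n[, , , 1] <- cos(th); n[, , , 2] <- sin(th)
    field_sequence(grid, u, n)
  })
}

#' Add relative noise to a field sequence
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' `level * RMS(component)` to each velocity component and perturbs the
#' director angle by Gaussian noise of standard deviation `level` radians,
#' renormalizing to unit length.
#'
#' @param fields a [field_sequence()].
#' @param level relative noise level (>= 0).
#' @param seed RNG seed.
#' @return a noisy [field_sequence()].
#' @export
add_noise <- function(fields, level, seed = 1L) {
  if (level < 0) stop("noise level must be nonnegative")
  if (level == 0) return(fields)
  d <- grid_dims(fields$grid)
  with_seed(seed, {
    u <- fields$u
    for (cc in 1:2) {
      rms <- sqrt(mean(u[, , , cc]^2))
      u[, , , cc] <- u[, , , cc] + stats::rnorm(prod(d), 0, level * rms)
    }
    th <- atan2(fields$n[, , , 2], fields$n[, , , 1]) +
      array(stats::rnorm(prod(d), 0, level), d)
    n <- array(0, c(d, 2L))
    n[, , , 1] <- cos(th); n[, , , 2] <- sin(th)
    field_sequence(fields$grid, u, n, fields$phi)
  })
}

#' Standard validation fixtures with known ground truth
#'
#' Registered fixtures:
#' \describe{
#'   \item{incompressibility}{time-modulated cellular flow with a gently
#'     drifting smooth director; ground truth: `div u = 0`.}
#'   \item{director-dynamics}{steady cellular flow advecting and rotating
#'     the director under planted coefficients `(c1, c2, c3) = (1, -1, -1)`;
#'     ground truth: the director evolution equation.}
#'   \item{stress-balance}{extensional flow with extension rate `E` and a
#'     cubic mean flow (nonzero vorticity), uniform director; ground truth:
#'     `Qbar:Abar - E = 0` and its rank-2 form.}
#'   \item{defect-mask}{a +1/2 defect with an intensity hole at the core;
#'     ground truth: the mask excludes the core.}
#' }
#'
#' @param name fixture name.
#' @param noise relative noise level applied after generation (default 0).
#' @param seed RNG seed for noise (and any stochastic ingredient).
#' @param n grid points per axis (default 64).
#' @param E extension rate for the stress-balance fixture (default 0.56).
#' @return list with `fields` (a [field_sequence()]), `truth` (named list of
#'   planted facts), `grid`.
#' @export
make_fixture <- function(name, noise = 0, seed = 1L, n = 64L, E = 0.56) {
  registered <- c("incompressibility", "director-dynamics", "stress-balance",
                  "defect-mask")
  if (!name %in% registered) {
    stop("unknown fixture '", name, "'; registered fixtures: ",
         paste(registered, collapse = ", "))
  }
  out <- switch(
    name,
    "incompressibility" = {
      grid <- default_fixture_grid(n, umax = 2.1)
      Lt <- grid$nt * grid$dt
      # many-mode random stream flow: exactly divergence-free, but with a
      # data manifold rich enough that no accidental algebraic near-relation
      # among velocity monomials competes with the planted one (a one- or
      # two-mode vortex lattice is a Laplacian eigenfunction and plants
      # spurious near-exact relations)
      u <- random_stream_flow(grid, cutoff = 3L, seed = 1301L, amp = 1)
      co <- grid_coords(grid)
      kx <- 2 * pi / (grid$nx * grid$dx)
      thA <- 0.4 * outer(sin(kx * co$x), cos(kx * co$y)) + 0.2
      thB <- 0.3 * outer(cos(kx * co$x), sin(kx * co$y))
      nn <- array(0, c(grid_dims(grid), 2L))
      for (k in seq_len(grid$nt)) {
        th <- thA + sin(2 * pi * co$t[k] / Lt) * thB
        nn[, , k, 1] <- cos(th); nn[, , k, 2] <- sin(th)
      }
      fields <- field_sequence(grid, u, nn)
      list(fields = fields,
           truth = list(relation = "div u = 0"))
    },
    "director-dynamics" = {
      grid <- default_fixture_grid(n, umax = 1.5)
      u <- cellular_flow(1, 1, grid) + cellular_flow(0.45, 2, grid)
      co <- grid_coords(grid)
      kx <- 2 * pi / (grid$nx * grid$dx)
      theta0 <- 0.3 + 0.4 * outer(sin(kx * co$x), cos(kx * co$y)) +
        0.3 * outer(cos(2 * kx * co$x), sin(kx * co$y))
      coef <- c(1, -1, -1)
      fields <- director_dynamics(u, theta0, coef, grid, substeps = 2L)
      list(fields = fields,
           truth = list(coef = coef,
                        relation = "dn/dt + c1 (u.grad)n + c2 Omega n + c3 Pperp Abar n = 0"))
    },
    "stress-balance" = {
      dx <- 5 / (n - 1)  # nondimensional box of side 5, matching film data extents
      grid <- field_grid(n, n, n, dx, dx, 0.2 * dx / (1.4 + 0.5))
      Lt <- grid$nt * grid$dt
      fields <- extensional_flow(grid, E,
                                 f = c(0, 0, 0, 0.06), g = c(0, 0, 0, 0.06),
                                 t_mod = function(t) 1 + 0.2 * sin(2 * pi * t / Lt))
      list(fields = fields,
           truth = list(E = E, relation = "Qbar:Abar - E = 0"))
    },
    "defect-mask" = {
      grid <- default_fixture_grid(max(n, 32L), umax = 1)
      dd <- defect_director(0.5, c(pi, pi), grid)
      co <- grid_coords(grid)
      X <- outer(co$x - pi, rep(1, grid$ny))
      Y <- outer(rep(1, grid$nx), co$y - pi)
      r2 <- X^2 + Y^2
      r0 <- 6 * grid$dx
      phi <- array(rep(1 - exp(-r2 / (2 * r0^2)), grid$nt), grid_dims(grid))
      u <- array(0, c(grid_dims(grid), 2L))
      u[, , , 1] <- 0.1  # quiescent background flow
      fields <- field_sequence(grid, u, dd$n, phi)
      list(fields = fields,
           truth = list(core = c(pi, pi), core_radius = r0))
    })
  if (noise > 0) out$fields <- add_noise(out$fields, noise, seed)
  out$grid <- out$fields$grid
  out$name <- name
  out
}
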