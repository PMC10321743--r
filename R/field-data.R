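# Field containers and preprocessing: grids, field sequences, director
# calculus with nematic sign handling, nondimensionalization, masking,
# and structure-tensor director extraction.

#' Regular space-time grid descriptor
#'
#' @param nx,ny,nt grid point counts (each >= 5).
#' @param dx,dy,dt grid spacings (> 0).
#' @param origin coordinates of grid point (1,1,1); defaults to the origin.
#' @return object of class `field_grid`.
#' @export
field_grid <- function(nx, ny, nt, dx, dy, dt, origin = c(0, 0, 0)) {
  nx <- as.integer(nx); ny <- as.integer(ny); nt <- as.integer(nt)
  if (any(c(nx, ny, nt) < 5L)) stop("grid needs at least 5 points per axis")
  if (any(c(dx, dy, dt) <= 0)) stop("grid spacings must be positive")
  structure(list(nx = nx, ny = ny, nt = nt, dx = dx, dy = dy, dt = dt,
                 origin = as.numeric(origin)),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field_grid: %d x %d x %d, spacing (%.4g, %.4g, %.4g), extents (%.4g, %.4g, %.4g)\n",
              x$nx, x$ny, x$nt, x$dx, x$dy, x$dt,
              (x$nx - 1) * x$dx, (x$ny - 1) * x$dy, (x$nt - 1) * x$dt))
  invisible(x)
}

grid_dims <- function(grid) c(grid$nx, grid$ny, grid$nt)
grid_spacing <- function(grid) c(grid$dx, grid$dy, grid$dt)

#' Grid coordinate vectors
#' @param grid a [field_grid()].
#' @return list with numeric vectors `x`, `y`, `t`.
#' @export
grid_coords <- function(grid) {
  list(x = grid$origin[1] + (0:(grid$nx - 1L)) * grid$dx,
       y = grid$origin[2] + (0:(grid$ny - 1L)) * grid$dy,
       t = grid$origin[3] + (0:(grid$nt - 1L)) * grid$dt)
}

#' Gridded velocity / director / intensity sequence
#'
#' The raw material of discovery: velocity `u` and nematic director `n`
#' (unit length, physically sign-ambiguous) plus a scalar intensity or
#' packing-fraction proxy `phi` in `[0, 1]`, all on a regular (x, y, t)
#' grid.  The scalar order parameter is fixed at 1: away from defects the
#' filaments are essentially perfectly aligned, and near defects the data
#' are excluded by the mask rather than modeled through S.
#'
#' @param grid a [field_grid()].
#' @param u numeric array `(nx, ny, nt, 2)` of velocity components.
#' @param n numeric array `(nx, ny, nt, 2)` of director components,
#'   unit length at every point (tolerance 1e-6).
#' @param phi numeric array `(nx, ny, nt)` in `[0, 1]`; defaults to 1.
#' @return object of class `field_sequence`.
#' @export
field_sequence <- function(grid, u, n, phi = NULL) {
  d <- grid_dims(grid)
  if (!identical(dim(u), c(d, 2L))) stop("u must have dim (nx, ny, nt, 2)")
  if (!identical(dim(n), c(d, 2L))) stop("n must have dim (nx, ny, nt, 2)")
  if (is.null(phi)) phi <- array(1, d)
  if (!identical(dim(phi), d)) stop("phi must have dim (nx, ny, nt)")
  if (!all(is.finite(u))) stop("u must be finite everywhere")
  nn <- n[, , , 1]^2 + n[, , , 2]^2
  if (max(abs(nn - 1)) > 1e-6) stop("director must be unit length (|n| = 1)")
  if (min(phi) < -1e-12 || max(phi) > 1 + 1e-12) stop("phi must lie in [0, 1]")
  structure(list(grid = grid, u = u, n = n, phi = pmin(pmax(phi, 0), 1), S = 1),
            class = "field_sequence")
}

#' @export
print.field_sequence <- function(x, ...) {
  g <- x$grid
  cat(sprintf("field_sequence on %d x %d x %d grid\n", g$nx, g$ny, g$nt))
  cat(sprintf("  mean |u| = %.4g, phi in [%.3g, %.3g]\n",
              mean(sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2)),
              min(x$phi), max(x$phi)))
  invisible(x)
}

#' Renormalize a director array to unit length
#' @keywords internal
normalize_director <- function(n) {
  len <- sqrt(n[, , , 1]^2 + n[, , , 2]^2)
  n[, , , 1] <- n[, , , 1] / len
  n[, , , 2] <- n[, , , 2] / len
  n
}

sgn_pos <- function(x) ifelse(x < 0, -1, 1)  # ties broken toward +

# Index helpers working on arrays of any dimensionality (TRUE = take all).
slice_index <- function(A, axis, i) {
  nd <- length(dim(A))
  args <- rep(list(TRUE), nd)
  args[[axis]] <- i
  args
}

# Shift an array along an axis by k (edge values replicated; the
# callers overwrite boundary slices with one-sided formulas).
shift_arr <- function(A, axis, k) {
  d <- dim(A)
  idx <- pmin(pmax(seq_len(d[axis]) + k, 1L), d[axis])
  do.call(`[`, c(list(A), slice_index(A, axis, idx), list(drop = FALSE)))
}

set_slice <- function(A, axis, i, value) {
  do.call(`[<-`, c(list(A), slice_index(A, axis, i), list(value = value)))
}

get_slice <- function(A, axis, i) {
  do.call(`[`, c(list(A), slice_index(A, axis, i), list(drop = FALSE)))
}

#' Differentiate a sign-ambiguous director field
#'
#' Before differencing, each stencil neighbor is flipped so that its dot
#' product with the center director is nonnegative (ties broken toward +).
#' The result transforms like `n` under a pointwise sign flip, so any even
#' product of director factors built from it is gauge invariant.  Interior
#' points use the centered second-order stencil, boundaries the one-sided
#' second-order stencil.
#'
#' @param n director array `(nx, ny, nt, 2)`, unit length.
#' @param axis 1 = x, 2 = y, 3 = t.
#' @param h grid spacing along the axis.
#' @return array `(nx, ny, nt, 2)` holding the derivative of each component.
#' @export
director_diff <- function(n, axis, h) {
  d <- dim(n)
  if (length(d) != 4L || d[4] != 2L) stop("director_diff expects an (nx,ny,nt,2) array")
  if (!(axis %in% 1:3)) stop("axis out of range")
  nax <- d[axis]
  if (nax < 3L) stop("need at least 3 points along axis")
  dot_with <- function(a, b) a[, , , 1] * b[, , , 1] + a[, , , 2] * b[, , , 2]
  mul_sign <- function(a, s) { a[, , , 1] <- a[, , , 1] * s; a[, , , 2] <- a[, , , 2] * s; a }
  np1 <- apply(n, 4, shift_arr, axis = axis, k = 1L, simplify = FALSE)
  np1 <- array(unlist(np1), d)
  nm1 <- apply(n, 4, shift_arr, axis = axis, k = -1L, simplify = FALSE)
  nm1 <- array(unlist(nm1), d)
  sp <- sgn_pos(dot_with(np1, n))
  sm <- sgn_pos(dot_with(nm1, n))
  out <- (mul_sign(np1, sp) - mul_sign(nm1, sm)) / (2 * h)
  # one-sided second-order boundaries, neighbors aligned to the boundary point
  one_sided <- function(i0, i1, i2, sign) {
    n0 <- get_slice(n, axis, i0); n1 <- get_slice(n, axis, i1); n2 <- get_slice(n, axis, i2)
    s1 <- sgn_pos(n0[, , , 1] * n1[, , , 1] + n0[, , , 2] * n1[, , , 2])
    s2 <- sgn_pos(n0[, , , 1] * n2[, , , 1] + n0[, , , 2] * n2[, , , 2])
    v <- n0
    for (cc in 1:2) {
      v[, , , cc] <- sign * (-3 * n0[, , , cc] + 4 * s1 * n1[, , , cc] - s2 * n2[, , , cc]) / (2 * h)
    }
    v
  }
  out <- set_slice(out, axis, 1L, one_sided(1L, 2L, 3L, 1))
  out <- set_slice(out, axis, nax, one_sided(nax, nax - 1L, nax - 2L, -1))
  out
}

#' Sweep-align a sign-ambiguous director field
#'
#' Produces a representative of the nematic field with consistent signs by a
#' deterministic sweep: the t-column at (1,1) is aligned first, then each
#' y-column at x = 1, then each x-row.  The overall sign is fixed so the mean
#' director has a nonnegative x component (tie broken toward +y).  On
#' defect-free data the result is independent of the stored per-point signs;
#' near topological defects a branch cut is unavoidable, which is why
#' discovery masks defect cores.
#'
#' @param n director array `(nx, ny, nt, 2)`.
#' @return aligned array of the same shape.
#' @export
align_director <- function(n) {
  d <- dim(n)
  nx <- d[1]; ny <- d[2]; nt <- d[3]
  f <- array(1, d[1:3])
  consec_sign <- function(axis) {
    # sign of dot(n_k, n_{k+1}) along axis, dims reduced by 1 along axis
    n0 <- get_slice(n, axis, 1:(d[axis] - 1L))
    n1 <- get_slice(n, axis, 2:d[axis])
    sgn_pos(n0[, , , 1] * n1[, , , 1] + n0[, , , 2] * n1[, , , 2])
  }
  st <- consec_sign(3L); sy <- consec_sign(2L); sx <- consec_sign(1L)
  # seed line: t-column at (1,1)
  f[1, 1, ] <- cumprod(c(1, st[1, 1, ]))
  # y-columns at x = 1, seeded per t-slice
  fy <- apply(rbind(1, matrix(sy[1, , ], nrow = ny - 1L)), 2, cumprod)  # ny x nt
  f[1, , ] <- sweep(fy, 2, f[1, 1, ], `*`)
  # x-rows, seeded per (y, t)
  fx <- apply(rbind(1, matrix(sx, nrow = nx - 1L)), 2, cumprod)  # nx x (ny*nt)
  f <- array(sweep(fx, 2, as.vector(f[1, , ]), `*`), d[1:3])
  out <- n
  out[, , , 1] <- n[, , , 1] * f
  out[, , , 2] <- n[, , , 2] * f
  m <- c(sum(out[, , , 1]), sum(out[, , , 2]))
  tol <- 1e-9 * prod(d[1:3])
  if (m[1] < -tol || (abs(m[1]) <= tol && m[2] < 0)) {
    out <- -out
  }
  out
}

#' Kinematic tensors derived from a field sequence
#'
#' Computes, with the package's standard stencils, the traceless nematic
#' tensor `Qbar_ij = n_i n_j - delta_ij / 2`, the velocity gradient
#' `gradu[i, j] =` derivative along i of component j, its symmetric part `A`,
#' traceless symmetric part `Abar`, antisymmetric part `Omega`, the scalar
#' vorticity `omega = -2 Omega_xy`, the divergence, and the transverse
#' projector `Pperp_ij = delta_ij - n_i n_j`.
#'
#' @param fields a [field_sequence()].
#' @return object of class `derived_fields`: list of arrays; rank-2 fields
#'   have dim `(nx, ny, nt, 2, 2)`.
#' @export
derived_fields <- function(fields) {
  g <- fields$grid
  d <- grid_dims(g)
  h <- grid_spacing(g)
  gradu <- array(0, c(d, 2L, 2L))
  for (i in 1:2) for (j in 1:2) {
    gradu[, , , i, j] <- central_diff(fields$u[, , , j], i, h[i])
  }
  A <- gradu; Om <- gradu
  for (i in 1:2) for (j in 1:2) {
    A[, , , i, j] <- (gradu[, , , i, j] + gradu[, , , j, i]) / 2
    Om[, , , i, j] <- (gradu[, , , i, j] - gradu[, , , j, i]) / 2
  }
  div <- gradu[, , , 1, 1] + gradu[, , , 2, 2]
  Abar <- A
  Abar[, , , 1, 1] <- A[, , , 1, 1] - div / 2
  Abar[, , , 2, 2] <- A[, , , 2, 2] - div / 2
  omega <- -2 * Om[, , , 1, 2]
  n <- fields$n
  Qbar <- array(0, c(d, 2L, 2L))
  Qbar[, , , 1, 1] <- n[, , , 1]^2 - 0.5
  Qbar[, , , 2, 2] <- n[, , , 2]^2 - 0.5
  Qbar[, , , 1, 2] <- n[, , , 1] * n[, , , 2]
  Qbar[, , , 2, 1] <- Qbar[, , , 1, 2]
  Pperp <- -Qbar
  Pperp[, , , 1, 1] <- Pperp[, , , 1, 1] + 0.5
  Pperp[, , , 2, 2] <- Pperp[, , , 2, 2] + 0.5
  gradn <- array(0, c(d, 2L, 2L))  # gradn[i, j] = d_i n_j, sign-aligned
  for (i in 1:2) {
    di <- director_diff(n, i, h[i])
    gradn[, , , i, 1] <- di[, , , 1]
    gradn[, , , i, 2] <- di[, , , 2]
  }
  structure(list(Qbar = Qbar, gradu = gradu, A = A, Abar = Abar,
                 Omega = Om, omega = omega, div = div, Pperp = Pperp,
                 gradn = gradn),
            class = "derived_fields")
}

#' Pointwise norm of the director gradient
#' @param fields a [field_sequence()] (or a derived_fields object).
#' @return array `(nx, ny, nt)` of the Frobenius norm of the spatial
#'   director gradient.
#' @export
director_gradient_norm <- function(fields) {
  df <- if (inherits(fields, "derived_fields")) fields else derived_fields(fields)
  sqrt(df$gradn[, , , 1, 1]^2 + df$gradn[, , , 1, 2]^2 +
       df$gradn[, , , 2, 1]^2 + df$gradn[, , , 2, 2]^2)
}

#' Nondimensionalize a field sequence
#'
#' Chooses a characteristic length and time scale so that the (mask-weighted)
#' mean speed and mean absolute vorticity are both unity, and rescales the
#' grid spacings and velocity accordingly.  The director and phi are
#' dimensionless and unchanged.
#'
#' @param fields a [field_sequence()].
#' @param mask optional [build_mask()] result (or numeric weight array);
#'   weights the means.
#' @return list with elements `fields` (rescaled [field_sequence()]) and
#'   `scales` (list with `length` and `time`).
#' @export
nondimensionalize <- function(fields, mask = NULL) {
  g <- fields$grid
  w <- if (is.null(mask)) array(1, grid_dims(g)) else if (inherits(mask, "field_mask")) mask$psi else mask
  df <- derived_fields(fields)
  speed <- sqrt(fields$u[, , , 1]^2 + fields$u[, , , 2]^2)
  sw <- sum(w)
  if (sw <= 0) stop("mask excludes all data")
  mu <- sum(w * speed) / sw
  mo <- sum(w * abs(df$omega)) / sw
  if (mu == 0 || mo == 0) stop("degenerate field, cannot nondimensionalize")
  time_scale <- 1 / mo
  length_scale <- mu / mo
  g2 <- field_grid(g$nx, g$ny, g$nt,
                   g$dx / length_scale, g$dy / length_scale, g$dt / time_scale,
                   origin = g$origin / c(length_scale, length_scale, time_scale))
  u2 <- fields$u * time_scale / length_scale
  out <- field_sequence(g2, u2, fields$n, fields$phi)
  list(fields = out, scales = list(length = length_scale, time = time_scale))
}

#' Build a data-reliability mask
#'
#' The Boolean field `psi0` is 1 where the intensity proxy is at or above the
#' intensity threshold AND the director gradient norm is at or below the
#' gradient threshold (defect cores and dark regions drop out); `psi` is
#' `psi0` smoothed by repeated box passes and clipped to `[0, 1]`, so it
#' vanishes smoothly over excluded regions and approaches 1 far from them.
#'
#' @param phi intensity array `(nx, ny, nt)`.
#' @param n director array `(nx, ny, nt, 2)`.
#' @param grid a [field_grid()].
#' @param intensity_frac intensity threshold as a fraction of `max(phi)`
#'   (default 0.15).
#' @param gradient_mult director-gradient threshold as a multiple of the
#'   median gradient norm (default 2).
#' @param passes number of box-smoothing passes (default 10).
#' @param width box kernel width per axis (default 5).
#' @return object of class `field_mask` with fields `psi`, `psi0`,
#'   `thresholds`, `passes`.
#' @export
build_mask <- function(phi, n, grid, intensity_frac = 0.15,
                       gradient_mult = 2, passes = 10L, width = 5L) {
  if (intensity_frac <= 0 || gradient_mult <= 0) stop("thresholds must be positive")
  h <- grid_spacing(grid)
  gn <- array(0, dim(phi))
  for (i in 1:2) {
    di <- director_diff(n, i, h[i])
    gn <- gn + di[, , , 1]^2 + di[, , , 2]^2
  }
  gn <- sqrt(gn)
  thr_int <- intensity_frac * max(phi)
  # floor keeps rounding-level gradients of a uniform director inside
  thr_grad <- max(gradient_mult * stats::median(gn), 1e-8)
  psi0 <- (phi >= thr_int) & (gn <= thr_grad)
  psi <- box_smooth(array(as.numeric(psi0), dim(phi)), width = width, passes = passes)
  psi <- pmin(pmax(psi, 0), 1)
  structure(list(psi = psi, psi0 = psi0,
                 thresholds = c(intensity = thr_int, gradient = thr_grad),
                 passes = passes, width = width),
            class = "field_mask")
}

#' @export
print.field_mask <- function(x, ...) {
  cat(sprintf("field_mask: %.1f%% of points retained (psi0), thresholds int=%.3g grad=%.3g\n",
              100 * mean(x$psi0), x$thresholds["intensity"], x$thresholds["gradient"]))
  invisible(x)
}

#' Extract a director and intensity proxy from a grayscale image stack
#'
#' Structure-tensor orientation analysis: the director is the unit
#' eigenvector of the Gaussian-smoothed intensity structure tensor for its
#' smallest eigenvalue, i.e. the direction along which the intensity varies
#' least (the local filament orientation).  Points where the tensor is
#' nearly isotropic (eigenvalue gap below `gap_tol` relative to the trace)
#' are flagged invalid so the mask can exclude them.  `phi` is the blurred
#' intensity rescaled to `[0, 1]`.
#'
#' @param stack numeric array `(nx, ny, nt)` of grayscale intensities.
#' @param deriv_sigma Gaussian blur (pixels) applied before differentiation.
#' @param tensor_sigma Gaussian blur (pixels) applied to the tensor entries.
#' @param gap_tol relative eigenvalue-gap tolerance (default 1e-8).
#' @return list with `n` (`(nx, ny, nt, 2)`), `phi`, `valid` (logical array).
#' @export
extract_director <- function(stack, deriv_sigma = 1, tensor_sigma = 4,
                             gap_tol = 1e-8) {
  d <- dim(stack)
  if (length(d) != 3L) stop("extract_director expects an (nx, ny, nt) stack")
  I <- gauss_smooth(stack, deriv_sigma, axes = 1:2)
  gx <- central_diff(I, 1, 1)
  gy <- central_diff(I, 2, 1)
  J11 <- gauss_smooth(gx * gx, tensor_sigma, axes = 1:2)
  J22 <- gauss_smooth(gy * gy, tensor_sigma, axes = 1:2)
  J12 <- gauss_smooth(gx * gy, tensor_sigma, axes = 1:2)
  gap <- sqrt((J11 - J22)^2 + 4 * J12^2)
  tr <- J11 + J22
  valid <- gap > gap_tol * pmax(tr, .Machine$double.eps)
  # angle of the dominant (largest-variation) eigenvector, director is normal to it
  ang_max <- 0.5 * atan2(2 * J12, J11 - J22)
  ang <- ang_max + pi / 2
  n <- array(0, c(d, 2L))
  n[, , , 1] <- cos(ang)
  n[, , , 2] <- sin(ang)
  n[, , , 1][!valid] <- 1  # placeholder direction; flagged invalid
  n[, , , 2][!valid] <- 0
  phi <- gauss_smooth(stack, tensor_sigma, axes = 1:2)
  rng <- range(phi)
  phi <- if (diff(rng) > 0) (phi - rng[1]) / diff(rng) else array(0, d)
  list(n = n, phi = phi, valid = valid)
}

#' Read a grayscale TIFF stack into an (nx, ny, nt) array
#'
#' @param paths character vector of single- or multi-frame TIFF files.
#' @return numeric array `(nx, ny, nt)` with intensities in `[0, 1]`.
#' @export
read_image_stack <- function(paths) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF stacks requires the 'tiff' package")
  }
  frames <- list()
  for (p in paths) {
    img <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(img)) img <- list(img)
    frames <- c(frames, img)
  }
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]  # first channel of RGB(A)
    t(f)  # TIFF rows are y; internal layout is x-fastest
  })
  array(unlist(frames), c(dim(frames[[1]]), length(frames)))
}

#' Write a field sequence to long-format CSV
#'
#' Columns `t, x, y, ux, uy, nx, ny, phi`, one row per grid point, t slowest
#' and x fastest.  Intended for small fixtures; round-trips with
#' [read_field_csv()].
#'
#' @param fields a [field_sequence()].
#' @param path output file path.
#' @export
write_field_csv <- function(fields, path) {
  g <- fields$grid
  co <- grid_coords(g)
  df <- data.frame(
    t = rep(co$t, each = g$nx * g$ny),
    x = rep(co$x, times = g$ny * g$nt),
    y = rep(rep(co$y, each = g$nx), times = g$nt),
    ux = as.vector(fields$u[, , , 1]),
    uy = as.vector(fields$u[, , , 2]),
    nx = as.vector(fields$n[, , , 1]),
    ny = as.vector(fields$n[, , , 2]),
    phi = as.vector(fields$phi))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a field sequence from long-format CSV
#' @param path CSV written by [write_field_csv()] (columns
#'   `t, x, y, ux, uy, nx, ny, phi`).
#' @return a [field_sequence()].
#' @export
read_field_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "ux", "uy", "nx", "ny", "phi")
  if (!all(need %in% names(df))) stop("CSV must have columns ", paste(need, collapse = ", "))
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y)); ts <- sort(unique(df$t))
  spacing <- function(v) {
    dv <- diff(v)
    if (max(abs(dv - dv[1])) > 1e-8 * abs(dv[1])) stop("grid is not uniform")
    dv[1]
  }
  g <- field_grid(length(xs), length(ys), length(ts),
                  spacing(xs), spacing(ys), spacing(ts),
                  origin = c(xs[1], ys[1], ts[1]))
  o <- order(df$t, df$y, df$x)
  d <- grid_dims(g)
  u <- array(0, c(d, 2L)); n <- array(0, c(d, 2L))
  u[, , , 1] <- df$ux[o]; u[, , , 2] <- df$uy[o]
  n[, , , 1] <- df$nx[o]; n[, , , 2] <- df$ny[o]
  field_sequence(g, u, normalize_director(n), array(df$phi[o], d))
}
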