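# Low-level grid operators: finite differences, spectral differences,
# local least-squares (Savitzky-Golay) smoothing, box/Gaussian filters.
# All 3D arrays are laid out (nx, ny, nt): x fastest, t slowest.
# Axis codes: 1 = x, 2 = y, 3 = t.

#' Apply a linear operator along one axis of a 3D array
#'
#' Permutes the requested axis to the front, applies `f` to the resulting
#' `n x prod(rest)` matrix, and permutes back.  Every stencil in the package
#' (differences, smoothers, spectral derivatives) funnels through this.
#'
#' @param A numeric 3D array.
#' @param axis axis index (1 = x, 2 = y, 3 = t).
#' @param f function taking and returning a matrix with the axis as rows.
#' @return array with the same shape as `A`.
#' @keywords internal
apply_axis <- function(A, axis, f) {
  d <- dim(A)
  if (is.null(d)) stop("apply_axis expects an array")
  if (axis < 1L || axis > length(d)) stop("axis out of range")
  perm <- c(axis, setdiff(seq_along(d), axis))
  B <- aperm(A, perm)
  M <- matrix(B, nrow = d[axis])
  M2 <- f(M)
  out <- array(M2, dim(B))
  aperm(out, order(perm))
}

#' Second-order finite-difference matrix
#'
#' Centered three-point stencil at interior points, one-sided second-order
#' stencils at the two boundary points.  Exact for polynomials up to degree 2.
#'
#' @param n number of grid points (>= 3).
#' @param h grid spacing.
#' @return dense `n x n` matrix `D` with `D %*% f` the derivative of `f`.
#' @keywords internal
diff_matrix <- function(n, h) {
  if (n < 3L) stop("need at least 3 points along axis for differentiation")
  D <- matrix(0, n, n)
  for (i in 2:(n - 1L)) {
    D[i, i - 1L] <- -1 / (2 * h)
    D[i, i + 1L] <- 1 / (2 * h)
  }
  D[1L, 1:3] <- c(-3, 4, -1) / (2 * h)
  D[n, n - (2:0)] <- c(1, -4, 3) / (2 * h)
  D
}

#' Differentiate a field along an axis with second-order stencils
#'
#' @param A numeric 3D array (nx, ny, nt).
#' @param axis 1 = x, 2 = y, 3 = t.
#' @param h grid spacing along that axis.
#' @return array of the same shape holding the derivative.
#' @export
central_diff <- function(A, axis, h) {
  d <- dim(A)
  if (is.null(d) || length(d) != 3L) stop("central_diff expects a 3D array")
  if (!(axis %in% 1:3)) stop("axis out of range")
  D <- diff_matrix(d[axis], h)
  apply_axis(A, axis, function(M) D %*% M)
}

#' Spectral (FFT) derivative along an axis of a periodic field
#'
#' Exact to rounding for band-limited periodic data; used on synthetic probe
#' fields where machine-precision derivatives are needed (identity
#' classification, fingerprint deduplication).  `h` is the grid spacing, the
#' implied period is `n * h`.
#'
#' @inheritParams central_diff
#' @param order derivative order (1 or 2).
#' @export
spectral_diff <- function(A, axis, h, order = 1L) {
  d <- dim(A)
  if (is.null(d) || length(d) != 3L) stop("spectral_diff expects a 3D array")
  if (!(axis %in% 1:3)) stop("axis out of range")
  n <- d[axis]
  L <- n * h
  m <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1L):-1L)[1:n]
  if (n %% 2L == 0L && order %% 2L == 1L) m[n / 2 + 1L] <- 0  # drop Nyquist for odd orders
  ik <- (2i * pi * m / L)^order
  apply_axis(A, axis, function(M) {
    Re(stats::mvfft(stats::mvfft(M) * ik, inverse = TRUE)) / n
  })
}

#' Local polynomial (Savitzky-Golay) smoothing matrix
#'
#' Row `p` holds the weights of a least-squares polynomial fit of degree
#' `degree` over a `window`-point stencil, evaluated at point `p`.  Interior
#' windows are centered; near the boundary the window shifts to stay inside
#' the grid and the fit is evaluated at the (off-center) target point, so
#' polynomials up to `degree` are reproduced exactly everywhere.
#'
#' @param n number of grid points.
#' @param window odd stencil width.
#' @param degree polynomial degree (< window).
#' @keywords internal
savgol_matrix <- function(n, window, degree) {
  if (window %% 2L != 1L) stop("window must be odd")
  if (window < degree + 1L) stop("window must be at least degree + 1")
  if (window > n) stop("window larger than grid")
  half <- (window - 1L) %/% 2L
  W <- matrix(0, n, n)
  for (p in seq_len(n)) {
    lo <- max(1L, min(p - half, n - window + 1L))
    pos <- lo:(lo + window - 1L)
    X <- outer(pos - p, 0:degree, "^")
    # weights of the fitted value at offset 0: e1' (X'X)^-1 X'
    w <- solve(crossprod(X), t(X))[1L, ]
    W[p, pos] <- w
  }
  W
}

#' Moving least-squares smoothing of a scalar field
#'
#' Local polynomial least-squares smoothing over a spatiotemporal window,
#' implemented as sequential one-dimensional Savitzky-Golay filters along x,
#' y and t.  The separable pass structure reproduces multivariate polynomials
#' up to the fit degree exactly (each 1D pass is exact in its own variable
#' with the others held fixed), which is the property the downstream
#' second-order difference stencils rely on.
#'
#' @param A numeric 3D array (nx, ny, nt).
#' @param window odd window width per axis (default 5).
#' @param degree polynomial fit degree (default 2).
#' @param axes axes to smooth along (default all three).
#' @return smoothed array.
#' @export
mls_smooth <- function(A, window = 5L, degree = 2L, axes = 1:3) {
  d <- dim(A)
  if (is.null(d) || length(d) != 3L) stop("mls_smooth expects a 3D array")
  for (ax in axes) {
    if (window > d[ax]) stop("window larger than grid")
    W <- savgol_matrix(d[ax], window, degree)
    A <- apply_axis(A, ax, function(M) W %*% M)
  }
  A
}

#' Box-filter matrix with renormalized truncated edges
#' @keywords internal
box_matrix <- function(n, width = 5L) {
  half <- (width - 1L) %/% 2L
  W <- matrix(0, n, n)
  for (p in seq_len(n)) {
    pos <- max(1L, p - half):min(n, p + half)
    W[p, pos] <- 1 / length(pos)
  }
  W
}

#' Gaussian-filter matrix with renormalized truncated tails
#' @keywords internal
gauss_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  W <- matrix(0, n, n)
  for (p in seq_len(n)) {
    pos <- max(1L, p - half):min(n, p + half)
    k <- exp(-((pos - p)^2) / (2 * sigma^2))
    W[p, pos] <- k / sum(k)
  }
  W
}

#' Smooth a field with repeated box passes along each axis
#' @keywords internal
box_smooth <- function(A, width = 5L, passes = 1L, axes = 1:3) {
  for (i in seq_len(passes)) {
    for (ax in axes) {
      W <- box_matrix(dim(A)[ax], width)
      A <- apply_axis(A, ax, function(M) W %*% M)
    }
  }
  A
}

#' Gaussian blur along selected axes
#' @keywords internal
gauss_smooth <- function(A, sigma, axes = 1:2) {
  for (ax in axes) {
    W <- gauss_matrix(dim(A)[ax], sigma)
    A <- apply_axis(A, ax, function(M) W %*% M)
  }
  A
}

#' Trapezoidal quadrature weights for one axis
#' @keywords internal
trapz_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1L, n)] <- h / 2
  w
}

# Run an expression with a temporary RNG seed, restoring global state after.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
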