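# Weak formulation: weight functions on random spatiotemporal subdomains,
# integration by parts off noisy data onto smooth weights, trapezoidal
# quadrature, and assembly of the feature matrix G.

#' Default subdomain extents for a grid
#'
#' The reference extents are 54 x 54 x 65 points on a 128 x 128 x 1000
#' experimental mesh.  Each axis is capped at its reference extent and
#' otherwise takes the reference spatial fraction 54/128 of the axis, with
#' a floor of 9 points (enough for the envelope and the trapezoid rule to
#' resolve each other).  On the reference mesh this reproduces
#' 54 x 54 x 65; on a cubic fixture grid it gives a proportional cube, so
#' every axis contributes comparable noise averaging.
#'
#' @param grid a [field_grid()].
#' @return integer vector of extents (px, py, pt).
#' @export
default_subdomain_extents <- function(grid) {
  d <- grid_dims(grid)
  ref_ext <- c(54, 54, 65)
  ext <- pmin(d, ref_ext, pmax(9L, round(d * 54 / 128)))
  as.integer(ext)
}

#' Sample random subdomains
#'
#' Subdomain start corners are uniform over all admissible placements
#' (equivalently, centers are uniform over the admissible interior),
#' reproducibly from the seed.
#'
#' @param grid a [field_grid()].
#' @param count number of subdomains.
#' @param extents integer extents (px, py, pt); default
#'   [default_subdomain_extents()].
#' @param seed RNG seed.
#' @return list of subdomains, each `list(start, extent)` (1-based starts).
#' @export
sample_subdomains <- function(grid, count, extents = NULL, seed = 1L) {
  d <- grid_dims(grid)
  if (is.null(extents)) extents <- default_subdomain_extents(grid)
  extents <- as.integer(extents)
  if (any(extents > d)) stop("subdomain extents exceed grid")
  if (any(extents < 9L)) stop("subdomain extents must be at least 9 points")
  maxstart <- d - extents + 1L
  with_seed(seed, {
    lapply(seq_len(count), function(k) {
      list(start = vapply(maxstart, function(m) sample.int(m, 1L), integer(1)),
           extent = extents)
    })
  })
}

envelope_vals <- function(xi, tau) {
  e0 <- (1 - xi^2)^tau
  e1 <- -2 * tau * xi * (1 - xi^2)^(tau - 1)
  e2 <- -2 * tau * (1 - xi^2)^(tau - 1) + 4 * tau * (tau - 1) * xi^2 * (1 - xi^2)^(tau - 2)
  rbind(e0, e1, e2)
}

# value/derivative rows (orders 0..2, wrt the reference coordinate) of the
# envelope, optionally multiplied by a cosine modulation.
axis_weight_vals <- function(xi, tau, modulated, phase) {
  E <- envelope_vals(xi, tau)
  if (!modulated) return(E)
  M0 <- cos(pi * xi - phase)
  M1 <- -pi * sin(pi * xi - phase)
  M2 <- -pi^2 * M0
  rbind(E[1, ] * M0,
        E[2, ] * M0 + E[1, ] * M1,
        E[3, ] * M0 + 2 * E[2, ] * M1 + E[1, ] * M2)
}

outer3 <- function(a, b, c) {
  array(outer(outer(a, b), c), c(length(a), length(b), length(c)))
}

#' Construct a weight function on a subdomain
#'
#' The weight is the product of (i) the envelope `(1-x^2)^tau (1-y^2)^tau
#' (1-t^2)^tau` in subdomain reference coordinates, which vanishes together
#' with `tau - 1` derivatives on the boundary; (ii) an optional cosine
#' modulation `cos(pi x_m - theta)` along one axis; and (iii) the
#' reliability mask restricted to the subdomain, when supplied.  Envelope
#' and modulation derivatives are analytic; mask derivatives are formed with
#' the standard stencils and combined by the Leibniz rule.
#'
#' @param subdomain a subdomain from [sample_subdomains()].
#' @param grid a [field_grid()].
#' @param tau envelope power (default 4).
#' @param modulation 0 for none, or axis 1/2/3 to modulate.
#' @param phase modulation phase in `[0, 2pi)`.
#' @param mask optional mask array `(nx, ny, nt)` (full grid; the subdomain
#'   slice is taken internally).
#' @return object of class `weight_function` with `$array(alpha)` giving
#'   the derivative array for a multi-index `alpha = c(kx, ky, kt)`.
#' @export
make_weight <- function(subdomain, grid, tau = 4, modulation = 0L, phase = 0,
                        mask = NULL) {
  ext <- subdomain$extent
  start <- subdomain$start
  h <- grid_spacing(grid)
  vals <- list()
  for (ax in 1:3) {
    xi <- seq(-1, 1, length.out = ext[ax])
    V <- axis_weight_vals(xi, tau, modulated = (modulation == ax), phase = phase)
    s <- 2 / ((ext[ax] - 1) * h[ax])  # d(xi)/d(physical)
    V[2, ] <- V[2, ] * s
    V[3, ] <- V[3, ] * s^2
    vals[[ax]] <- V
  }
  msub <- NULL
  if (!is.null(mask)) {
    idx <- lapply(1:3, function(ax) start[ax]:(start[ax] + ext[ax] - 1L))
    msub <- mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(msub) <- ext
  }
  cache <- new.env(parent = emptyenv())
  sep_arr <- function(alpha) {
    outer3(vals[[1]][alpha[1] + 1L, ], vals[[2]][alpha[2] + 1L, ],
           vals[[3]][alpha[3] + 1L, ])
  }
  mask_deriv <- function(beta) {
    key <- paste0("m", paste(beta, collapse = ""))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    arr <- msub
    for (ax in 1:3) {
      for (q in seq_len(beta[ax])) arr <- central_diff(arr, ax, h[ax])
    }
    cache[[key]] <- arr
    arr
  }
  warr <- function(alpha) {
    key <- paste0("w", paste(alpha, collapse = ""))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    if (is.null(msub)) {
      out <- sep_arr(alpha)
    } else {
      out <- array(0, ext)
      for (bx in 0:alpha[1]) for (by in 0:alpha[2]) for (bt in 0:alpha[3]) {
        cf <- choose(alpha[1], bx) * choose(alpha[2], by) * choose(alpha[3], bt)
        out <- out + cf * sep_arr(c(bx, by, bt)) *
          mask_deriv(c(alpha[1] - bx, alpha[2] - by, alpha[3] - bt))
      }
    }
    cache[[key]] <- out
    out
  }
  Q <- quad_array(ext, h)
  wq <- function(alpha) {
    key <- paste0("q", paste(alpha, collapse = ""))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    out <- warr(alpha) * Q
    cache[[key]] <- out
    out
  }
  structure(list(array = warr, wq = wq, subdomain = subdomain, tau = tau,
                 modulation = modulation, phase = phase, has_mask = !is.null(msub)),
            class = "weight_function")
}

#' Integration-by-parts plan of a term
#'
#' Derivatives on a monomial consisting of a single field factor (delta /
#' epsilon symbols aside) are moved entirely onto the weight function, one
#' integration by parts per derivative with no boundary terms (the envelope
#' vanishes with `tau - 1` derivatives).  Derivatives locked inside
#' multi-factor products stay on the data.
#'
#' @param term a library term.
#' @param tau envelope power that will be used (for order checking).
#' @return list, one entry per monomial: `list(transfer, sign, order)`.
#' @export
transfer_derivatives <- function(term, tau = 4) {
  lapply(term$monomials, function(m) {
    fieldpos <- which(vapply(m$factors, function(f) f$sym %in% c("u", "n"), logical(1)))
    ord <- if (length(fieldpos) == 1L) factor_order(m$factors[[fieldpos]]) else 0L
    transfer <- length(fieldpos) == 1L && ord > 0L
    if (transfer && ord > tau - 1L) {
      stop("transfer order exceeds tau - 1; raise the envelope power")
    }
    list(transfer = transfer, sign = if (transfer) (-1)^ord else 1, order = ord)
  })
}

# Slice a field sequence to a subdomain (same grid spacings).
slice_fields <- function(fields, subdomain) {
  ext <- subdomain$extent; start <- subdomain$start
  idx <- lapply(1:3, function(ax) start[ax]:(start[ax] + ext[ax] - 1L))
  g <- fields$grid
  sub_grid <- field_grid(ext[1], ext[2], ext[3], g$dx, g$dy, g$dt,
                         origin = g$origin + (start - 1L) * grid_spacing(g))
  u <- fields$u[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  n <- fields$n[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  dim(u) <- c(ext, 2L); dim(n) <- c(ext, 2L)
  phi <- fields$phi[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(phi) <- ext
  field_sequence(sub_grid, u, n, phi)
}

quad_array <- function(ext, h) {
  outer3(trapz_weights(ext[1], h[1]), trapz_weights(ext[2], h[2]),
         trapz_weights(ext[3], h[3]))
}

# Weak integral of one monomial for one tensor-component assignment.
integrate_monomial <- function(ctx, mono, plan, free_assign, weight) {
  total <- 0
  for (ba in bound_assignments(mono_bound_labels(mono))) {
    asg <- c(free_assign, ba)
    pref <- symbols_prefactor(mono, asg)
    if (pref == 0) next
    if (plan$transfer) {
      fieldpos <- which(vapply(mono$factors, function(f) f$sym %in% c("u", "n"), logical(1)))
      f <- mono$factors[[fieldpos]]
      axes <- c(if (length(f$derivs)) unname(asg[f$derivs]) else integer(0), rep(3L, f$dt))
      alpha <- tabulate(axes, nbins = 3L)
      base <- if (f$sym == "u") ctx$u[, , , asg[[f$comps]]] else ctx$n[, , , asg[[f$comps]]]
      total <- total + plan$sign * pref * sum(base * weight$wq(alpha))
    } else {
      arr <- mono_product_array(ctx, mono, asg)
      if (is.null(arr)) arr <- array(1, ctx$dims)
      total <- total + pref * sum(arr * weight$wq(c(0L, 0L, 0L)))
    }
  }
  total
}

#' Weak-form integral of a term over one subdomain
#'
#' @param term a library term.
#' @param weight a [make_weight()] object.
#' @param fields a [field_sequence()] covering the subdomain's grid, or a
#'   prebuilt subdomain [eval_context()].
#' @param comp free-index component values (length = rank).
#' @param transfer apply the integration-by-parts plan (default TRUE);
#'   FALSE evaluates all derivatives on the data (used by oracles).
#' @return scalar integral value.
#' @export
integrate_term <- function(term, weight, fields, comp = integer(0),
                           transfer = TRUE) {
  sub <- weight$subdomain
  ctx <- if (inherits(fields, "eval_context")) fields
         else eval_context(slice_fields(fields, sub))
  if (!all(is.finite(ctx$u)) || !all(is.finite(ctx$n))) {
    stop("non-finite data inside subdomain")
  }
  plans <- transfer_derivatives(term, tau = weight$tau)
  free_assign <- stats::setNames(as.integer(comp), FREE_LABELS[seq_along(comp)])
  total <- 0
  for (k in seq_along(term$monomials)) {
    plan <- plans[[k]]
    if (!transfer) plan <- list(transfer = FALSE, sign = 1, order = 0L)
    total <- total + integrate_monomial(ctx, term$monomials[[k]], plan,
                                        free_assign, weight)
  }
  total
}

# All-index weak integrals of a term's leading monomial (no transfer, plain
# weight): contributes rows to the single-term scale Xi.
uncontracted_weak_sq <- function(ctx, term, weight) {
  m <- term$monomials[[1]]
  labs <- sort(unique(mono_labels(m)))
  wq0 <- weight$wq(c(0L, 0L, 0L))
  total <- 0
  for (asg in bound_assignments(labs)) {
    pref <- symbols_prefactor(m, asg)
    if (pref == 0) next
    arr <- mono_product_array(ctx, m, asg)
    if (is.null(arr)) arr <- array(1, ctx$dims)
    total <- total + (pref * sum(arr * wq0))^2
  }
  total
}

#' Assemble the weak-form feature matrix G
#'
#' One row per (subdomain, weight function, tensor component); one column
#' per library term.  Each subdomain gets the four modulation choices (none,
#' x, y, t) with independent random phases.  The director restricted to each
#' subdomain is sign-aligned before evaluation, so rows are invariant under
#' arbitrary stored-sign flips away from defects.  Columns whose single-term
#' scale Xi is negligible relative to the largest (no usable variation in
#' the data, e.g. time derivatives of a steady field) are flagged inactive.
#'
#' @param library a `term_library`.
#' @param fields a nondimensionalized [field_sequence()].
#' @param mask optional [build_mask()] object or array; multiplies the
#'   weights.
#' @param count number of subdomains; default gives at least 10 rows per
#'   column.
#' @param extents subdomain extents; default [default_subdomain_extents()].
#' @param tau envelope power (default 4).
#' @param seed RNG seed for subdomain placement and phases.
#' @return object of class `feature_matrix` with fields `G`, `Xi`, `rows`
#'   (metadata data.frame), `library`, `active`, `config`.
#' @export
build_feature_matrix <- function(library, fields, mask = NULL, count = NULL,
                                 extents = NULL, tau = 4, seed = 1L) {
  terms <- library$terms
  N <- length(terms)
  if (N == 0L) stop("library is empty")
  comps <- class_components(library$spec$class)
  ncomp <- length(comps)
  n_weights <- 4L
  if (is.null(count)) count <- ceiling(10 * N / (n_weights * ncomp))
  if (is.null(extents)) extents <- default_subdomain_extents(fields$grid)
  subs <- sample_subdomains(fields$grid, count, extents, seed = seed)
  phases <- with_seed(seed + 1L, matrix(stats::runif(count * n_weights, 0, 2 * pi),
                                        count, n_weights))
  psi <- if (inherits(mask, "field_mask")) mask$psi else mask
  nrows <- count * n_weights * ncomp
  G <- matrix(0, nrows, N)
  colnames(G) <- vapply(terms, function(t) t$key, character(1))
  Xi2 <- numeric(N)
  plans <- lapply(terms, transfer_derivatives, tau = tau)
  meta <- data.frame(subdomain = integer(nrows), weight = integer(nrows),
                     comp = character(nrows), stringsAsFactors = FALSE)
  row <- 0L
  for (l in seq_len(count)) {
    sub <- subs[[l]]
    ctx <- eval_context(slice_fields(fields, sub))
    weights <- lapply(1:n_weights, function(k) {
      make_weight(sub, fields$grid, tau = tau, modulation = k - 1L,
                  phase = phases[l, k], mask = psi)
    })
    for (k in seq_len(n_weights)) {
      wobj <- weights[[k]]
      for (ci in seq_len(ncomp)) {
        row <- row + 1L
        free_assign <- stats::setNames(as.integer(comps[[ci]]),
                                       FREE_LABELS[seq_along(comps[[ci]])])
        for (r in seq_len(N)) {
          tm <- terms[[r]]
          val <- 0
          for (q in seq_along(tm$monomials)) {
            val <- val + integrate_monomial(ctx, tm$monomials[[q]], plans[[r]][[q]],
                                            free_assign, wobj)
          }
          G[row, r] <- val
        }
        meta$subdomain[row] <- l
        meta$weight[row] <- k
        meta$comp[row] <- paste(comps[[ci]], collapse = "")
      }
      for (r in seq_len(N)) {
        Xi2[r] <- Xi2[r] + uncontracted_weak_sq(ctx, terms[[r]], wobj)
      }
    }
  }
  if (any(!is.finite(G))) stop("non-finite entries in feature matrix")
  Xi <- sqrt(Xi2)
  if (max(abs(G)) == 0) stop("no usable data: all weak integrals vanish (mask may exclude everything)")
  active <- Xi > 1e-10 * max(Xi)
  structure(list(G = G, Xi = Xi, rows = meta, library = library,
                 active = active,
                 config = list(count = count, extents = extents, tau = tau,
                               seed = seed, n_weights = n_weights)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d rows x %d terms (%d active), %d subdomains of %s points\n",
              nrow(x$G), ncol(x$G), sum(x$active), x$config$count,
              paste(x$config$extents, collapse = "x")))
  invisible(x)
}
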