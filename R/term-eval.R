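# Numeric evaluation of symbolic terms on gridded fields.
#
# An evaluation context bundles the (sign-aligned) fields with a derivative
# backend and a memo cache.  The "stencil" backend uses the second-order
# finite differences applied to experimental data; the "spectral" backend is
# used on periodic synthetic probe fields where near machine-precision
# derivatives are required (identity classification, fingerprints,
# covariance checks).

#' Build an evaluation context for term arrays
#'
#' @param fields a [field_sequence()] (or list with `u`, `n`, `grid`).
#' @param backend `"stencil"` (second-order differences, one-sided at
#'   boundaries) or `"spectral"` (FFT, periodic fields only).
#' @param align sign-align the director with [align_director()] first
#'   (default TRUE); evaluation then treats `n` as an ordinary vector field.
#' @return an environment of class `eval_context`.
#' @export
eval_context <- function(fields, backend = c("stencil", "spectral"), align = TRUE) {
  backend <- match.arg(backend)
  ctx <- new.env(parent = emptyenv())
  ctx$u <- fields$u
  ctx$n <- if (align) align_director(fields$n) else fields$n
  ctx$dims <- dim(fields$u)[1:3]
  ctx$h <- grid_spacing(fields$grid)
  ctx$backend <- backend
  ctx$cache <- new.env(parent = emptyenv())
  class(ctx) <- "eval_context"
  ctx
}

ctx_diff <- function(ctx, A, axis) {
  if (ctx$backend == "spectral") spectral_diff(A, axis, ctx$h[axis])
  else central_diff(A, axis, ctx$h[axis])
}

# Array of one factor under a concrete index assignment.
# assign: named integer vector mapping labels to components 1/2.
factor_array <- function(ctx, f, assign) {
  comp <- assign[[f$comps]]
  axes <- sort(c(if (length(f$derivs)) unname(assign[f$derivs]) else integer(0),
                 rep(3L, f$dt)))
  key <- paste(f$sym, comp, paste(axes, collapse = ""), sep = "|")
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  arr <- if (f$sym == "u") ctx$u[, , , comp] else ctx$n[, , , comp]
  for (ax in axes) arr <- ctx_diff(ctx, arr, ax)
  ctx$cache[[key]] <- arr
  arr
}

mono_bound_labels <- function(mono) {
  labs <- mono_labels(mono)
  sort(unique(labs[!(labs %in% FREE_LABELS)]))
}

# Constant (delta/eps) prefactor of a monomial under an assignment;
# 0 kills the combination.
symbol_factor <- function(f, assign) {
  a <- assign[[f$comps[1]]]; b <- assign[[f$comps[2]]]
  if (f$sym == "delta") return(if (a == b) 1 else 0)
  if (a == b) 0 else if (a == 1L) 1 else -1  # eps_12 = 1, eps_21 = -1
}

bound_assignments <- function(bound) {
  if (length(bound) == 0L) return(list(stats::setNames(integer(0), character(0))))
  grid <- expand.grid(rep(list(1:2), length(bound)))
  lapply(seq_len(nrow(grid)), function(r) {
    stats::setNames(as.integer(grid[r, ]), bound)
  })
}

# delta/eps prefactor of a monomial under an assignment (0 kills the combo).
symbols_prefactor <- function(mono, asg) {
  pref <- mono$coef
  for (f in mono$factors) {
    if (f$sym %in% c("delta", "eps")) {
      pref <- pref * symbol_factor(f, asg)
      if (pref == 0) return(0)
    }
  }
  pref
}

# Cached pointwise product of the field (u/n) factors of a monomial under a
# concrete assignment; NULL when the monomial has no field factors.
mono_product_array <- function(ctx, mono, asg) {
  ff <- Filter(function(f) f$sym %in% c("u", "n"), mono$factors)
  if (length(ff) == 0L) return(NULL)
  labs <- unique(unlist(lapply(ff, function(f) c(f$derivs, f$comps))))
  key <- paste0("P|", paste(vapply(ff, factor_string, character(1)), collapse = ";"),
                "|", paste(labs, asg[labs], sep = "", collapse = ","))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  arr <- NULL
  for (f in ff) {
    fa <- factor_array(ctx, f, asg)
    arr <- if (is.null(arr)) fa else arr * fa
  }
  ctx$cache[[key]] <- arr
  arr
}

# Pointwise array of a monomial with free indices fixed.
mono_array <- function(ctx, mono, free_assign) {
  out <- array(0, ctx$dims)
  for (ba in bound_assignments(mono_bound_labels(mono))) {
    asg <- c(free_assign, ba)
    pref <- symbols_prefactor(mono, asg)
    if (pref == 0) next
    arr <- mono_product_array(ctx, mono, asg)
    if (is.null(arr)) arr <- array(1, ctx$dims)
    out <- out + pref * arr
  }
  out
}

#' Evaluate one tensor component of a term pointwise on the grid
#'
#' @param ctx an [eval_context()].
#' @param term a library term.
#' @param comp integer vector of free-index values (length = rank).
#' @return numeric array `(nx, ny, nt)`.
#' @export
term_component <- function(ctx, term, comp = integer(0)) {
  free_assign <- stats::setNames(as.integer(comp), FREE_LABELS[seq_along(comp)])
  out <- array(0, ctx$dims)
  for (m in term$monomials) out <- out + mono_array(ctx, m, free_assign)
  out
}

# 2-norm over the grid of the term's leading monomial with every index
# (free and contracted) opened up -- the "uncontracted tensor" scale.
uncontracted_norm <- function(ctx, term) {
  m <- term$monomials[[1]]
  labs <- sort(unique(mono_labels(m)))
  total <- 0
  for (asg in bound_assignments(labs)) {
    pref <- symbols_prefactor(m, asg)
    if (pref == 0) next
    arr <- mono_product_array(ctx, m, asg)
    if (is.null(arr)) arr <- array(1, ctx$dims)
    total <- total + sum((pref * arr)^2)
  }
  sqrt(total)
}

#' Strong-form relative residual of a relation on given fields
#'
#' Evaluates `sum_r c_r F^r` pointwise over the grid and normalizes by the
#' largest single term (multi-term relations) or by the uncontracted tensor
#' norm (single-term relations).
#'
#' @param terms list of library terms (all of one symmetry class).
#' @param coefs numeric coefficients.
#' @param ctx an [eval_context()].
#' @return the scalar residual eta.
#' @export
strong_form_eta <- function(terms, coefs, ctx) {
  comps <- class_components(terms[[1]]$class)
  res2 <- 0
  tnorm2 <- numeric(length(terms))
  for (cc in comps) {
    arrs <- lapply(terms, term_component, ctx = ctx, comp = cc)
    tot <- array(0, ctx$dims)
    for (r in seq_along(terms)) {
      tot <- tot + coefs[r] * arrs[[r]]
      tnorm2[r] <- tnorm2[r] + sum((coefs[r] * arrs[[r]])^2)
    }
    res2 <- res2 + sum(tot^2)
  }
  if (length(terms) == 1L) {
    denom <- uncontracted_norm(ctx, terms[[1]])
  } else {
    denom <- sqrt(max(tnorm2))
  }
  if (denom == 0) stop("degenerate normalization")
  sqrt(res2) / denom
}

#' Remove numerically dependent terms from a library
#'
#' Evaluates every term on several independent band-limited random probe
#' field sets (spectral derivatives, so evaluations are exact to rounding),
#' samples the resulting component arrays at a fixed set of grid points, and
#' removes any term whose fingerprint vector lies (to `tol`) in the span of
#' the retained earlier terms or is numerically zero.  Removals are logged
#' in the library's `removed` field.
#'
#' @param library a `term_library`.
#' @param probes list of periodic [field_sequence()] probes (>= 3 advised);
#'   defaults to three [random_smooth_fields()] draws on a 24^3 grid.
#' @param npoints sample points per probe (the default gives >= 200 samples
#'   across probes and components).
#' @param tol relative tolerance of the rank test (default 1e-6).
#' @return the pruned `term_library`.
#' @export
fingerprint_dedup <- function(library, probes = NULL, npoints = 120L, tol = 1e-6) {
  if (is.null(probes)) {
    g <- field_grid(24L, 24L, 24L, 2 * pi / 24, 2 * pi / 24, 2 * pi / 24)
    probes <- lapply(1:3, function(s) random_smooth_fields(g, cutoff = 3L, seed = 100L + s))
  }
  ctxs <- lapply(probes, eval_context, backend = "spectral", align = FALSE)
  comps <- class_components(library$spec$class)
  idx <- lapply(ctxs, function(ctx) {
    np <- prod(ctx$dims)
    unique(pmax(1L, round(seq(1, np, length.out = npoints))))
  })
  fp <- function(term) {
    v <- unlist(lapply(seq_along(ctxs), function(k) {
      unlist(lapply(comps, function(cc) {
        term_component(ctxs[[k]], term, cc)[idx[[k]]]
      }))
    }))
    if (any(!is.finite(v))) stop("probe evaluation produced non-finite values")
    v
  }
  kept <- list()
  Q <- NULL
  removed <- library$removed
  for (term in library$terms) {
    v <- fp(term)
    nv <- sqrt(sum(v^2))
    if (nv < tol * sqrt(length(v))) {
      removed <- c(removed, list(list(key = term$key, label = pretty_term(term),
                                      reason = "identically zero on probes")))
      next
    }
    r <- if (is.null(Q)) v else v - Q %*% crossprod(Q, v)
    nr <- sqrt(sum(r^2))
    if (nr < tol * nv) {
      removed <- c(removed, list(list(key = term$key, label = pretty_term(term),
                                      reason = "linearly dependent on earlier terms")))
      next
    }
    kept <- c(kept, list(term))
    Q <- cbind(Q, r / nr)
  }
  library$terms <- kept
  library$removed <- removed
  library
}

#' Convenience: a deduplicated library for a rank/parity choice
#'
#' Generates the grammar library and applies [fingerprint_dedup()] with
#' default probes.
#'
#' @param ... passed to [library_spec()].
#' @param probes optional probe list for deduplication.
#' @return a `term_library`.
#' @export
standard_library <- function(..., probes = NULL) {
  fingerprint_dedup(generate_library(library_spec(...)), probes = probes)
}
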