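# Orchestration: configuration, the end-to-end discovery pipeline,
# relation rendering and report serialization.

#' Discovery run configuration
#'
#' Validated bundle of every tunable of a discovery run; serialized verbatim
#' into reports so results are reproducible from the report alone.
#'
#' @param libraries list of [library_spec()]s to search.
#' @param count subdomains per library (NULL: 10 rows per column).
#' @param extents subdomain extents (NULL: [default_subdomain_extents()]).
#' @param tau envelope power.
#' @param gamma STR growth threshold.
#' @param accept_eta,stop_eta acceptance / stop residuals.
#' @param smooth_window,smooth_degree moving least-squares smoothing
#'   parameters (window NULL disables smoothing).
#' @param use_mask build and apply the reliability mask.
#' @param nondim nondimensionalize before discovery.
#' @param n_uncertainty half-sample resamples for coefficient uncertainty.
#' @param seed master seed; all randomness (subdomains, phases, subsamples,
#'   probes) derives from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(libraries = default_library_set(),
                       count = NULL, extents = NULL, tau = 4,
                       gamma = 1.15, accept_eta = 0.1, stop_eta = 0.4,
                       smooth_window = 5L, smooth_degree = 2L,
                       use_mask = TRUE, nondim = TRUE,
                       n_uncertainty = 100L, seed = 1L) {
  if (gamma <= 1) stop("gamma must exceed 1")
  if (accept_eta <= 0 || stop_eta <= 0) stop("residual thresholds must be positive")
  structure(list(libraries = libraries, count = count, extents = extents,
                 tau = tau, gamma = gamma, accept_eta = accept_eta,
                 stop_eta = stop_eta, smooth_window = smooth_window,
                 smooth_degree = smooth_degree, use_mask = use_mask,
                 nondim = nondim, n_uncertainty = as.integer(n_uncertainty),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' The default set of library specs searched by the pipeline
#'
#' Scalar even, vector odd, and symmetric-traceless even: the classes in
#' which the fundamental relations of the active nematic live.  (Scalar
#' odd, vector even and the antisymmetric class are available through
#' [library_spec()].)
#'
#' @return named list of [library_spec()]s.
#' @export
default_library_set <- function() {
  list(scalar_even = library_spec(0L, "even"),
       vector_odd = library_spec(1L, "odd"),
       symtraceless_even = library_spec(2L, "even"))
}

#' Preprocess a field sequence for discovery
#'
#' Builds the reliability mask from the raw intensity and director, smooths
#' the velocity components and the nematic-tensor components (smoothing the
#' tensor rather than n itself keeps the operation gauge invariant), and
#' nondimensionalizes so the mean speed and vorticity are unity.
#'
#' @param fields a [field_sequence()].
#' @param config a [run_config()].
#' @return list with `fields`, `mask`, `scales`.
#' @export
preprocess_fields <- function(fields, config = run_config()) {
  mask <- NULL
  if (config$use_mask) {
    mask <- build_mask(fields$phi, fields$n, fields$grid)
  }
  if (!is.null(config$smooth_window)) {
    w <- config$smooth_window; dg <- config$smooth_degree
    u <- fields$u
    u[, , , 1] <- mls_smooth(u[, , , 1], w, dg)
    u[, , , 2] <- mls_smooth(u[, , , 2], w, dg)
    q1 <- mls_smooth(fields$n[, , , 1]^2 - 0.5, w, dg)
    q2 <- mls_smooth(fields$n[, , , 1] * fields$n[, , , 2], w, dg)
    # director from the smoothed Q-tensor: angle of the major eigenvector
    ang <- 0.5 * atan2(2 * q2, 2 * q1)
    n <- fields$n
    n[, , , 1] <- cos(ang); n[, , , 2] <- sin(ang)
    fields <- field_sequence(fields$grid, u, n, fields$phi)
  }
  scales <- list(length = 1, time = 1)
  if (config$nondim) {
    nd <- nondimensionalize(fields, mask)
    fields <- nd$fields
    scales <- nd$scales
  }
  list(fields = fields, mask = mask, scales = scales)
}

#' Run the full discovery pipeline
#'
#' Preprocess, generate and deduplicate each library, assemble the weak-form
#' feature matrix, discover relations by sequentially thresholded
#' regression, classify each as identity or physical on synthetic probes,
#' and quantify coefficient uncertainty by half-sample resampling.
#'
#' @param fields a [field_sequence()] (raw; preprocessing is applied here).
#' @param config a [run_config()].
#' @param probes optional probe fields for dedup/classification (defaults
#'   derive from the master seed).
#' @return object of class `spider_run`: list with `reports` (per library),
#'   `scales`, `mask`, `config`.
#' @export
spider_discover <- function(fields, config = run_config(), probes = NULL) {
  pre <- preprocess_fields(fields, config)
  if (is.null(probes)) {
    probes <- default_probes(seed = config$seed + 7777L)
  }
  reports <- list()
  libnames <- names(config$libraries)
  if (is.null(libnames)) libnames <- paste0("library", seq_along(config$libraries))
  for (k in seq_along(config$libraries)) {
    lib <- fingerprint_dedup(generate_library(config$libraries[[k]]), probes = probes)
    fm <- build_feature_matrix(lib, pre$fields,
                               mask = if (config$use_mask) pre$mask else NULL,
                               count = config$count, extents = config$extents,
                               tau = config$tau, seed = config$seed + 13L * k)
    rep <- discover_all(fm, gamma = config$gamma,
                        accept_eta = config$accept_eta,
                        stop_eta = config$stop_eta,
                        classify_probes = probes)
    for (q in seq_along(rep$relations)) {
      rel <- rep$relations[[q]]
      if (length(rel$support_idx) > 1L) {
        rel$uncertainty <- estimate_uncertainty(fm$G, rel$support_idx,
                                                nsample = config$n_uncertainty,
                                                seed = config$seed + 97L * k + q)
      }
      rep$relations[[q]] <- rel
    }
    reports[[libnames[k]]] <- rep
  }
  structure(list(reports = reports, scales = pre$scales, mask = pre$mask,
                 config = config),
            class = "spider_run")
}

#' @export
print.spider_run <- function(x, ...) {
  cat("spider_run\n")
  for (nm in names(x$reports)) {
    rep <- x$reports[[nm]]
    cat(sprintf("-- %s: %d relation(s)\n", nm, length(rep$relations)))
    for (r in rep$relations) {
      cat("   ", render_relation(r, library = rep$library), "\n")
    }
  }
  invisible(x)
}

#' Render a relation as an equation string
#'
#' Coefficients are normalized to the leading (largest-magnitude) term.
#' When the library is supplied, term keys are replaced by index-notation
#' labels, and for director-equation supports the strain/rotation split is
#' regrouped into the `Omega n` / `Pperp Abar n` notation when the raw
#' coefficients are consistent with it.
#'
#' @param relation a `spider_relation`.
#' @param library optional `term_library` for labels.
#' @param digits significant digits.
#' @return a string like `"d_a u_a = 0"`.
#' @export
render_relation <- function(relation, library = NULL, digits = 3) {
  labels <- relation$keys
  if (!is.null(library)) {
    keys <- vapply(library$terms, function(t) t$key, character(1))
    idx <- match(relation$keys, keys)
    labels <- ifelse(is.na(idx), relation$keys,
                     vapply(library$terms[idx], pretty_term, character(1)))
  }
  co <- relation$coefs
  lead <- which.max(abs(co))
  co <- co / co[lead]
  unc <- relation$uncertainty
  fmt <- function(k) {
    v <- co[k]
    s <- format(signif(v, digits))
    if (!is.null(unc) && is.finite(unc$pct[k])) {
      s <- sprintf("(%s +- %.2g%%)", s, unc$pct[k])
    }
    s
  }
  parts <- vapply(seq_along(co), function(k) {
    if (k == lead && is.null(unc)) {
      if (abs(co[k] - 1) < 1e-12) paste0("[", labels[k], "]")
      else paste0(fmt(k), " [", labels[k], "]")
    } else paste0(fmt(k), " [", labels[k], "]")
  }, character(1))
  paste(paste(parts, collapse = " + "), "= 0")
}

#' Map a discovered vector-odd relation to director-equation coefficients
#'
#' The grammar represents the director equation with raw velocity-gradient
#' factors; the strain/rotation couplings appear through the columns
#' `d_i u_a n_a`, `d_a u_i n_a`, `n_i n_a d_a u_b n_b` and `(d_a u_a) n_i`.
#' With coefficients normalized to the `d_t n_i` term this inverts to
#' `c1` (advection), `c2` (rotation) and `c3` (aligned strain), with
#' consistency requiring the `n_i (n A n)` coefficient to equal `-c3` and
#' the divergence coupling to vanish.
#'
#' @param relation a `spider_relation` from the vector-odd library.
#' @param library the `term_library`.
#' @return list with `c1`, `c2`, `c3`, `consistency` (largest unexplained
#'   normalized coefficient), or NULL if the support contains no time
#'   derivative term.
#' @export
director_equation_coefficients <- function(relation, library) {
  ref <- director_equation_terms()
  refkeys <- vapply(ref, function(t) t$key, character(1))
  co <- relation$coefs
  k_dt <- which(relation$keys == refkeys[["dt"]])
  if (length(k_dt) != 1L || abs(co[k_dt]) < 1e-12) return(NULL)
  co <- co / co[k_dt]
  pick <- function(nm) {
    k <- which(relation$keys == refkeys[[nm]])
    if (length(k) == 1L) co[k] else 0
  }
  c1 <- pick("adv")
  cA <- pick("gradA")  # n_a d_i u_a: derivative on the free index
  cB <- pick("gradB")  # n_a d_a u_i: transposed coupling
  cnn <- pick("nnAn")
  cdiv <- pick("divn")
  c3 <- cA + cB
  c2 <- cA - cB
  other <- !(relation$keys %in% refkeys)
  resid <- max(c(abs(cnn + c3), abs(cdiv), if (any(other)) abs(co[other]) else 0))
  list(c1 = c1, c2 = c2, c3 = c3, consistency = resid)
}

# Canonical reference terms of the director equation in the raw
# velocity-gradient basis the grammar emits.
director_equation_terms <- function() {
  mk <- function(...) make_term(list(new_monomial(1, list(...))), 1L, "odd", "vector")
  list(
    dt = mk(new_factor("n", dt = 1L, comps = "i")),
    adv = mk(new_factor("u", comps = "a"), new_factor("n", derivs = "a", comps = "i")),
    gradA = mk(new_factor("u", derivs = "i", comps = "a"), new_factor("n", comps = "a")),
    gradB = mk(new_factor("u", derivs = "a", comps = "i"), new_factor("n", comps = "a")),
    nnAn = mk(new_factor("u", derivs = "a", comps = "b"), new_factor("n", comps = "a"),
              new_factor("n", comps = "b"), new_factor("n", comps = "i")),
    divn = mk(new_factor("u", derivs = "a", comps = "a"), new_factor("n", comps = "i")))
}

#' Serialize a discovery run to JSON
#'
#' @param run a `spider_run` (or single `discovery_report`).
#' @param path output path.
#' @export
write_report_json <- function(run, path) {
  rel_obj <- function(rel, library) {
    list(keys = as.list(rel$keys),
         labels = lapply(library$terms[match(rel$keys,
                   vapply(library$terms, function(t) t$key, character(1)))], pretty_term),
         coefficients = rel$coefs, eta = rel$eta, kind = rel$kind,
         classification = rel$classification,
         probe_eta = rel$probe_eta,
         rendered = render_relation(rel, library),
         uncertainty = if (!is.null(rel$uncertainty))
           list(mean = rel$uncertainty$mean, sd = rel$uncertainty$sd,
                pct = rel$uncertainty$pct) else NULL)
  }
  rep_obj <- function(rep) {
    list(relations = lapply(rep$relations, rel_obj, library = rep$library),
         full_etas = rep$full_etas,
         library_size = length(rep$library$terms),
         removed = rep$library$removed,
         config = rep$config)
  }
  obj <- if (inherits(run, "discovery_report")) rep_obj(run)
  else list(reports = lapply(run$reports, rep_obj),
            scales = run$scales,
            config = lapply(unclass(run$config), function(x) {
              if (inherits(x, "library_spec")) unclass(x)
              else if (is.list(x) && all(vapply(x, inherits, logical(1), "library_spec")))
                lapply(x, unclass)
              else x
            }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' One-line per relation plain-text summary of a run
#'
#' @param run a `spider_run`.
#' @return character vector (one line per relation), invisibly printed.
#' @export
report_summary <- function(run) {
  out <- character(0)
  for (nm in names(run$reports)) {
    rep <- run$reports[[nm]]
    if (length(rep$relations) == 0L) {
      out <- c(out, sprintf("%s: no relations found", nm))
      next
    }
    for (r in rep$relations) {
      out <- c(out, sprintf("%s: %s   [eta = %.3g, %s]", nm,
                            render_relation(r, rep$library), r$eta,
                            r$classification))
    }
  }
  out
}
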