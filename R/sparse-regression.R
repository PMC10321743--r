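# Sparse identification of relations from the weak-form feature matrix:
# minimum-singular-vector solutions, sequentially thresholded regression,
# iterative multi-relation discovery, identity classification on synthetic
# probes, combinatorial validation and half-sample uncertainty.

#' Unit-norm minimizer of |G c|
#'
#' The right singular vector of `G` for its smallest singular value, i.e.
#' the solution of the constrained least-squares problem `G'G c = 0`,
#' `|c| = 1`.  The sign is fixed so the largest-magnitude entry is positive.
#'
#' @param G numeric matrix.
#' @return unit-norm coefficient vector.
#' @export
min_singular_vector <- function(G) {
  if (length(G) == 0L) stop("empty matrix")
  if (any(!is.finite(G))) stop("non-finite entries in G")
  sv <- svd(G, nu = 0)
  d <- sv$d
  p <- length(d)
  if (p >= 2L && d[p - 1L] > 0 && (d[p - 1L] - d[p]) / d[p - 1L] < 1e-12) {
    warning("smallest singular value is (near-)degenerate; choice is deterministic but not unique")
  }
  c_ <- sv$v[, p]
  if (c_[which.max(abs(c_))] < 0) c_ <- -c_
  c_
}

# Minimum-singular-vector solution in column-normalized coordinates: each
# column is scaled to unit 2-norm before the SVD so the minimizer targets
# relative (not absolute) cancellation, then coefficients are mapped back
# and renormalized.  This is the solve used throughout STR.
msv_scaled <- function(G, norms = NULL) {
  if (is.null(norms)) norms <- sqrt(colSums(G^2))
  norms[norms == 0] <- 1
  c_ <- min_singular_vector(sweep(G, 2, norms, `/`))
  c_ <- c_ / norms
  c_ / sqrt(sum(c_^2))
}

#' Normalized weak-form residual of a relation
#'
#' `eta = |G c| / Xi` where for multi-term relations `Xi` is the 2-norm of
#' the largest term `max_r |c_r G^r|`, and for single-term relations it is
#' the supplied uncontracted-tensor scale of that term.
#'
#' @param G feature-matrix columns of the relation's support.
#' @param c_ coefficients on those columns.
#' @param kind `"multi"` or `"single"`.
#' @param Xi single-term scale (required for `kind = "single"`).
#' @return scalar residual.
#' @export
residual_eta <- function(G, c_, kind = c("multi", "single"), Xi = NULL) {
  kind <- match.arg(kind)
  G <- as.matrix(G)
  num <- sqrt(sum((G %*% c_)^2))
  if (kind == "single") {
    if (is.null(Xi) || Xi == 0) stop("degenerate normalization")
    return(num / Xi)
  }
  scales <- abs(c_) * sqrt(colSums(G^2))
  den <- max(scales)
  if (den == 0) stop("degenerate normalization")
  num / den
}

#' Sequentially thresholded regression on one library
#'
#' Starting from the full library, repeatedly computes the
#' minimum-singular-vector solution, records the residual `eta_k`, and
#' discards the term with the smallest magnitude `|c_r G^r|` (ties broken
#' toward the later term in canonical order).  Iteration stops when a
#' single term remains or when the residual would grow by more than the
#' factor `gamma`; the support before the jump is selected.  A single-term
#' selection is re-normalized with the single-term scale before acceptance.
#'
#' @param G feature matrix (active columns).
#' @param Xi single-term scales per column.
#' @param gamma residual growth threshold (default 1.15).
#' @param accept_eta residual below which a relation is accepted
#'   (default 0.1).
#' @param keys optional column names for reporting.
#' @return list with `trace` (per-iteration support/coefficients/eta) and
#'   `relation` (the selected `spider_relation`, or NULL if not accepted).
#' @export
str_solve <- function(G, Xi, gamma = 1.15, accept_eta = 0.1, keys = colnames(G)) {
  stopifnot(ncol(G) >= 1L)
  if (is.null(keys)) keys <- as.character(seq_len(ncol(G)))
  active <- seq_len(ncol(G))
  trace <- list()
  repeat {
    Ga <- G[, active, drop = FALSE]
    c_ <- msv_scaled(Ga)
    kind <- if (length(active) == 1L) "single" else "multi"
    eta <- residual_eta(Ga, c_, kind, Xi = Xi[active])
    trace[[length(trace) + 1L]] <- list(support = active, c = c_, eta = eta,
                                        kind = kind)
    if (length(active) == 1L) break
    mags <- abs(c_) * sqrt(colSums(Ga^2))
    drop_k <- max(which(mags == min(mags)))  # tie: later in canonical order
    active <- active[-drop_k]
  }
  etas <- vapply(trace, function(s) s$eta, numeric(1))
  sel <- length(trace)
  # the growth rule; jumps within numerical-zero territory (quadrature /
  # rounding noise) do not count, so exact relations prune fully
  eta_floor <- 1e-9
  for (k in seq_len(length(trace) - 1L)) {
    if (etas[k + 1L] > gamma * etas[k] && etas[k + 1L] > eta_floor) { sel <- k; break }
  }
  st <- trace[[sel]]
  relation <- NULL
  if (st$eta <= accept_eta) {
    relation <- new_relation(keys[st$support], st$c, st$eta, st$kind,
                             support_idx = st$support)
  }
  list(trace = trace, relation = relation, selected = sel)
}

new_relation <- function(keys, coefs, eta, kind, support_idx = NULL) {
  structure(list(keys = keys, coefs = coefs / sqrt(sum(coefs^2)), eta = eta,
                 kind = kind, support_idx = support_idx,
                 classification = "unclassified", uncertainty = NULL),
            class = "spider_relation")
}

#' @export
print.spider_relation <- function(x, ...) {
  cat(render_relation(x), "\n")
  invisible(x)
}

#' Iterative discovery of all relations in a library
#'
#' Repeats [str_solve()]; after each accepted relation the relation's
#' largest-magnitude term is removed from the library and the search
#' continues, stopping when the full remaining library's residual exceeds
#' `stop_eta`, when a candidate is rejected, or when the library empties.
#' Columns flagged inactive in the feature matrix (negligible single-term
#' scale) are excluded up front.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param gamma STR growth threshold (default 1.15).
#' @param accept_eta acceptance residual (default 0.1).
#' @param stop_eta full-library residual at which the search stops
#'   (default 0.4).
#' @param classify_probes optional list of probe [field_sequence()]s; if
#'   supplied, each accepted relation is classified identity/physical.
#' @param stability_pct multi-term candidates whose coefficients move by more
#'   than this percent SD under half-row resampling are treated as noise
#'   artifacts rather than relations (default 5); the search then escalates
#'   to an exhaustive small-support combinatorial search before stopping.
#' @param comb_kmax largest support size tried in the combinatorial
#'   escalation (default 4).
#' @param comb_budget subset budget of the escalation (default 2e5).
#' @return object of class `discovery_report`.
#' @export
discover_all <- function(fm, gamma = 1.15, accept_eta = 0.1, stop_eta = 0.4,
                         classify_probes = NULL, stability_pct = 5,
                         comb_kmax = 4L, comb_budget = 2e5) {
  keys <- colnames(fm$G)
  active <- which(fm$active)
  relations <- list()
  traces <- list()
  full_etas <- numeric(0)
  # single-term pre-scan: columns that are relations on their own (their
  # weak norm is small against the uncontracted tensor scale) are reported
  # and removed first; exactly satisfied constraints otherwise leave the
  # multi-term normalization of STR degenerate
  if (length(active) > 0L) {
    eta1 <- sqrt(colSums(fm$G[, active, drop = FALSE]^2)) / fm$Xi[active]
    singles <- active[eta1 <= accept_eta]
    for (idx in singles[order(eta1[match(singles, active)])]) {
      rel <- new_relation(keys[idx], 1, eta1[match(idx, active)], "single",
                          support_idx = idx)
      if (!is.null(classify_probes)) {
        rel <- classify_identity(rel, fm$library, probes = classify_probes)
      }
      relations[[length(relations) + 1L]] <- rel
    }
    active <- setdiff(active, singles)
  }
  round <- 0L
  stable <- function(rel_local) {
    # a genuine relation keeps its coefficients under half-row resampling;
    # a noise-overfit combination does not
    if (length(rel_local$support_idx) <= 1L) return(TRUE)
    unc <- estimate_uncertainty(fm$G, rel_local$support_idx, nsample = 40L,
                                seed = fm$config$seed + 31L * round)
    all(is.finite(unc$pct)) && max(unc$pct) <= stability_pct
  }
  repeat {
    if (length(active) == 0L) break
    round <- round + 1L
    Ga <- fm$G[, active, drop = FALSE]
    c_full <- msv_scaled(Ga)
    kindf <- if (length(active) == 1L) "single" else "multi"
    eta_full <- residual_eta(Ga, c_full, kindf, Xi = fm$Xi[active])
    full_etas <- c(full_etas, eta_full)
    if (eta_full > stop_eta) break
    res <- str_solve(Ga, fm$Xi[active], gamma = gamma, accept_eta = accept_eta,
                     keys = keys[active])
    traces[[length(traces) + 1L]] <- res$trace
    rel <- res$relation
    if (!is.null(rel)) {
      rel$support_idx <- active[rel$support_idx]
      if (!stable(rel)) rel <- NULL
    }
    if (is.null(rel)) {
      # STR did not produce a validated relation: exhaustive search over
      # small supports (the tractable regime) before giving up
      for (K in 2:min(comb_kmax, length(active))) {
        if (length(active) < 2L || choose(length(active), K) > comb_budget) break
        cand <- combinatorial_search(Ga, fm$Xi[active], K, budget = comb_budget,
                                     keys = keys[active])
        if (cand$eta > accept_eta) next
        cand$support_idx <- active[cand$support_idx]
        if (stable(cand)) { rel <- cand; break }
      }
    }
    if (is.null(rel)) break
    if (!is.null(classify_probes)) {
      rel <- classify_identity(rel, fm$library, probes = classify_probes)
    }
    relations[[length(relations) + 1L]] <- rel
    # prune: remove the largest-magnitude term of the accepted relation
    mags <- abs(rel$coefs) * sqrt(colSums(fm$G[, rel$support_idx, drop = FALSE]^2))
    biggest <- rel$support_idx[which.max(mags)]
    active <- setdiff(active, biggest)
  }
  structure(list(relations = relations, traces = traces, full_etas = full_etas,
                 library = fm$library, feature = fm,
                 config = list(gamma = gamma, accept_eta = accept_eta,
                               stop_eta = stop_eta)),
            class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf("discovery_report: %d relation(s)\n", length(x$relations)))
  for (r in x$relations) {
    cat("  ", render_relation(r, library = x$library),
        sprintf("   [eta = %.3g, %s]\n", r$eta, r$classification))
  }
  invisible(x)
}

#' Classify a relation as identity or physical on synthetic probes
#'
#' Rebuilds the relation's terms on band-limited random smooth fields
#' (spectral derivatives) and evaluates the strong-form residual.
#' Identities hold for arbitrary smooth fields, so their probe residual is
#' at rounding level; physical relations fail on generic (compressible)
#' probe flows.
#'
#' @param relation a `spider_relation`.
#' @param library the `term_library` the relation came from.
#' @param probes list of probe [field_sequence()]s (default: three
#'   [random_smooth_fields()] draws on a 48^3 periodic grid).
#' @param cutoff identity residual cutoff (default 1e-6).
#' @return the relation with `classification` set.
#' @export
classify_identity <- function(relation, library, probes = NULL, cutoff = 1e-6) {
  terms <- library$terms[match(relation$keys,
                               vapply(library$terms, function(t) t$key, character(1)))]
  if (any(vapply(terms, is.null, logical(1)))) stop("relation keys not found in library")
  if (is.null(probes)) probes <- default_probes()
  etas <- vapply(probes, function(p) {
    ctx <- eval_context(p, backend = "spectral", align = FALSE)
    strong_form_eta(terms, relation$coefs, ctx)
  }, numeric(1))
  relation$probe_eta <- max(etas)
  relation$classification <- if (max(etas) < cutoff) "identity" else "physical"
  relation
}

# Probe fields for classification: the director-angle amplitude is kept
# moderate so that cos/sin of the angle stay band limited to double
# precision on the grid (trigonometric harmonics of a band-limited angle
# decay factorially; 0.3 rad puts them below rounding at the Nyquist mode).
default_probes <- function(n = 48L, count = 3L, seed = 2024L) {
  g <- field_grid(n, n, n, 2 * pi / n, 2 * pi / n, 2 * pi / n)
  lapply(seq_len(count), function(s) {
    random_smooth_fields(g, cutoff = 3L, seed = seed + s, theta_amp = 0.3)
  })
}

#' Exhaustive search for the best K-term relation
#'
#' Minimizes the residual `eta` over all K-subsets of the library columns;
#' exact but exponential, used to validate STR selections.
#'
#' @param G feature matrix (active columns).
#' @param Xi single-term scales.
#' @param K support size.
#' @param budget maximum number of subsets (default 1e6).
#' @param keys optional column names.
#' @return `spider_relation` of the optimal subset.
#' @export
combinatorial_search <- function(G, Xi, K, budget = 1e6, keys = colnames(G)) {
  N <- ncol(G)
  if (is.null(keys)) keys <- as.character(seq_len(N))
  if (K < 1L || K > N) stop("K out of range")
  if (choose(N, K) > budget) {
    stop("combinatorial budget exceeded; validate with STR plus greedy term addition instead")
  }
  sets <- utils::combn(N, K)
  best <- NULL
  for (q in seq_len(ncol(sets))) {
    s <- sets[, q]
    Gs <- G[, s, drop = FALSE]
    c_ <- if (K == 1L) 1 else msv_scaled(Gs)
    kind <- if (K == 1L) "single" else "multi"
    eta <- residual_eta(Gs, c_, kind, Xi = if (K == 1L) Xi[s] else NULL)
    if (is.null(best) || eta < best$eta) {
      best <- new_relation(keys[s], c_, eta, kind, support_idx = s)
    }
  }
  best
}

#' Half-sample uncertainty of relation coefficients
#'
#' With the support fixed, recomputes the minimum-singular-vector solution
#' on `nsample` random half-row subsamples of the feature matrix (columns
#' restricted to the support), aligns signs with the full-matrix solution,
#' and reports per-coefficient means, SDs and percent SDs.
#'
#' @param G full feature matrix.
#' @param support integer column indices of the relation.
#' @param nsample number of subsamples (default 100).
#' @param frac fraction of rows per subsample (default 0.5).
#' @param seed RNG seed.
#' @return data.frame with `mean`, `sd`, `pct` per coefficient, plus the
#'   full-matrix solution as attribute `"c_full"`.
#' @export
estimate_uncertainty <- function(G, support, nsample = 100L, frac = 0.5,
                                 seed = 1L) {
  Gs <- G[, support, drop = FALSE]
  norms <- sqrt(colSums(Gs^2))
  c_full <- if (length(support) == 1L) 1 else msv_scaled(Gs, norms)
  m <- nrow(Gs)
  draws <- with_seed(seed, {
    replicate(nsample, sample.int(m, floor(frac * m)), simplify = FALSE)
  })
  samples <- matrix(NA_real_, nsample, length(support))
  skipped <- 0L
  for (q in seq_len(nsample)) {
    Gq <- Gs[draws[[q]], , drop = FALSE]
    if (length(support) == 1L) { samples[q, ] <- 1; next }
    cq <- tryCatch(msv_scaled(Gq, norms), error = function(e) NULL)
    if (is.null(cq)) { skipped <- skipped + 1L; next }
    if (sum(cq * c_full) < 0) cq <- -cq
    samples[q, ] <- cq
  }
  ok <- stats::complete.cases(samples)
  mu <- colMeans(samples[ok, , drop = FALSE])
  sdv <- apply(samples[ok, , drop = FALSE], 2, stats::sd)
  out <- data.frame(mean = mu, sd = sdv, pct = 100 * sdv / abs(mu))
  attr(out, "c_full") <- c_full
  attr(out, "skipped") <- skipped
  out
}
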