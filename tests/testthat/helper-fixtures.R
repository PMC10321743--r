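# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .fixture_cache[[key]] <- val
  val
}

periodic_grid <- function(n = 24L, L = 2 * pi) {
  field_grid(n, n, n, L / n, L / n, L / n)
}

cached_probes <- function(n = 24L) {
  memo(paste0("probes", n), {
    g <- periodic_grid(n)
    lapply(1:3, function(s) random_smooth_fields(g, cutoff = 3L, seed = 100L + s,
                                                 theta_amp = 0.3))
  })
}

cached_probes_fine <- function() {
  # finer periodic probes for identity classification, where spectral
  # exactness must push the residual of true identities below 1e-6
  memo("probes_fine", spidr:::default_probes(n = 48L))
}

cached_library <- function(rank, parity, ...) {
  memo(paste0("lib", rank, parity), {
    fingerprint_dedup(generate_library(library_spec(rank, parity, ...)),
                      probes = cached_probes())
  })
}

# a single canonical raw term built from factor shorthand, for targeted tests
raw_term <- function(..., rank = 0L, parity = "even",
                     class = if (rank == 0L) "scalar" else "vector") {
  spidr:::make_term(list(spidr:::new_monomial(1, list(...))), rank, parity, class)
}

fac <- function(sym, dt = 0L, derivs = character(), comps = character()) {
  spidr:::new_factor(sym, dt = dt, derivs = derivs, comps = comps)
}

term_key <- function(term) term$key

library_labels <- function(lib) vapply(lib$terms, pretty_term, character(1))

find_term <- function(lib, label) {
  k <- which(library_labels(lib) == label)
  if (length(k) != 1L) stop("term not found: ", label)
  lib$terms[[k]]
}
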