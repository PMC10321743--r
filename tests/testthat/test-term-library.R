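# Symbolic term grammar: canonicalization, unit-director simplification,
# generation, parity/rotation properties and fingerprint deduplication.

test_that("canonicalization merges index-relabeled and reordered duplicates", {
  t1 <- raw_term(fac("u", comps = "a"), fac("n", derivs = "a", comps = "i"),
                 rank = 1L, parity = "odd", class = "vector")
  t2 <- raw_term(fac("n", derivs = "b", comps = "i"), fac("u", comps = "b"),
                 rank = 1L, parity = "odd", class = "vector")
  expect_identical(t1$key, t2$key)
  # distinct slot assignment stays distinct: d_i u_j vs d_j u_i (rank 2)
  s1 <- spidr:::make_term(list(spidr:::new_monomial(1, list(fac("u", derivs = "i", comps = "j")))),
                          2L, "even", "antisymmetric")
  s2 <- spidr:::make_term(list(spidr:::new_monomial(1, list(fac("u", derivs = "j", comps = "i")))),
                          2L, "even", "antisymmetric")
  expect_false(identical(s1$key, s2$key))
})

test_that("unit-director identities simplify as expected", {
  # n_a n_a -> 1
  t <- raw_term(fac("n", comps = "a"), fac("n", comps = "a"))
  expect_identical(t$key, "1*1")
  # n_a d_t n_a vanishes identically
  z <- spidr:::simplify_unit_director(
    spidr:::new_monomial(1, list(fac("n", comps = "a"), fac("n", dt = 1L, comps = "a"))))
  expect_null(z)
  # n_b d_b n_a u_a has no applicable rule
  t3 <- raw_term(fac("n", comps = "b"), fac("n", derivs = "b", comps = "a"),
                 fac("u", comps = "a"))
  expect_identical(length(t3$monomials), 1L)
  # second derivatives rewrite: n_a d_b d_b n_a = -(d_b n_c)(d_b n_c)
  t4 <- raw_term(fac("n", comps = "a"), fac("n", derivs = c("b", "b"), comps = "a"))
  expect_identical(length(t4$monomials), 1L)
  expect_identical(t4$monomials[[1]]$factors[[1]]$derivs, "a")
})

test_that("generated libraries contain the governing-equation terms", {
  lib0 <- cached_library(0L, "even")
  labs0 <- library_labels(lib0)
  expect_true("d_a u_a" %in% labs0)            # incompressibility
  expect_true("n_a n_b d_a u_b" %in% labs0)    # aligned strain (stress balance, scalar)
  expect_true("1" %in% labs0)                  # constant term
  expect_identical(sum(labs0 == "1"), 1L)
  lib1 <- cached_library(1L, "odd")
  labs1 <- library_labels(lib1)
  ref <- spidr:::director_equation_terms()
  keys1 <- vapply(lib1$terms, term_key, character(1))
  for (nm in c("dt", "adv", "gradA", "gradB", "nnAn", "divn")) {
    expect_true(ref[[nm]]$key %in% keys1, label = paste("missing", nm))
  }
  # Qbar, Abar and the (n A n) Qbar coupling of the stress balance, plus the
  # mixed Leslie coupling, are all generated by the raw grammar; the
  # deduplicated library may keep algebraically equivalent representatives
  # (in 2D the symmetrized Abar n (x) n projection equals Abar / 2, say)
  lib2raw <- memo("lib2raw", generate_library(library_spec(2L, "even")))
  keys2 <- vapply(lib2raw$terms, term_key, character(1))
  mk2 <- function(...) spidr:::project_term(spidr:::new_monomial(1, list(...)),
                                            library_spec(2L, "even"))
  qbar <- mk2(fac("n", comps = "i"), fac("n", comps = "j"))
  abar <- mk2(fac("u", derivs = "i", comps = "j"))
  nAnQ <- mk2(fac("u", derivs = "a", comps = "b"), fac("n", comps = "a"),
              fac("n", comps = "b"), fac("n", comps = "i"), fac("n", comps = "j"))
  leslie2 <- mk2(fac("u", derivs = "i", comps = "a"), fac("n", comps = "a"),
                 fac("n", comps = "j"))
  for (t in list(qbar, abar, nAnQ, leslie2)) expect_true(t$key %in% keys2)
})

test_that("library generation respects bounds and rejects blowups", {
  expect_error(generate_library(library_spec(0L, "even", max_factors = 8L,
                                             max_plain_n = 8L, max_plain_u = 8L,
                                             max_derived = 2L, max_deriv_multi = 2L)),
               "10\\^4")
  small <- generate_library(library_spec(1L, "odd", max_factors = 2L))
  full <- generate_library(library_spec(1L, "odd"))
  expect_lt(length(small$terms), length(full$terms))
  expect_true(all(vapply(small$terms, function(t)
    spidr:::mono_n_fields(t$monomials[[1]]) <= 2L, logical(1))))
})

test_that("even terms are invariant and odd terms flip under n -> -n", {
  probes <- cached_probes()
  p <- probes[[1]]
  pf <- p
  pf$n <- -pf$n
  ctx1 <- eval_context(p, backend = "spectral", align = FALSE)
  ctx2 <- eval_context(pf, backend = "spectral", align = FALSE)
  for (tm in cached_library(0L, "even")$terms[1:8]) {
    a <- term_component(ctx1, tm); b <- term_component(ctx2, tm)
    expect_equal(a, b, tolerance = 1e-12)
  }
  for (tm in cached_library(1L, "odd")$terms[1:8]) {
    a <- term_component(ctx1, tm, 1L); b <- term_component(ctx2, tm, 1L)
    expect_equal(a, -b, tolerance = 1e-12)
  }
})

test_that("vector terms are covariant under a quarter-turn rotation", {
  # rotate the probe by 90 degrees: (x, y) -> (-y, x), so the rotated field
  # at (x', y') samples the original at (y', -x'); on the periodic grid the
  # coordinate flip is index-exact
  p <- cached_probes()[[1]]
  d <- dim(p$u)[1:3]
  ri <- c(1L, d[1]:2L)  # 0-based negation mod n, in 1-based indexing
  rot_scal <- function(A) {
    B <- array(0, d)
    for (k in seq_len(d[3])) B[, , k] <- t(A[, ri, k])
    B
  }
  pr <- p
  pr$u <- array(0, dim(p$u))
  pr$u[, , , 1] <- rot_scal(-p$u[, , , 2])
  pr$u[, , , 2] <- rot_scal(p$u[, , , 1])
  pr$n <- array(0, dim(p$n))
  pr$n[, , , 1] <- rot_scal(-p$n[, , , 2])
  pr$n[, , , 2] <- rot_scal(p$n[, , , 1])
  ctx <- eval_context(p, backend = "spectral", align = FALSE)
  ctxr <- eval_context(pr, backend = "spectral", align = FALSE)
  for (tm in cached_library(1L, "odd")$terms[c(2, 4, 6)]) {
    v1 <- term_component(ctx, tm, 1L)
    v2 <- term_component(ctx, tm, 2L)
    w1 <- term_component(ctxr, tm, 1L)
    w2 <- term_component(ctxr, tm, 2L)
    expect_equal(w1, rot_scal(-v2), tolerance = 1e-8)
    expect_equal(w2, rot_scal(v1), tolerance = 1e-8)
  }
})

test_that("fingerprint deduplication removes dependent and zero terms", {
  # plant grad-u n, A n, Omega n: rank 2 family, one term removed
  mk1 <- function(...) spidr:::make_term(list(...), 1L, "odd", "vector")
  m_gradA <- spidr:::new_monomial(1, list(fac("u", derivs = "i", comps = "a"),
                                          fac("n", comps = "a")))
  m_gradB <- spidr:::new_monomial(1, list(fac("u", derivs = "a", comps = "i"),
                                          fac("n", comps = "a")))
  t_raw <- mk1(m_gradA)
  t_A <- mk1(spidr:::new_monomial(0.5, m_gradA$factors),
             spidr:::new_monomial(0.5, m_gradB$factors))
  t_Om <- mk1(spidr:::new_monomial(0.5, m_gradA$factors),
              spidr:::new_monomial(-0.5, m_gradB$factors))
  lib <- structure(list(spec = library_spec(1L, "odd"),
                        terms = list(t_raw, t_A, t_Om), removed = list()),
                   class = "term_library")
  dd <- fingerprint_dedup(lib, probes = cached_probes())
  expect_identical(length(dd$terms), 2L)
  expect_identical(length(dd$removed), 1L)
  # eps_ij n_i n_j is identically zero
  t_eps <- spidr:::make_term(list(spidr:::new_monomial(
    1, list(fac("eps", comps = c("a", "b")), fac("n", comps = "a"),
            fac("n", comps = "b")))), 0L, "even", "scalar")
  lib2 <- structure(list(spec = library_spec(0L, "even"),
                         terms = list(t_eps), removed = list()),
                    class = "term_library")
  dd2 <- fingerprint_dedup(lib2, probes = cached_probes())
  expect_identical(length(dd2$terms), 0L)
  expect_match(dd2$removed[[1]]$reason, "zero")
  # an independent set passes through unchanged
  lib3 <- cached_library(0L, "even")
  dd3 <- fingerprint_dedup(lib3, probes = cached_probes())
  expect_identical(length(dd3$terms), length(lib3$terms))
})

test_that("deduplicated libraries have full-rank fingerprints", {
  lib <- cached_library(1L, "odd")
  ctxs <- lapply(cached_probes(), eval_context, backend = "spectral", align = FALSE)
  idx <- round(seq(1, prod(ctxs[[1]]$dims), length.out = 100))
  M <- vapply(lib$terms, function(tm) {
    unlist(lapply(ctxs, function(ctx) {
      c(term_component(ctx, tm, 1L)[idx], term_component(ctx, tm, 2L)[idx])
    }))
  }, numeric(600))
  M <- sweep(M, 2, sqrt(colSums(M^2)), `/`)
  expect_gt(min(svd(M)$d), 1e-6)
})

test_that("libraries round-trip through JSON", {
  lib <- cached_library(0L, "even")
  path <- tempfile(fileext = ".json")
  write_library_json(lib, path)
  back <- read_library_json(path)
  expect_identical(vapply(back$terms, term_key, character(1)),
                   vapply(lib$terms, term_key, character(1)))
  ctx <- eval_context(cached_probes()[[1]], backend = "spectral", align = FALSE)
  expect_equal(term_component(ctx, back$terms[[5]]),
               term_component(ctx, lib$terms[[5]]), tolerance = 1e-12)
})

test_that("terms render in readable index notation", {
  lib <- cached_library(0L, "even")
  expect_true("d_a u_a" %in% library_labels(lib))
  rel <- spidr:::new_relation(find_term(lib, "d_a u_a")$key, 1, 0.01, "single")
  expect_match(render_relation(rel, lib), "d_a u_a")
  expect_match(render_relation(rel, lib), "= 0")
})
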