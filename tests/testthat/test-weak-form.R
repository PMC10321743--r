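# Weight functions, subdomain sampling, integration by parts and the
# feature matrix.

test_that("subdomain sampling is seeded, admissible and uniform", {
  g <- field_grid(64, 64, 64, 0.1, 0.1, 0.1)
  s1 <- sample_subdomains(g, 50, c(16L, 16L, 16L), seed = 9L)
  s2 <- sample_subdomains(g, 50, c(16L, 16L, 16L), seed = 9L)
  s3 <- sample_subdomains(g, 50, c(16L, 16L, 16L), seed = 10L)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  starts <- t(vapply(s1, function(s) s$start, integer(3)))
  expect_true(all(starts >= 1L & starts <= 64L - 16L + 1L))
  # barely fitting placement is forced
  s4 <- sample_subdomains(g, 3, c(64L, 64L, 64L), seed = 1L)
  expect_true(all(vapply(s4, function(s) all(s$start == 1L), logical(1))))
  expect_error(sample_subdomains(g, 3, c(80L, 16L, 16L)), "exceed")
  # uniformity of centers over admissible starts
  s5 <- sample_subdomains(g, 2000, c(16L, 16L, 16L), seed = 4L)
  x <- vapply(s5, function(s) s$start[1], integer(1))
  p <- chisq.test(tabulate(x, 49))$p.value
  expect_gt(p, 0.01)
})

test_that("the envelope vanishes with its derivatives at the boundary", {
  g <- field_grid(33, 33, 33, 0.1, 0.1, 0.1)
  sub <- list(start = c(1L, 1L, 1L), extent = c(33L, 33L, 33L))
  w <- make_weight(sub, g, tau = 4)
  w0 <- w$array(c(0L, 0L, 0L))
  expect_equal(w0[17, 17, 17], 1)  # center value
  expect_true(all(abs(w0[1, , ]) < 1e-14))
  for (alpha in list(c(1L,0L,0L), c(2L,0L,0L), c(1L,1L,0L), c(0L,0L,1L))) {
    wa <- w$array(alpha)
    expect_lt(max(abs(wa[1, , ])), 1e-10)
    expect_lt(max(abs(wa[33, , ])), 1e-10)
  }
  expect_true(all(w0 >= 0 & w0 <= 1))
})

test_that("the tau = 4 envelope integrates to (256/315)^3 over the cube", {
  n <- 55L
  g <- field_grid(n, n, n, 2 / (n - 1), 2 / (n - 1), 2 / (n - 1))
  sub <- list(start = c(1L, 1L, 1L), extent = c(n, n, n))
  w <- make_weight(sub, g, tau = 4)
  I <- sum(w$wq(c(0L, 0L, 0L)))
  expect_equal(I, (256 / 315)^3, tolerance = 1e-4)
})

test_that("a mask of zero kills the weight", {
  g <- field_grid(16, 16, 16, 0.1, 0.1, 0.1)
  sub <- list(start = c(1L, 1L, 1L), extent = c(16L, 16L, 16L))
  w <- make_weight(sub, g, mask = array(0, c(16, 16, 16)))
  expect_equal(max(abs(w$array(c(0L, 0L, 0L)))), 0)
})

test_that("derivative transfer moves single-factor derivatives onto the weight", {
  lib <- cached_library(1L, "odd")
  plan_dt <- transfer_derivatives(find_term(lib, "d_t n_i"))
  expect_true(plan_dt[[1]]$transfer)
  expect_identical(plan_dt[[1]]$sign, -1)
  lib0 <- cached_library(0L, "even")
  plan_div <- transfer_derivatives(find_term(lib0, "d_a u_a"))
  expect_true(plan_div[[1]]$transfer)
  # derivative locked inside a product stays on the data
  plan_adv <- transfer_derivatives(find_term(lib, "d_a n_i u_a"))
  expect_false(plan_adv[[1]]$transfer)
  # a transfer deeper than the envelope smoothness is refused
  expect_error(transfer_derivatives(find_term(lib, "d_t n_i"), tau = 1),
               "tau")
})

test_that("transferred and direct integrals agree on analytic fields", {
  n <- 48L
  g <- field_grid(n, n, n, 2 * pi / n, 2 * pi / n, 2 * pi / n)
  p <- random_smooth_fields(g, cutoff = 2L, seed = 5, theta_amp = 0.3)
  ctx <- eval_context(p, backend = "spectral", align = FALSE)
  sub <- list(start = c(1L, 1L, 1L), extent = c(n, n, n))
  w <- make_weight(sub, g, tau = 4, modulation = 2L, phase = 0.7)
  lib <- cached_library(1L, "odd")
  tdt <- find_term(lib, "d_t n_i")
  v_tr <- integrate_term(tdt, w, ctx, comp = 1L, transfer = TRUE)
  v_di <- integrate_term(tdt, w, ctx, comp = 1L, transfer = FALSE)
  expect_equal(v_tr, v_di, tolerance = 2e-5)
  lib0 <- cached_library(0L, "even")
  tdiv <- find_term(lib0, "d_a u_a")
  v_tr2 <- integrate_term(tdiv, w, ctx, transfer = TRUE)
  v_di2 <- integrate_term(tdiv, w, ctx, transfer = FALSE)
  expect_equal(v_tr2, v_di2, tolerance = 2e-5)
})

test_that("an odd modulation phase annihilates an even integrand", {
  n <- 33L
  g <- field_grid(n, n, 9L, 2 / (n - 1), 2 / (n - 1), 0.1)
  sub <- list(start = c(1L, 1L, 1L), extent = c(n, n, 9L))
  # integrand 1 (constant term) against cos(pi x - pi/2) = sin(pi x): odd in x
  w <- make_weight(sub, g, tau = 4, modulation = 1L, phase = pi / 2)
  expect_lt(abs(sum(w$wq(c(0L, 0L, 0L)))), 1e-12)
})

test_that("trapezoid quadrature of the weak integrand converges at order 2", {
  # the envelope makes pure-envelope integrals superalgebraic, so probe the
  # order with a rough (|x|-type) integrand instead
  ref <- integrate(function(t) abs(t) * (1 - t^2)^4, -1, 1, rel.tol = 1e-12)$value
  err <- vapply(c(17L, 33L, 65L), function(n) {
    h <- 2 / (n - 1)
    x <- seq(-1, 1, length.out = n)
    f <- abs(x) * (1 - x^2)^4  # kink at 0 limits trapezoid to O(h^2)
    abs(sum(spidr:::trapz_weights(n, h) * f) - ref)
  }, numeric(1))
  expect_gt(err[1] / err[2], 3.4)
  expect_lt(err[1] / err[2], 4.6)
  expect_gt(err[2] / err[3], 3.4)
})

test_that("feature matrix bookkeeping matches its configuration", {
  fx <- make_fixture("incompressibility", n = 24L)
  nd <- nondimensionalize(fx$fields)
  lib <- cached_library(0L, "even")
  fm <- build_feature_matrix(lib, nd$fields, count = 12L, extents = c(12L, 12L, 12L),
                             seed = 2L)
  expect_identical(nrow(fm$G), 12L * 4L)  # count x weights x 1 scalar component
  expect_identical(ncol(fm$G), length(lib$terms))
  expect_true(all(is.finite(fm$G)))
  lib1 <- cached_library(1L, "odd")
  fm1 <- build_feature_matrix(lib1, nd$fields, count = 6L, extents = c(12L, 12L, 12L),
                              seed = 2L)
  expect_identical(nrow(fm1$G), 6L * 4L * 2L)  # two vector components
})

test_that("the divergence column is tiny on a divergence-free flow", {
  fx <- make_fixture("incompressibility", n = 32L)
  nd <- nondimensionalize(fx$fields)
  lib <- cached_library(0L, "even")
  fm <- build_feature_matrix(lib, nd$fields, seed = 2L)
  k <- which(library_labels(lib) == "d_a u_a")
  eta1 <- sqrt(sum(fm$G[, k]^2)) / fm$Xi[k]
  expect_lt(eta1, 0.01)
  others <- sqrt(colSums(fm$G^2)) / fm$Xi
  expect_gt(stats::median(others, na.rm = TRUE), 0.1)
})

test_that("weak-form rows are invariant under arbitrary director sign flips", {
  fx <- make_fixture("director-dynamics", n = 24L)
  nd <- nondimensionalize(fx$fields)
  flip <- fx$fields
  set.seed(8)
  s <- array(sample(c(-1, 1), 24^3, replace = TRUE), c(24, 24, 24))
  nf <- nd$fields$n
  nf[, , , 1] <- nf[, , , 1] * s
  nf[, , , 2] <- nf[, , , 2] * s
  flipped <- field_sequence(nd$fields$grid, nd$fields$u, nf, nd$fields$phi)
  lib <- cached_library(1L, "odd")
  sub <- lib
  sub$terms <- lib$terms[1:6]
  fm1 <- build_feature_matrix(sub, nd$fields, count = 4L, extents = c(12L, 12L, 12L), seed = 5L)
  fm2 <- build_feature_matrix(sub, flipped, count = 4L, extents = c(12L, 12L, 12L), seed = 5L)
  expect_equal(fm1$G, fm2$G, tolerance = 1e-10)
})

test_that("the weak form keeps a planted relation visible under heavy noise", {
  fx <- make_fixture("incompressibility", n = 48L, noise = 0.5, seed = 21L)
  pre <- preprocess_fields(fx$fields, run_config(use_mask = FALSE))
  lib <- cached_library(0L, "even")
  fm <- build_feature_matrix(lib, pre$fields, seed = 2L)
  k <- which(library_labels(lib) == "d_a u_a")
  eta_weak <- sqrt(sum(fm$G[, k]^2)) / fm$Xi[k]
  expect_lt(eta_weak, 0.1)
  # pointwise strong form on the raw noisy data drowns against the clean scale
  clean <- make_fixture("incompressibility", n = 48L)
  df_noisy <- derived_fields(fx$fields)
  df_clean <- derived_fields(clean$fields)
  strong <- sqrt(mean(df_noisy$div^2)) /
    sqrt(mean(df_clean$gradu^2))
  expect_gt(strong, 1)
})
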