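# Synthetic generators: stream-function flows, planted director dynamics,
# defects, probes and noise.

test_that("extensional flow matches its closed form and is divergence-free", {
  g <- field_grid(17, 17, 5, 0.1, 0.1, 0.1)
  fs <- extensional_flow(g, 0.5)
  co <- grid_coords(g)
  x <- co$x - mean(co$x)
  expect_equal(fs$u[, 9, 1, 1], 0.5 * x, tolerance = 1e-12)
  expect_equal(fs$u[9, , 1, 2], -0.5 * x, tolerance = 1e-12)
  df <- derived_fields(fs)
  expect_lt(max(abs(df$div)), 1e-12)
  # Qbar : Abar = E pointwise for n = x hat
  tr <- df$Qbar[, , , 1, 1] * df$Abar[, , , 1, 1] + df$Qbar[, , , 2, 2] * df$Abar[, , , 2, 2] +
    2 * df$Qbar[, , , 1, 2] * df$Abar[, , , 1, 2]
  expect_equal(tr, array(0.5, c(17, 17, 5)), tolerance = 1e-10)
  # polynomial mean flow stays exactly divergence-free
  fs2 <- extensional_flow(g, 0.5, f = c(0, 0, 0, 0.1), g = c(0, 1, 0, 0.2))
  expect_lt(max(abs(derived_fields(fs2)$div)), 1e-10)
  # zero rate, zero mean flow: no flow
  fs3 <- extensional_flow(g, 0)
  expect_equal(max(abs(fs3$u)), 0)
})

test_that("cellular flow is a divergence-free vortex lattice with peak speed a", {
  g <- default_fixture_grid(32L)
  u <- cellular_flow(0.8, 2, g)
  nn <- array(0, c(32, 32, 32, 2)); nn[, , , 1] <- 1
  fs <- field_sequence(g, u, nn)
  df <- derived_fields(fs)
  # stencil divergence vanishes identically for the single-mode lattice
  expect_lt(max(abs(df$div[2:31, 2:31, ])), 1e-12)
  expect_equal(max(sqrt(u[, , , 1]^2 + u[, , , 2]^2)), 0.8, tolerance = 1e-10)
  # both strain and rotation are exercised
  expect_gt(max(abs(df$Omega[, , , 1, 2])), 0.5)
  expect_gt(max(abs(df$Abar)), 0.5)
})

test_that("director dynamics preserve planted structure", {
  g <- default_fixture_grid(24L)
  # zero flow: the director is frozen
  u0 <- array(0, c(24, 24, 24, 2))
  th0 <- matrix(0.3, 24, 24)
  fs <- director_dynamics(u0, th0, c(1, -1, -1), g)
  expect_equal(fs$n[, , 24, ], fs$n[, , 1, ], tolerance = 1e-12)
  # CFL guard
  expect_error(director_dynamics(u0 + 50, th0, c(1, -1, -1), g), "CFL")
})

test_that("a vortex core rotates the director at the planted rate", {
  # at the stagnation point of a cellular vortex the strain vanishes and
  # the angle obeys the closed scalar ODE d theta / dt = c2 * Omega_xy,
  # with Omega_xy = a at the core: an analytically solvable reduction
  n <- 48L
  a <- 0.8
  g <- default_fixture_grid(n, umax = a)
  u <- cellular_flow(a, 1, g)
  th0 <- matrix(0.2, n, n)
  coef <- c(1, -1, -1)
  fs <- director_dynamics(u, th0, coef, g, substeps = 2L)
  ic <- n %/% 4L + 1L  # grid point at (pi/2, pi/2): the vortex core
  expect_lt(max(abs(u[ic, ic, , ])), 1e-14)
  t_end <- (n - 1) * g$dt
  th_end <- atan2(fs$n[ic, ic, n, 2], fs$n[ic, ic, n, 1])
  expect_equal(th_end, 0.2 + coef[2] * a * t_end, tolerance = 1e-4)
})

test_that("extensional flow with aligned director is a fixed point of the dynamics", {
  # Pperp Abar n = 0 and Omega = 0 for n = x hat in pure extension
  n <- 32L
  g <- field_grid(n, n, n, 6 / n, 6 / n, 0.02)
  fx <- extensional_flow(g, 0.4)
  fs <- director_dynamics(fx$u, matrix(0, n, n), c(1, -1, -1), g)
  expect_equal(max(abs(fs$n[, , , 2])), 0, tolerance = 1e-8)
})

test_that("defect directors wind correctly and diverge at the core", {
  g <- field_grid(64, 64, 5, 0.1, 0.1, 0.1)
  for (m in c(0.5, -0.5)) {
    dd <- defect_director(m, c(3.2, 3.2), g)
    # winding of the director angle around a loop enclosing the core
    ij <- cbind(c(53:12, rep(12, 41), 12:53, rep(53, 41)),
                c(rep(12, 42), 12:52, rep(53, 42), 52:12))
    th <- atan2(dd$n[, , 1, 2], dd$n[, , 1, 1])[ij]
    dth <- diff(th)
    dth <- dth - round(dth / pi) * pi  # director angle is defined mod pi
    expect_equal(sum(dth), -m * 2 * pi, tolerance = 1e-6)
    # Q tensor is single-valued on the loop
    q1 <- (dd$n[, , 1, 1]^2 - 0.5)[ij]
    expect_lt(max(abs(q1 - (0.5 * cos(2 * th)))), 1e-10)
  }
  expect_error(defect_director(1, c(0, 0), g), "1/2")
  # |grad n| = |m| / r within 5% away from the core
  dd <- defect_director(0.5, c(3.2, 3.2), g)
  nn <- dd$n
  gn <- array(0, c(64, 64, 5))
  for (ax in 1:2) {
    d <- director_diff(nn, ax, 0.1)
    gn <- gn + d[, , , 1]^2 + d[, , , 2]^2
  }
  gn <- sqrt(gn)
  ic <- 33L  # core cell
  for (off in c(8L, 12L, 16L)) {
    r <- off * 0.1
    expect_equal(gn[ic + off, ic, 3], 0.5 / r, tolerance = 0.05)
  }
})

test_that("random smooth probes are reproducible, band-limited and compressible", {
  g <- periodic_grid(24L)
  p1 <- random_smooth_fields(g, cutoff = 3L, seed = 4L)
  p2 <- random_smooth_fields(g, cutoff = 3L, seed = 4L)
  p3 <- random_smooth_fields(g, cutoff = 3L, seed = 5L)
  expect_identical(p1$u, p2$u)
  expect_false(identical(p1$u, p3$u))
  # no spectral content above the cutoff
  sp <- abs(fft(p1$u[, , 1, 1]))
  idx <- c(5:21)  # modes 4..: beyond cutoff 3 (1-based FFT bins)
  expect_lt(max(sp[idx, 1]) / max(sp), 1e-12)
  # generically compressible: physical relations fail on probes
  df <- derived_fields(p1)
  expect_gt(sqrt(mean(df$div^2)) / sqrt(mean(df$gradu^2)), 0.1)
  expect_error(random_smooth_fields(g, cutoff = 12L), "Nyquist")
})

test_that("noise injection is calibrated and preserves unit directors", {
  fx <- make_fixture("incompressibility", n = 24L)
  same <- add_noise(fx$fields, 0, seed = 1L)
  expect_identical(same$u, fx$fields$u)
  noisy <- add_noise(fx$fields, 0.2, seed = 6L)
  added <- noisy$u[, , , 1] - fx$fields$u[, , , 1]
  expect_equal(sd(as.vector(added)), 0.2 * sqrt(mean(fx$fields$u[, , , 1]^2)),
               tolerance = 0.05)
  len <- sqrt(noisy$n[, , , 1]^2 + noisy$n[, , , 2]^2)
  expect_equal(max(abs(len - 1)), 0, tolerance = 1e-12)
  expect_error(add_noise(fx$fields, -0.1), "nonnegative")
})

test_that("fixtures are registered, reproducible and self-consistent", {
  expect_error(make_fixture("unknown"), "registered fixtures")
  f1 <- make_fixture("director-dynamics", n = 16L, noise = 0.1, seed = 3L)
  f2 <- make_fixture("director-dynamics", n = 16L, noise = 0.1, seed = 3L)
  expect_identical(f1$fields$n, f2$fields$n)
  expect_identical(f1$truth$coef, c(1, -1, -1))
  f3 <- make_fixture("stress-balance", n = 16L)
  expect_identical(f3$truth$E, 0.56)
})

test_that("each fixture satisfies its ground truth in weak form at zero noise", {
  # incompressibility fixture: div u
  fx <- make_fixture("incompressibility", n = 32L)
  nd <- nondimensionalize(fx$fields)
  lib0 <- cached_library(0L, "even")
  fm <- build_feature_matrix(lib0, nd$fields, count = 10L, seed = 4L)
  k <- which(library_labels(lib0) == "d_a u_a")
  expect_lt(sqrt(sum(fm$G[, k]^2)) / fm$Xi[k], 1e-3)
  # stress balance: Qbar : Abar + c = 0
  fs <- make_fixture("stress-balance", n = 32L)
  nd2 <- nondimensionalize(fs$fields)
  kA <- which(library_labels(lib0) == "n_a n_b d_a u_b")
  k1 <- which(library_labels(lib0) == "1")
  fm2 <- build_feature_matrix(lib0, nd2$fields, count = 10L, seed = 4L)
  Gs <- fm2$G[, c(kA, k1)]
  c_ <- spidr:::msv_scaled(Gs)
  expect_lt(residual_eta(Gs, c_, "multi"), 1e-3)
  # director dynamics: the planted support solves the weak system
  fd <- make_fixture("director-dynamics", n = 32L)
  nd3 <- nondimensionalize(fd$fields)
  ref <- spidr:::director_equation_terms()
  lib1 <- generate_library(library_spec(1L, "odd"))
  lib1$terms <- ref[c("dt", "adv", "gradA", "nnAn")]
  fm3 <- build_feature_matrix(lib1, nd3$fields, count = 10L, seed = 4L)
  c3 <- spidr:::msv_scaled(fm3$G)
  expect_lt(residual_eta(fm3$G, c3, "multi"), 2e-2)
})
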