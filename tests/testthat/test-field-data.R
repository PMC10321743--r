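# Field containers, director calculus, nondimensionalization, masking,
# structure-tensor extraction and CSV round-trips.

make_uniform_fields <- function(n = 8L, ux = 0.3, uy = -0.1, theta = 0.4) {
  g <- field_grid(n, n, n, 0.2, 0.2, 0.1)
  u <- array(0, c(n, n, n, 2)); u[, , , 1] <- ux; u[, , , 2] <- uy
  nn <- array(0, c(n, n, n, 2))
  nn[, , , 1] <- cos(theta); nn[, , , 2] <- sin(theta)
  field_sequence(g, u, nn)
}

test_that("field containers validate their invariants", {
  expect_error(field_grid(3, 8, 8, 0.1, 0.1, 0.1), "at least 5")
  expect_error(field_grid(8, 8, 8, -0.1, 0.1, 0.1), "positive")
  fs <- make_uniform_fields()
  bad_n <- fs$n * 2
  expect_error(field_sequence(fs$grid, fs$u, bad_n), "unit length")
  bad_u <- fs$u; bad_u[1, 1, 1, 1] <- NA
  expect_error(field_sequence(fs$grid, bad_u, fs$n), "finite")
})

test_that("director differentiation is blind to stored signs", {
  g <- field_grid(16, 16, 6, 0.3, 0.3, 0.2)
  co <- grid_coords(g)
  k <- 0.8
  th <- array(rep(k * co$x, times = 16 * 6), c(16, 16, 6))
  n <- array(0, c(16, 16, 6, 2))
  n[, , , 1] <- cos(th); n[, , , 2] <- sin(th)
  set.seed(3)
  flip <- array(sample(c(-1, 1), 16 * 16 * 6, replace = TRUE), c(16, 16, 6))
  nf <- n
  nf[, , , 1] <- n[, , , 1] * flip; nf[, , , 2] <- n[, , , 2] * flip
  d1 <- director_diff(n, 1L, g$dx)
  d2 <- director_diff(nf, 1L, g$dx)
  # |dn/dx| = |d theta/dx| = k for a rotating director, regardless of signs
  mag1 <- sqrt(d1[, , , 1]^2 + d1[, , , 2]^2)
  mag2 <- sqrt(d2[, , , 1]^2 + d2[, , , 2]^2)
  expect_equal(mag2, mag1, tolerance = 1e-12)
  expect_equal(max(abs(mag1[2:15, , ] - k)), 0, tolerance = k * 0.01)
  expect_equal(max(abs(mag1 - k)), 0, tolerance = k * 0.03)  # one-sided edges
  # uniform director stored with random signs differentiates to zero
  nu <- array(0, c(16, 16, 6, 2))
  nu[, , , 1] <- flip  # +-x direction
  expect_equal(max(abs(director_diff(nu, 2L, g$dy))), 0, tolerance = 1e-14)
})

test_that("derived fields satisfy their algebraic identities", {
  fx <- make_fixture("incompressibility", n = 16L)
  df <- derived_fields(fx$fields)
  expect_equal(df$Qbar[, , , 1, 1] + df$Qbar[, , , 2, 2],
               array(0, dim(df$div)), tolerance = 1e-12)
  expect_equal(df$A + df$Omega, df$gradu, tolerance = 1e-12)
  expect_equal(df$Abar[, , , 1, 1] + df$Abar[, , , 2, 2],
               array(0, dim(df$div)), tolerance = 1e-12)
  # Pperp annihilates n
  n <- fx$fields$n
  for (i in 1:2) {
    pn <- df$Pperp[, , , i, 1] * n[, , , 1] + df$Pperp[, , , i, 2] * n[, , , 2]
    expect_lt(max(abs(pn)), 1e-12)
  }
  expect_equal(df$omega, -2 * df$Omega[, , , 1, 2], tolerance = 1e-14)
})

test_that("derived fields reproduce closed forms on the extensional flow", {
  g <- field_grid(17, 17, 5, 0.1, 0.1, 0.1)
  fs <- extensional_flow(g, 0.5)
  df <- derived_fields(fs)
  expect_equal(df$Abar[, , , 1, 1], array(0.5, c(17, 17, 5)), tolerance = 1e-10)
  expect_equal(df$Abar[, , , 2, 2], array(-0.5, c(17, 17, 5)), tolerance = 1e-10)
  expect_lt(max(abs(df$div)), 1e-12)
  expect_lt(max(abs(df$Omega)), 1e-12)
  # n = x hat: Qbar = diag(1/2, -1/2)
  expect_equal(df$Qbar[, , , 1, 1], array(0.5, c(17, 17, 5)))
  expect_equal(df$Qbar[, , , 1, 2], array(0, c(17, 17, 5)))
})

test_that("nondimensionalization enforces unit mean speed and vorticity", {
  # shear flow u = (k y, 0): brute-force the expected scales
  n <- 24L
  g <- field_grid(n, n, 6L, 0.5, 0.5, 0.3)
  co <- grid_coords(g)
  k <- 0.7
  u <- array(0, c(n, n, 6, 2))
  u[, , , 1] <- aperm(array(rep(k * co$y, n * 6), c(n, n, 6)), c(2, 1, 3))
  nn <- array(0, c(n, n, 6, 2)); nn[, , , 1] <- 1
  fs <- field_sequence(g, u, nn)
  mean_speed <- mean(abs(k * co$y))
  mean_vort <- k  # omega = d_y u_x - d_x u_y = k exactly
  nd <- nondimensionalize(fs)
  expect_equal(nd$scales$time, 1 / mean_vort, tolerance = 1e-10)
  expect_equal(nd$scales$length, mean_speed / mean_vort, tolerance = 1e-10)
  df <- derived_fields(nd$fields)
  speed <- sqrt(nd$fields$u[, , , 1]^2 + nd$fields$u[, , , 2]^2)
  expect_equal(mean(speed), 1, tolerance = 1e-10)
  expect_equal(mean(abs(df$omega)), 1, tolerance = 1e-10)
  # second call is the identity transform
  nd2 <- nondimensionalize(nd$fields)
  expect_equal(nd2$scales$length, 1, tolerance = 1e-10)
  expect_equal(nd2$scales$time, 1, tolerance = 1e-10)
})

test_that("nondimensionalization rejects degenerate fields", {
  fs <- make_uniform_fields(ux = 0, uy = 0)
  expect_error(nondimensionalize(fs), "degenerate field")
})

test_that("the mask excludes an intensity hole and relaxes to one far away", {
  n <- 64L
  g <- field_grid(n, n, 5L, 0.1, 0.1, 0.1)
  co <- grid_coords(g)
  ic <- n %/% 2L
  r <- sqrt(outer((co$x - co$x[ic])^2, (co$y - co$y[ic])^2, `+`))
  phi <- array(rep(as.numeric(r > 12 * g$dx), 5), c(n, n, 5))
  nn <- array(0, c(n, n, 5, 2)); nn[, , , 1] <- 1
  m <- build_mask(phi, nn, g)
  expect_true(all(m$psi >= 0 & m$psi <= 1))
  expect_lt(m$psi[ic, ic, 3], 0.05)
  expect_gt(m$psi[3, 3, 3], 0.99)
  # transition monotone along a ray from the center out (edge cells excluded:
  # the truncated box kernel renormalizes there)
  ray <- m$psi[ic:(n - 6L), ic, 3]
  expect_true(all(diff(ray) >= -1e-9))
  # uniform bright data keep a unit mask
  fs <- make_uniform_fields(12L)
  m2 <- build_mask(fs$phi, fs$n, fs$grid)
  expect_equal(m2$psi, array(1, c(12, 12, 12)))
  expect_error(build_mask(fs$phi, fs$n, fs$grid, intensity_frac = -1), "positive")
})

test_that("a defect core is masked even at full intensity", {
  # director gradient diverges like |m|/r at the core, so the gradient
  # threshold trips there even when the image is uniformly bright
  g <- field_grid(48, 48, 5, 0.2, 0.2, 0.2)
  dd <- defect_director(0.5, c(4.8, 4.8), g)
  phi <- array(1, c(48, 48, 5))
  m <- build_mask(phi, dd$n, g, passes = 3L)
  ic <- round(4.8 / 0.2) + 1L
  expect_lt(min(m$psi[(ic - 1):(ic + 1), (ic - 1):(ic + 1), 3]), 0.8)
  expect_gt(m$psi[4, 4, 3], 0.95)
})

test_that("structure-tensor extraction recovers stripe orientation", {
  n <- 48L
  x <- (0:(n - 1))
  stack <- array(0.5 + 0.5 * cos(2 * pi * 4 * x / n), c(n, n, 2))
  ex <- extract_director(stack)
  # stripes varying along x: least variation along y, director = +-y hat
  mid <- 10:38
  expect_lt(max(abs(ex$n[mid, mid, 1, 1])), 0.05)
  expect_true(all(abs(ex$n[mid, mid, 1, 2]) > 0.99))
  expect_true(all(ex$valid[mid, mid, ]))
  # constant image: isotropic tensor everywhere, all flagged invalid
  ex0 <- extract_director(array(0.5, c(16, 16, 2)))
  expect_false(any(ex0$valid))
})

test_that("45-degree stripes give a 45-degree director within 2 degrees", {
  n <- 48L
  xy <- outer(0:(n - 1), 0:(n - 1), `+`)
  stack <- array(rep(0.5 + 0.5 * cos(2 * pi * 4 * xy / n), 2), c(n, n, 2))
  ex <- extract_director(stack)
  mid <- 15:34
  ang <- atan2(ex$n[mid, mid, 1, 2], ex$n[mid, mid, 1, 1]) * 180 / pi
  ang <- (ang + 180) %% 180  # nematic: fold to [0, 180)
  expect_true(all(abs(ang - 135) < 2))
})

test_that("field sequences round-trip through long-format CSV", {
  fx <- make_fixture("incompressibility", n = 8L)
  path <- tempfile(fileext = ".csv")
  write_field_csv(fx$fields, path)
  back <- read_field_csv(path)
  expect_equal(back$u, fx$fields$u, tolerance = 1e-10)
  expect_equal(abs(back$n[, , , 1]), abs(fx$fields$n[, , , 1]), tolerance = 1e-10)
  expect_equal(back$grid$dx, fx$fields$grid$dx, tolerance = 1e-10)
  expect_error(read_field_csv(tempfile()), "not found")
})
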