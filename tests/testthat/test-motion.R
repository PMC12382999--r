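# Motion decoupling: polynomial fits, displacement recovery, polar transform,
# adaptive thresholds and trinary filtering.

test_that("fit_polynomial recovers constant, linear and quadratic structure", {
  cst <- fit_polynomial(matrix(0.5, 9, 9), 5L)
  expect_equal(max(abs(cst$axx)), 0, tolerance = 1e-10)
  expect_equal(max(abs(cst$bx)), 0, tolerance = 1e-10)
  expect_equal(cst$c[5, 5], 0.5, tolerance = 1e-12)

  w <- 16L
  ramp <- matrix(rep((0:(w - 1)) / w, each = 9), 9, w, byrow = FALSE)
  ramp <- outer(rep(1, 9), (0:(w - 1)) / w)
  fr <- fit_polynomial(ramp, 5L)
  expect_equal(fr$bx[5, 8], 1 / w, tolerance = 1e-10)
  expect_equal(fr$by[5, 8], 0, tolerance = 1e-10)
  expect_equal(fr$c[5, 8], ramp[5, 8], tolerance = 1e-10)
  expect_equal(max(abs(interior(fr$axx, 3L))), 0, tolerance = 1e-9)

  # quadratic: oracle = direct weighted normal equations on one 5x5 window
  img <- outer(0:6, 0:6, function(y, x) x^2)
  ft <- fit_polynomial(img, 5L)
  u <- -2:2
  wts <- spacemot:::poly_gaussian_weights(5L)
  W2 <- outer(wts, wts)
  G <- matrix(0, 6, 6); rhs <- numeric(6)
  for (vi in 1:5) for (ui in 1:5) {
    g <- c(1, u[ui], u[vi], u[ui]^2, u[vi]^2, u[ui] * u[vi])
    G <- G + W2[vi, ui] * tcrossprod(g)
    rhs <- rhs + W2[vi, ui] * g * img[4 + u[vi], 4 + u[ui]]
  }
  q <- solve(G, rhs)
  expect_equal(ft$axx[4, 4], 2 * q[4], tolerance = 1e-9)
  expect_equal(ft$axx[4, 4], 2, tolerance = 1e-9)
  expect_equal(ft$bx[4, 4], q[2], tolerance = 1e-9)
})

test_that("fit_polynomial validates its window", {
  expect_error(fit_polynomial(matrix(0, 8, 8), 4L), "odd")
  expect_error(fit_polynomial(matrix(0, 8, 8), 9L), "exceeds")
  expect_error(fit_polynomial(matrix(c(NA, rep(0, 63)), 8, 8), 5L), "finite")
})

test_that("estimate_displacement recovers known shifts", {
  h <- 64L; w <- 64L
  f0 <- analytic_texture(h, w)
  # zero motion
  d0 <- estimate_displacement(f0, f0)
  expect_equal(max(abs(d0$dx)), 0, tolerance = 1e-8)
  expect_equal(max(abs(d0$dy)), 0, tolerance = 1e-8)
  # integer and half-pixel shifts (displacement = -shift of the sample grid)
  for (sh in list(c(1, 0), c(0.5, -0.5), c(-2, 2))) {
    d <- estimate_displacement(f0, analytic_texture(h, w, sh[1], sh[2]))
    expect_lt(abs(median(interior(d$dx)) + sh[1]), 0.25)
    expect_lt(abs(median(interior(d$dy)) + sh[2]), 0.25)
  }
  expect_error(estimate_displacement(f0, f0[, 1:32]), "shape")
})

test_that("to_polar is exact and round-trips", {
  f <- structure(list(dx = matrix(c(3, 0, -1, 2), 2),
                      dy = matrix(c(4, 0, 0, -7), 2)),
                 class = "displacement_field")
  p <- to_polar(f)
  expect_equal(p$rho[1, 1], 5)
  expect_equal(p$theta[1, 1], atan2(4, 3))
  expect_equal(p$rho[2, 1], 0)
  expect_identical(p$theta[2, 1], 0)          # convention at rho = 0
  expect_equal(p$theta[1, 2], pi)
  # property: round trip to machine precision on random fields
  set.seed(11)
  for (i in 1:5) {
    fd <- list(dx = matrix(rnorm(100), 10), dy = matrix(rnorm(100), 10))
    pp <- to_polar(fd)
    expect_equal(pp$rho * cos(pp$theta), fd$dx, tolerance = 1e-12)
    expect_equal(pp$rho * sin(pp$theta), fd$dy, tolerance = 1e-12)
  }
})

test_that("local_statistics computes windowed mean and population sd", {
  u <- list(rho = matrix(2, 20, 20))
  s <- local_statistics(u, 5L)
  expect_equal(s$mu, matrix(2, 20, 20), tolerance = 1e-12)
  expect_equal(s$sigma, matrix(0, 20, 20), tolerance = 1e-12)

  cb <- list(rho = outer(1:20, 1:20, function(i, j) 2 * ((i + j) %% 2)))
  s2 <- local_statistics(cb, 5L)
  # a full 5x5 window holds 13 of one value and 12 of the other
  i <- 10; j <- 11
  vals <- as.vector(cb$rho[(i - 2):(i + 2), (j - 2):(j + 2)])
  expect_equal(s2$mu[i, j], mean(vals), tolerance = 1e-12)
  expect_equal(s2$sigma[i, j], sqrt(mean((vals - mean(vals))^2)),
               tolerance = 1e-12)

  sp <- list(rho = { m <- matrix(0, 15, 15); m[8, 8] <- 3; m })
  s3 <- local_statistics(sp, 5L)
  expect_equal(s3$mu[8, 8], 3 / 25, tolerance = 1e-12)
  expect_error(local_statistics(sp, 17L), "exceeds")
})

test_that("adaptive thresholds and trinary classification follow the rules", {
  maps <- adaptive_thresholds(list(mu = matrix(1, 2, 2),
                                   sigma = matrix(0.4, 2, 2)))
  expect_equal(maps$tau_low[1, 1], 1.4)
  expect_equal(maps$tau_high[1, 1], 2.0)
  z <- adaptive_thresholds(list(mu = matrix(0, 1, 1), sigma = matrix(1, 1, 1)))
  expect_equal(z$tau_low[1, 1], 1.0)
  expect_equal(z$tau_high[1, 1], 2.5)
  expect_error(adaptive_thresholds(list(mu = 1, sigma = 1), k1 = 2, k2 = 1),
               "k2")

  polar <- list(rho = matrix(c(1.0, 1.4, 2.0, 2.1), 2))
  mp <- list(tau_low = matrix(1.4, 2, 2), tau_high = matrix(2.0, 2, 2))
  lab <- classify_motion(polar, mp)
  expect_equal(as.vector(lab), c(0L, 1L, 1L, 2L))   # boundaries -> class 1

  # degenerate all-static input: min_rho floor keeps everything static
  still <- list(rho = matrix(0, 4, 4))
  mz <- list(tau_low = matrix(0, 4, 4), tau_high = matrix(0, 4, 4))
  expect_true(all(classify_motion(still, mz) == 0L))
})

test_that("mask partition and k1 monotonicity hold on random fields", {
  set.seed(21)
  for (i in 1:100) {
    rho <- matrix(abs(rnorm(15 * 17, sd = 2)), 15, 17)
    polar <- list(rho = rho)
    st <- local_statistics(polar, 5L)
    lab <- classify_motion(polar, adaptive_thresholds(st, 1, 2.5))
    counts <- tabulate(lab + 1L, 3L)
    expect_identical(sum(counts), length(rho))
    if (i <= 10) {
      lab2 <- classify_motion(polar, adaptive_thresholds(st, 1.5, 2.5))
      # raising k1 only demotes pixels out of class >= 1
      expect_true(all(!(lab == 0L & lab2 > 0L)))
    }
  }
})

test_that("sparse features and rasterization are inverse selections", {
  polar <- list(rho = matrix(0, 5, 5), theta = matrix(0, 5, 5))
  mask <- matrix(0L, 5, 5)
  expect_identical(nrow(sparse_features(polar, mask)), 0L)
  expect_true(all(rasterize_motion(sparse_features(polar, mask), c(5, 5)) == 0))

  polar$rho[cbind(c(1, 3, 5), c(2, 4, 1))] <- c(1.5, 2.5, 3.5)
  polar$theta[cbind(c(1, 3, 5), c(2, 4, 1))] <- c(0.5, -1, 2)
  mask[cbind(c(1, 3, 5), c(2, 4, 1))] <- c(1L, 2L, 1L)
  sf <- sparse_features(polar, mask)
  expect_identical(nrow(sf), 3L)
  expect_setequal(sf$x, c(1, 3, 0))     # 0-based columns
  ras <- rasterize_motion(sf, c(5, 5))
  expect_equal(ras[3, 4, 1], 2.5)
  expect_equal(sum(ras[, , 1] != 0), 3)
  # round trip through the mask
  sf2 <- sparse_features(list(rho = ras[, , 1], theta = ras[, , 2]), mask)
  expect_equal(sf2, sf)
  bad <- data.frame(x = 7, y = 1, rho = 1, theta = 0, label = 1L)
  expect_error(rasterize_motion(bad, c(5, 5)), "bounds")
})
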