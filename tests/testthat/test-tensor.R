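# Axisymmetric tensor algebra.

test_that("to_matrix reproduces the limiting shapes", {
  d <- 2.3e-9
  # Sphere: orientation terms vanish.
  expect_equal(to_matrix(axisym_tensor(d, 0, theta = 1.1, phi = 2.2)),
               d * diag(3))
  # Stick along +z.
  expect_equal(to_matrix(axisym_tensor(d, 1, theta = 0)),
               diag(c(0, 0, 3 * d)))
  # Pancake limit: axial eigenvalue zero.
  ev <- eigen(to_matrix(axisym_tensor(1, -0.5, theta = 0)))$values
  expect_equal(sort(ev), c(0, 1.5, 1.5))
})

test_that("to_matrix eigenstructure matches the (iso, delta) parameterization", {
  t0 <- axisym_tensor(1e-9, 0.5, theta = pi / 3, phi = pi / 4)
  M <- to_matrix(t0)
  expect_equal(M, t(M))
  e <- eigen(M, symmetric = TRUE)
  expect_equal(sort(e$values), sort(c(2e-9, 0.5e-9, 0.5e-9)), tolerance = 1e-12)
  expect_equal(sum(diag(M)), 3 * t0$iso)
  # Axial eigenvector parallel to the stated symmetry axis.
  u <- e$vectors[, which.max(e$values)]
  axis <- c(cos(t0$phi) * sin(t0$theta), sin(t0$phi) * sin(t0$theta),
            cos(t0$theta))
  expect_equal(abs(sum(u * axis)), 1, tolerance = 1e-12)
})

test_that("to_matrix eigenvalues round-trip through eigenvalues_to_iso_delta", {
  with_seed_test(7, {
    for (i in 1:200) {
      iso <- 10^runif(1, -12, -8)
      delta <- runif(1, -0.5, 1)
      tt <- axisym_tensor(iso, delta, acos(runif(1, -1, 1)),
                          runif(1, 0, 2 * pi))
      ev <- eigen(to_matrix(tt), symmetric = TRUE, only.values = TRUE)$values
      # The axial eigenvalue is the single one, radial is degenerate.
      lpar <- iso * (1 + 2 * delta)
      lperp <- iso * (1 - delta)
      expect_equal(sort(ev), sort(c(lpar, lperp, lperp)),
                   tolerance = 1e-12)
      back <- eigenvalues_to_iso_delta(lpar, lperp)
      expect_equal(unname(back["iso"]), iso, tolerance = 1e-12)
      expect_equal(unname(back["delta"]), delta, tolerance = 1e-12)
    }
  })
})

test_that("constructors reject invalid parameters", {
  expect_error(axisym_tensor(1, 1.2), "delta")
  expect_error(axisym_tensor(1, -0.6), "delta")
  expect_error(axisym_tensor(-1, 0), "iso")
  expect_error(eigenvalues_to_iso_delta(0, 0), "degenerate")
  expect_error(eigenvalues_to_iso_delta(-1, 1))
})

test_that("eigenvalues_to_iso_delta handles the canonical shapes", {
  expect_equal(eigenvalues_to_iso_delta(1, 1), c(iso = 1, delta = 0))
  expect_equal(eigenvalues_to_iso_delta(3, 0), c(iso = 1, delta = 1))
  expect_equal(eigenvalues_to_iso_delta(0, 1.5), c(iso = 1, delta = -0.5))
})

test_that("p2 hits the standard values", {
  expect_equal(p2(1), 1)
  expect_equal(p2(0), -0.5)
  expect_equal(p2(1 / sqrt(3)), 0)
  expect_equal(p2(-1), 1)
})

test_that("closed-form contraction equals the explicit matrix double sum", {
  with_seed_test(11, {
    for (i in 1:2000) {
      b <- b_tensor(10^runif(1, 8.8, 11), runif(1, -0.5, 1),
                    acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
      D <- axisym_tensor(10^runif(1, -12, -8), runif(1, -0.5, 1),
                         acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
      oracle <- sum(to_matrix(b) * to_matrix(D))
      expect_equal(contract(b, D), oracle, tolerance = 1e-10)
    }
  })
})

test_that("spherical encoding is blind to anisotropy and orientation", {
  b <- b_tensor(1e10, 0, Theta = 0.3, Phi = 1)
  vals <- sapply(1:20, function(i) {
    D <- axisym_tensor(1e-9, runif(1, -0.5, 1), runif(1, 0, pi),
                       runif(1, 0, 2 * pi))
    contract(b, D)
  })
  expect_equal(vals, rep(1e10 * 1e-9, 20))
})

test_that("aligned linear encoding of a stick triples the exponent", {
  b <- b_tensor(1e10, 1, Theta = 0.7, Phi = 0.2)
  D <- axisym_tensor(1e-9, 1, theta = 0.7, phi = 0.2)
  expect_equal(contract(b, D), 3 * 1e10 * 1e-9)
})

test_that("contraction is invariant under joint rigid rotations", {
  with_seed_test(13, {
    b <- b_tensor(5e9, 0.8, acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
    D <- axisym_tensor(3e-9, -0.3, acos(runif(1, -1, 1)), runif(1, 0, 2 * pi))
    ub <- c(cos(b$phi) * sin(b$theta), sin(b$phi) * sin(b$theta), cos(b$theta))
    uD <- c(cos(D$phi) * sin(D$theta), sin(D$phi) * sin(D$theta), cos(D$theta))
    ref <- contract(b, D)
    for (i in 1:200) {
      R <- random_rotation()
      ab <- vec_to_angles(R %*% ub)
      aD <- vec_to_angles(R %*% uD)
      b2 <- b_tensor(3 * b$iso, b$delta, ab$theta, ab$phi)
      D2 <- axisym_tensor(D$iso, D$delta, aD$theta, aD$phi)
      expect_equal(contract(b2, D2), ref, tolerance = 1e-10)
    }
  })
})

test_that("cone angle and b-tensor anisotropy are mutual inverses", {
  expect_equal(bdelta_from_zeta(0), 1)
  expect_equal(bdelta_from_zeta(pi / 2), -0.5)
  expect_equal(zeta_from_bdelta(0) * 180 / pi, 54.7356103, tolerance = 1e-6)
  z <- seq(0, pi / 2, length.out = 500)
  expect_equal(zeta_from_bdelta(bdelta_from_zeta(z)), z, tolerance = 1e-9)
  # Monotone decreasing.
  expect_true(all(diff(bdelta_from_zeta(z)) < 0))
  expect_error(zeta_from_bdelta(1.01))
  expect_error(bdelta_from_zeta(-0.1))
})

test_that("shape ratio conversions are exact mutual inverses", {
  expect_equal(ratio_from_delta(0), 1)
  expect_equal(ratio_from_delta(-0.5), 0)
  expect_equal(delta_from_ratio(100), 99 / 102)
  expect_equal(ratio_from_delta(99 / 102), 100)
  d <- seq(-0.5, 0.99, length.out = 100)
  expect_equal(delta_from_ratio(ratio_from_delta(d)), d, tolerance = 1e-12)
  # Prolate limit: infinite ratio flagged, inverse clamps.
  expect_warning(r_inf <- ratio_from_delta(1), "infinite")
  expect_equal(r_inf, Inf)
  expect_equal(delta_from_ratio(Inf), 1 - 1e-9)
  expect_equal(delta_from_ratio(1e30, eps = 1e-6), 1 - 1e-6)
  expect_error(delta_from_ratio(-1))
})

test_that("orientation canonicalization folds antipodal axes together", {
  a <- rdtd:::canonical_axis(2.5, 1)
  expect_equal(a$theta, pi - 2.5)
  expect_equal(a$phi, (1 + pi) %% (2 * pi))
  b <- rdtd:::canonical_axis(0.5, 1)
  expect_equal(b$theta, 0.5)
  expect_equal(b$phi, 1)
})
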