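test_that("per-degree eigendecomposition is a faithful spectral factorization", {
  n_q <- 6
  Bid <- harmonic_order_matrices(array(diag(n_q), c(n_q, n_q, 1)), 1)
  e <- eigendecompose_b(Bid)
  expect_equal(e$per_l[[1]]$lambda, rep(1, n_q))
  # degenerate spectrum: columns are standard basis vectors up to permutation
  u <- e$per_l[[1]]$u
  expect_equal(u %*% t(u), diag(n_q), tolerance = 1e-12)
  expect_true(all(colSums(abs(u) > 1e-12) == 1))
  expect_equal(colSums(u), rep(1, n_q), tolerance = 1e-12)

  # rank-1
  v <- c(1, -2, 0.5, 3, -1, 0.25)
  B1 <- harmonic_order_matrices(array(v %o% v, c(n_q, n_q, 1)), 1)
  e1 <- eigendecompose_b(B1)
  expect_equal(e1$per_l[[1]]$lambda[1], sum(v^2))
  expect_lt(max(abs(e1$per_l[[1]]$lambda[-1])), 1e-12 * sum(v^2))
  expect_equal(abs(e1$per_l[[1]]$u[, 1]), abs(v) / sqrt(sum(v^2)),
               tolerance = 1e-12)

  # random PSD stack: orthonormality and reconstruction
  set.seed(5)
  vals <- array(0, c(n_q, n_q, 3))
  for (l in 1:3) { A <- matrix(rnorm(n_q * n_q), n_q); vals[, , l] <- A %*% t(A) }
  B <- harmonic_order_matrices(vals, 1)
  eb <- eigendecompose_b(B)
  for (l in 1:3) {
    u <- eb$per_l[[l]]$u
    expect_equal(t(u) %*% u, diag(n_q), tolerance = 1e-10)
    rec <- u %*% diag(eb$per_l[[l]]$lambda) %*% t(u)
    expect_lt(max(abs(rec - vals[, , l])), 1e-10 * max(abs(vals[, , l])))
  }
  # deterministic sign: largest-magnitude component positive
  for (l in 1:3) for (n in 1:n_q) {
    u <- eb$per_l[[l]]$u[, n]
    expect_gt(u[which.max(abs(u))], 0)
  }
  vals[1, 2, 1] <- vals[1, 2, 1] + 1   # break symmetry
  expect_error(eigendecompose_b(harmonic_order_matrices(vals, 1)),
               "not symmetric")
})

test_that("kappa expansion inverts on the eigenvector span", {
  n_q <- 6; n_l <- 3
  set.seed(6)
  vals <- array(0, c(n_q, n_q, n_l))
  for (l in 1:n_l) { A <- matrix(rnorm(n_q * n_q), n_q); vals[, , l] <- A %*% t(A) }
  basis <- eigendecompose_b(harmonic_order_matrices(vals, 1))
  cf <- harmonic_coefficients(matrix(rnorm(n_q * n_l^2), n_q, n_l^2), n_l, 1)

  # full-rank basis: expand then invert is the identity
  back <- kappa_inverse(kappa_expand(cf, basis), basis)
  expect_lt(max(abs(back$coef - cf$coef)), 1e-10)

  # coefficients aligned with one eigenvector: a single nonzero kappa row
  cf1 <- harmonic_coefficients(matrix(0, n_q, n_l^2), n_l, 1)
  cf1$coef[, 2] <- basis$per_l[[2]]$u[, 3] * 1.7   # an l=1 column
  K <- kappa_expand(cf1, basis)
  expect_equal(K$K[[2]][3, 1], 1.7, tolerance = 1e-12)
  expect_lt(max(abs(K$K[[2]][-3, ])), 1e-12)

  # rank-deficient basis acts as the orthogonal projector U U^T
  rd <- basis
  keep <- 1:3
  for (l in 1:n_l) {
    rd$per_l[[l]]$u <- basis$per_l[[l]]$u[, keep, drop = FALSE]
    rd$per_l[[l]]$lambda <- basis$per_l[[l]]$lambda[keep]
  }
  prj <- kappa_inverse(kappa_expand(cf, rd), rd)
  for (l in 1:n_l) {
    U <- rd$per_l[[l]]$u
    cols <- which(cf$idx[, 1] == l - 1)
    want <- U %*% (t(U) %*% cf$coef[, cols, drop = FALSE])
    expect_equal(prj$coef[, cols, drop = FALSE], want, tolerance = 1e-10)
  }
})

test_that("eigenvalue scaling fixes the kappa norms and is zero-safe", {
  # coefficients built from the same intensity as B are fixed points
  n_q <- 8; n_theta <- 16
  rb <- random_bandlimited(n_q, n_theta, seed = 12)
  B <- b_from_coeffs(rb$coef)
  basis <- eigendecompose_b(B)
  K <- kappa_expand(rb$coef, basis)
  Ks <- scale_kappa(K, basis)
  # fixed point up to eigen-solver rounding (lambda vs ||K||^2 agree to
  # a few ulps of the spectral condition, not to 1e-8 exactly)
  for (l in seq_along(K$K))
    expect_lt(max(abs(Ks$K[[l]] - K$K[[l]])),
              1e-6 * max(abs(K$K[[l]]), 1e-300))

  # zero eigenvalue -> zero output rows; all-zero K -> all-zero K'
  basis0 <- basis
  basis0$per_l[[1]]$lambda[] <- 0
  Kz <- scale_kappa(K, basis0)
  expect_true(all(Kz$K[[1]] == 0))
  K0 <- K
  for (l in seq_along(K0$K)) K0$K[[l]][] <- 0
  Kz2 <- scale_kappa(K0, basis)
  expect_true(all(unlist(Kz2$K) == 0))
})

test_that("modulus projection: fixed point, null basis, residual paths", {
  n_q <- 8; n_theta <- 16; n_l <- n_theta / 2
  rb <- random_bandlimited(n_q, n_theta, seed = 14)
  basis <- eigendecompose_b(b_from_coeffs(rb$coef))

  # self-consistent fixture is a fixed point
  out <- modulus_project(rb$si, basis)
  expect_lt(max(abs(out$values - rb$si$values)), 1e-6)
  # approximate idempotence
  out2 <- modulus_project(out, basis)
  expect_lt(max(abs(out2$values - out$values)), 1e-6)

  # all-zero B: band-limited input maps to zero
  B0 <- harmonic_order_matrices(array(0, c(n_q, n_q, n_l)), 1)
  z <- modulus_project(rb$si, eigendecompose_b(B0))
  expect_lt(max(abs(z$values)), 1e-10)

  # above-band-limit content passes through the grid-residual path exactly:
  # inject a pure degree l = n_l mode, built directly on the grid (it is
  # exactly orthogonal to all degrees < n_l under the DH quadrature)
  l_hi <- n_l; m_hi <- 4
  th <- pi * (0:(n_theta - 1)) / n_theta
  ph <- 2 * pi * (0:(2 * n_theta - 1)) / (2 * n_theta)
  nrm <- sqrt((2 * l_hi + 1) / (4 * pi) *
                exp(lgamma(l_hi - m_hi + 1) - lgamma(l_hi + m_hi + 1)))
  pth <- (-1)^m_hi * pracma::legendre(l_hi, cos(th))[m_hi + 1, ] * nrm
  mode_grid <- outer(pth, sqrt(2) * cos(m_hi * ph))
  hi_vals <- array(0, c(n_q, n_theta, 2 * n_theta))
  for (qi in seq_len(n_q)) hi_vals[qi, , ] <- mode_grid
  hi_grid <- spherical_intensity(hi_vals, 1)
  with_hi <- rb$si
  with_hi$values <- with_hi$values + hi_grid$values
  out3 <- modulus_project(with_hi, basis)
  expect_lt(max(abs((out3$values - out$values) - hi_grid$values)), 1e-6)

  # with corrections disabled the output is exactly band-limited and
  # lies in the eigenvector span
  out4 <- modulus_project(with_hi, basis, keep_grid_residual = FALSE,
                          keep_coeff_residual = FALSE)
  cf4 <- sht_forward(out4)
  rt <- sht_inverse(cf4, n_theta)
  expect_lt(max(abs(rt$values - out4$values)), 1e-9)
})

test_that("support mask geometry and projection behave as projectors", {
  cell <- unit_cell(5.1, 7.3, 9.2, 81, 96, 103)
  pk <- enumerate_hkl(cell, 2.2)
  pk1 <- pk[10, ]; class(pk1) <- class(pk)

  m1 <- build_support_mask(pk1, 2.2, 16, 16, width = 1)
  expect_equal(sum(m1$mask), 1)
  m5 <- build_support_mask(pk1, 2.2, 32, 32, width = 5)
  # interior peak: full 5^3 block
  expect_equal(sum(m5$mask), 125)
  expect_error(build_support_mask(pk1, 2.2, 16, 16, width = 4), "odd")

  # no overlaps at the study sampling; overlaps appear at coarse n_q
  mfull <- build_support_mask(pk, 2.2, 32, 32, width = 3)
  expect_equal(mfull$overlap_pairs, 0)
  mcoarse <- build_support_mask(pk, 2.2, 8, 32, width = 3)
  expect_gt(mcoarse$overlap_pairs, 0)

  # support projection: elementwise max(0, I) * M, exactly idempotent
  set.seed(20)
  si <- spherical_intensity(array(rnorm(32 * 32 * 64), c(32, 32, 64)), 2.2)
  ps <- support_project(si, mfull)
  expect_equal(ps$values, pmax(si$values, 0) * mfull$mask)
  expect_identical(support_project(ps, mfull)$values, ps$values)
  neg <- si; neg$values <- -abs(neg$values)
  expect_true(all(support_project(neg, mfull)$values == 0))
})
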