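test_that("3D correlator matches its definition on hand cases", {
  # all-zero intensities -> all-zero volume
  pk <- random_peaks(10, 1, seed = 1)
  pk$intensity <- 0
  expect_true(all(correlate_3d(pk, 4, 8, 1)$values == 0))

  # one peak, I = 2, self pair: 4 at (q, q, eta = 1)
  p1 <- bragg_peaks(1, 0, 0, matrix(c(0.5, 0, 0.1), 1), intensity = 2,
                    q_max = 1)
  cv <- correlate_3d(p1, 4, 8, 1)
  expect_equal(sum(cv$values), 4)
  iq <- min(floor(p1$q_mag / 1 * 4), 3) + 1
  expect_equal(cv$values[iq, iq, 8], 4)

  # two orthogonal peaks, equal |q|, I = 1 and 3
  p2 <- bragg_peaks(c(1, 2), c(0, 0), c(0, 0),
                    rbind(c(0.6, 0, 0), c(0, 0.6, 0)),
                    intensity = c(1, 3), q_max = 1)
  cv2 <- correlate_3d(p2, 4, 8, 1)
  iq <- min(floor(0.6 * 4), 3) + 1
  ie0 <- floor((0 + 1) / 2 * 8) + 1      # eta = 0 bin
  expect_equal(cv2$values[iq, iq, ie0], 6)    # two ordered cross pairs
  expect_equal(cv2$values[iq, iq, 8], 10)     # self pairs 1 + 9
  expect_equal(cv2$values, correlate_3d_oracle(p2, 4, 8, 1))
})

test_that("vectorized 3D correlator equals the double-loop oracle exactly", {
  for (s in 1:8) {
    set.seed(400 + s)
    n <- sample(5:60, 1)
    pk <- random_peaks(n, 1.5, seed = 100 + s)
    got <- correlate_3d(pk, 6, 16, 1.5)
    expect_identical(got$values, correlate_3d_oracle(pk, 6, 16, 1.5))
  }
  # chunked path agrees too (chunking changes the accumulation grouping,
  # so equality is to rounding rather than bit-exact)
  pk <- random_peaks(150, 1.5, seed = 9)
  got <- correlate_3d(pk, 6, 16, 1.5, chunk = 32L)
  expect_equal(got$values, correlate_3d_oracle(pk, 6, 16, 1.5),
               tolerance = 1e-14)
  # and with self pairs excluded
  got2 <- correlate_3d(pk, 6, 16, 1.5, self_pairs = FALSE)
  expect_identical(got2$values,
                   correlate_3d_oracle(pk, 6, 16, 1.5, self_pairs = FALSE))
})

test_that("3D correlation invariants hold", {
  pk <- random_peaks(80, 2, seed = 21)
  cv <- correlate_3d(pk, 8, 32, 2)
  # q-swap symmetry
  for (k in seq_len(32)) {
    expect_equal(cv$values[, , k], t(cv$values[, , k]))
  }
  # intensity scaling s -> correlation s^2
  pk2 <- pk
  pk2$intensity <- pk$intensity * 3
  expect_equal(correlate_3d(pk2, 8, 32, 2)$values, 9 * cv$values)
  # out-of-range / config errors
  expect_error(correlate_3d(pk, 8, 32, 1), "q_max")
  expect_error(correlate_3d(pk, 1, 32, 2), ">= 2")
})

test_that("Friedel-symmetric peak lists have no odd Legendre content", {
  fb <- make_toy_crystal(seed = 5, n_eta = 256)
  Fm <- legendre_matrix(fb$correlation$n_ang, 16)
  B <- b_from_correlation(fb$correlation, Fm)
  odd <- sqrt(sum(B$values[, , seq(2, 16, 2)]^2))
  even <- sqrt(sum(B$values[, , seq(1, 15, 2)]^2))
  expect_lt(odd / even, 1e-10)
})

test_that("2D correlator averages ordered pairs per pattern", {
  pat1 <- data.frame(q_mag = 0.4, phi = 1.0, intensity = 2)
  cv <- correlate_2d(list(pat1), 4, 8, 1)
  expect_equal(sum(cv$values), 4)            # single self pair at psi = 0
  expect_equal(cv$values[2, 2, 1], 4)

  # averaging identical patterns changes nothing
  pat2 <- data.frame(q_mag = c(0.3, 0.7), phi = c(0.2, 2.2),
                     intensity = c(1, 2))
  one <- correlate_2d(list(pat2), 4, 8, 1)
  two <- correlate_2d(list(pat2, pat2), 4, 8, 1)
  expect_equal(one$values, two$values)

  # random pattern against a double loop
  set.seed(31)
  pat3 <- data.frame(q_mag = runif(10, 0.1, 1), phi = runif(10, 0, 2 * pi),
                     intensity = runif(10))
  got <- correlate_2d(list(pat3), 5, 12, 1)
  want <- array(0, c(5, 5, 12))
  for (i in 1:10) for (j in 1:10) {
    psi <- abs(pat3$phi[i] - pat3$phi[j])
    psi <- min(psi %% (2 * pi), 2 * pi - psi %% (2 * pi))
    b1 <- min(floor(pat3$q_mag[i] / 1 * 5), 4) + 1
    b2 <- min(floor(pat3$q_mag[j] / 1 * 5), 4) + 1
    bp <- min(floor(psi / pi * 12), 11) + 1
    want[b1, b2, bp] <- want[b1, b2, bp] + pat3$intensity[i] * pat3$intensity[j]
  }
  expect_equal(got$values, want)
})

test_that("psi <-> eta conversion respects Ewald geometry", {
  n_q <- 6; n_ang <- 256; q_max <- 2
  qc <- (seq_len(n_q) - 0.5) * q_max / n_q
  psi <- (seq_len(n_ang) - 0.5) * pi / n_ang
  # smooth band-limited test volume, zero-derivative at the psi endpoints
  vals <- array(0, c(n_q, n_q, n_ang))
  for (i in 1:n_q) for (j in 1:n_q)
    vals[i, j, ] <- 1 + 0.5 * cos(psi) + 0.2 * cos(2 * psi) * (i + j) / 12
  cv <- correlation_volume(vals, q_max, "psi")

  # flat-Ewald limit: eta = cos(psi); an impulse lands at the cosine bin
  imp <- correlation_volume(array(0, c(n_q, n_q, n_ang)), q_max, "psi")
  kpsi <- 64
  imp$values[3, 5, kpsi] <- 1
  out <- convert_psi_eta(imp, k = Inf)
  eta_hit <- -1 + (which.max(out$values[3, 5, ]) - 0.5) * 2 / n_ang
  expect_equal(eta_hit, cos(psi[kpsi]), tolerance = 2 / n_ang * 2)

  # finite-k impulse position against the direct geometric formula
  k <- 3
  th <- pi / 2 + asin(qc / (2 * k))
  eta_pred <- cos(th[3]) * cos(th[5]) + sin(th[3]) * sin(th[5]) * cos(psi[kpsi])
  outk <- convert_psi_eta(imp, k = k)
  eta_hitk <- -1 + (which.max(outk$values[3, 5, ]) - 0.5) * 2 / n_ang
  expect_equal(eta_hitk, eta_pred, tolerance = 2 / n_ang * 2)

  # round trip psi -> eta -> psi: exact band coverage in the flat limit
  rt_flat <- convert_psi_eta(convert_psi_eta(cv, k = Inf), k = Inf)
  expect_lt(max(abs(rt_flat$values - cv$values)), 1e-6)
  # at finite k the edge of the Ewald-reachable eta band is a genuine
  # discontinuity; the round trip is accurate away from it
  rt <- convert_psi_eta(convert_psi_eta(cv, k = k), k = k)
  core <- which(sin(psi) > 0.35)
  expect_lt(max(abs(rt$values[, , core] - cv$values[, , core])), 1e-6)

  # geometry error when the Ewald sphere is too small
  expect_error(convert_psi_eta(cv, k = 0.9), "Ewald")
})
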