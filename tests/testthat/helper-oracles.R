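# Shared fixtures and independent brute-force oracles.

# random peak list (not a lattice): directions uniform on the sphere,
# magnitudes uniform in (0, q_max], intensities uniform
random_peaks <- function(n, q_max, seed) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  qm <- stats::runif(n, 0.05 * q_max, q_max)
  qv <- v * qm
  bragg_peaks(seq_len(n), rep(0L, n), rep(0L, n), qv,
              intensity = stats::runif(n), q_max = q_max)
}

# naive O(N^2) double-loop 3D correlator: scalar double arithmetic
# throughout, accumulating each bin in pair-encounter order (j outer,
# i inner) - the same rounding sequence as the vectorised grouped
# accumulation, so agreement is bit-exact.
correlate_3d_oracle <- function(peaks, n_q, n_eta, q_max,
                                self_pairs = TRUE) {
  qv <- as.matrix(peaks[, c("qx", "qy", "qz")])
  qm <- peaks$q_mag
  I <- peaks$intensity
  n <- nrow(qv)
  vals <- array(0, c(n_q, n_q, n_eta))
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (!self_pairs && i == j) next
      eta <- (qv[i, 1] * qv[j, 1] + qv[i, 2] * qv[j, 2] +
                qv[i, 3] * qv[j, 3]) / (qm[i] * qm[j])
      eta <- min(max(eta, -1), 1)
      iq1 <- min(floor(qm[i] / q_max * n_q), n_q - 1) + 1
      iq2 <- min(floor(qm[j] / q_max * n_q), n_q - 1) + 1
      ie <- min(floor((eta + 1) / 2 * n_eta), n_eta - 1) + 1
      vals[iq1, iq2, ie] <- vals[iq1, iq2, ie] + I[i] * I[j]
    }
  }
  vals
}

# random band-limited spherical intensity via coefficient synthesis
random_bandlimited <- function(n_q, n_theta, n_l = n_theta / 2, q_max = 1,
                               seed = 1) {
  set.seed(seed)
  coef <- matrix(stats::rnorm(n_q * n_l^2), n_q, n_l^2)
  list(coef = harmonic_coefficients(coef, n_l, q_max),
       si = sht_inverse(harmonic_coefficients(coef, n_l, q_max),
                        n_theta = n_theta))
}

# synthetic voxel-centre peak list: peaks sitting exactly on grid voxel
# centres (matched sampling between the correlation and the gridded volume)
voxel_center_peaks <- function(n_q, n_theta, q_max, n_peaks, seed) {
  set.seed(seed)
  n_phi <- 2L * n_theta
  qc <- (seq_len(n_q) - 0.5) * q_max / n_q
  th <- pi * (0:(n_theta - 1)) / n_theta
  ph <- 2 * pi * (0:(n_phi - 1)) / n_phi
  iq <- sample(seq_len(n_q), n_peaks, replace = TRUE)
  it <- sample(2:n_theta, n_peaks, replace = TRUE)   # skip zero-weight pole
  ip <- sample(seq_len(n_phi), n_peaks, replace = TRUE)
  dup <- duplicated(cbind(iq, it, ip))
  iq <- iq[!dup]; it <- it[!dup]; ip <- ip[!dup]
  n <- length(iq)
  dir <- cbind(sin(th[it]) * cos(ph[ip]), sin(th[it]) * sin(ph[ip]),
               cos(th[it]))
  qv <- dir * qc[iq]
  bragg_peaks(seq_len(n), rep(0L, n), rep(0L, n), qv,
              intensity = stats::runif(n, 0.2, 2), q_max = q_max)
}

# per-degree relative Frobenius difference of two harmonic-order stacks
b_rel_err <- function(B1, B2, l) {
  num <- sqrt(sum((B1$values[, , l + 1] - B2$values[, , l + 1])^2))
  den <- sqrt(sum(B2$values[, , l + 1]^2))
  num / den
}
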