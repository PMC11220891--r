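#' Correlation volume
#'
#' The FXS angular intensity correlation function C(q1, q2, ang) as an
#' `n_q x n_q x n_ang` array. The angular coordinate is either
#' `eta = cos(angle between q1 and q2)` on `n_ang` uniform bins spanning
#' `[-1, 1]`, or the detector-plane angle `psi` on uniform bins spanning
#' `[0, pi]`.
#'
#' @param values `n_q x n_q x n_ang` array.
#' @param q_max Radial cutoff in 1/Angstrom.
#' @param angular `"eta"` or `"psi"`.
#' @return A `correlation_volume` object.
#' @export
correlation_volume <- function(values, q_max, angular = c("eta", "psi")) {
  angular <- match.arg(angular)
  d <- dim(values)
  stopifnot(length(d) == 3, d[1] == d[2])
  structure(list(values = values, q_max = q_max,
                 n_q = d[1], n_ang = d[3], angular = angular),
            class = "correlation_volume")
}

#' @export
print.correlation_volume <- function(x, ...) {
  cat(sprintf("correlation volume: n_q=%d n_%s=%d q_max=%.3f\n",
              x$n_q, x$angular, x$n_ang, x$q_max))
  invisible(x)
}

# radial bin: uniform over [0, q_max], top edge clamped into the last bin
q_bin <- function(q, q_max, n_q) {
  pmin(floor(q / q_max * n_q), n_q - 1L) + 1L
}

# eta bin over [-1, 1], top edge clamped
eta_bin <- function(eta, n_eta) {
  pmin(floor((eta + 1) / 2 * n_eta), n_eta - 1L) + 1L
}

#' 3D Bragg-peak correlation function
#'
#' The "ground truth" correlator: an unrestricted double sum over ordered
#' pairs of peaks accumulating `I_i * I_j` into the bin
#' `(bin(q_i), bin(q_j), bin(eta_ij))`, with
#' `eta_ij = dot(q_i, q_j) / (|q_i| |q_j|)` clamped to `[-1, 1]`. The Dirac
#' delta is realised as nearest-bin assignment; no kernel smoothing and no
#' occupancy normalization.
#'
#' @param peaks A [bragg_peaks()] list with intensities.
#' @param n_q,n_eta Radial / angular bin counts (each `>= 2`).
#' @param q_max Radial cutoff; all peaks must satisfy `q_mag <= q_max`.
#' @param self_pairs Include the `i = j` terms (default TRUE; the double sum
#'   is unrestricted).
#' @param chunk Number of peaks per vectorised block (memory control).
#' @return A [correlation_volume()] in eta parametrization, symmetric under
#'   swap of the two q axes.
#' @export
correlate_3d <- function(peaks, n_q, n_eta, q_max, self_pairs = TRUE,
                         chunk = 512L) {
  stopifnot(inherits(peaks, "bragg_peaks"))
  if (n_q < 2 || n_eta < 2) stop("n_q and n_eta must be >= 2", call. = FALSE)
  if (nrow(peaks) == 0) stop("empty peak list", call. = FALSE)
  if (any(peaks$q_mag > q_max))
    stop("peak with q_mag > q_max", call. = FALSE)
  qv <- as.matrix(peaks[, c("qx", "qy", "qz")])
  qm <- peaks$q_mag
  I <- peaks$intensity
  iq <- q_bin(qm, q_max, n_q)
  np <- nrow(qv)
  vals <- array(0, c(n_q, n_q, n_eta))
  for (lo in seq(1L, np, by = chunk)) {
    hi <- min(lo + chunk - 1L, np)
    rows <- lo:hi
    G <- qv[rows, , drop = FALSE] %*% t(qv)
    eta <- pmin(pmax(G / outer(qm[rows], qm), -1), 1)
    ie <- eta_bin(eta, n_eta)
    w <- outer(I[rows], I)
    if (!self_pairs) w[cbind(seq_along(rows), rows)] <- 0
    # flat index into the (n_q, n_q, n_eta) array for all pairs in the chunk
    flat <- iq[rows][row(ie)] + (iq[col(ie)] - 1L) * n_q +
      (ie - 1L) * (n_q * n_q)
    acc <- rowsum(as.vector(w), as.vector(flat))
    at <- as.integer(rownames(acc))
    vals[at] <- vals[at] + acc[, 1]
  }
  correlation_volume(vals, q_max, "eta")
}

#' Per-pattern 2D peak correlation function
#'
#' The detector-frame correlator: within each diffraction pattern, every
#' ordered pair of peaks accumulates `I_i * I_j` at
#' `(bin(q_i), bin(q_j), bin(psi_ij))` with `psi_ij = |phi_i - phi_j|`
#' wrapped into `[0, pi]`; the result is the plain average over patterns.
#' Raw peak intensities are correlated (no per-pattern mean subtraction).
#'
#' @param patterns List of data frames with columns `q_mag`, `phi`
#'   (radians, in `[0, 2*pi)`) and `intensity`.
#' @param n_q,n_psi Bin counts (each `>= 2`).
#' @param q_max Radial cutoff.
#' @param self_pairs Include `i = j` terms.
#' @return A [correlation_volume()] in psi parametrization.
#' @export
correlate_2d <- function(patterns, n_q, n_psi, q_max, self_pairs = TRUE) {
  if (!length(patterns)) stop("need at least one pattern", call. = FALSE)
  if (n_q < 2 || n_psi < 2) stop("n_q and n_psi must be >= 2", call. = FALSE)
  vals <- array(0, c(n_q, n_q, n_psi))
  for (pat in patterns) {
    stopifnot(all(c("q_mag", "phi", "intensity") %in% names(pat)))
    if (any(pat$q_mag > q_max)) stop("peak with q_mag > q_max", call. = FALSE)
    iq <- q_bin(pat$q_mag, q_max, n_q)
    dphi <- abs(outer(pat$phi, pat$phi, "-"))
    psi <- pmin(dphi %% (2 * pi), 2 * pi - (dphi %% (2 * pi)))
    ip <- pmin(floor(psi / pi * n_psi), n_psi - 1L) + 1L
    w <- outer(pat$intensity, pat$intensity)
    if (!self_pairs) diag(w) <- 0
    flat <- iq[row(ip)] + (iq[col(ip)] - 1L) * n_q + (ip - 1L) * (n_q * n_q)
    acc <- rowsum(as.vector(w), as.vector(flat))
    at <- as.integer(rownames(acc))
    vals[at] <- vals[at] + acc[, 1]
  }
  correlation_volume(vals / length(patterns), q_max, "psi")
}

# Ewald-sphere polar angle of a scattering vector of magnitude q at
# wavenumber k: theta(q) = pi/2 + asin(q / (2k)); requires q < 2k.
ewald_theta <- function(q, k) {
  if (any(q >= 2 * k))
    stop("Ewald geometry undefined: need k > q_max / 2", call. = FALSE)
  pi / 2 + asin(q / (2 * k))
}

#' Convert a correlation volume between psi and eta parametrizations
#'
#' On the Ewald sphere at wavenumber `k`, two scattering vectors of
#' magnitudes q1, q2 separated by detector azimuth psi subtend
#' `eta = cos(theta(q1)) cos(theta(q2)) + sin(theta(q1)) sin(theta(q2)) cos(psi)`
#' with `theta(q) = pi/2 + asin(q / 2k)`. In the flat-Ewald limit
#' (`k -> Inf`) this reduces to `eta = cos(psi)`. The conversion resamples
#' the angular axis by cubic spline, applies the Jacobian
#' `|d psi / d eta| = 1 / (sin(theta1) sin(theta2) sin(psi))` (densities
#' transform), and applies the Ewald curvature factor `|q1| |q2|` relating the
#' 2D correlator to the 3D one (divided back out for `eta -> psi`). The two
#' directions are mutually inverse up to resampling error.
#'
#' @param cv A [correlation_volume()].
#' @param k X-ray wavenumber in 1/Angstrom (`Inf` for the flat limit);
#'   must exceed `q_max / 2`.
#' @param direction `"psi_to_eta"` or `"eta_to_psi"`; default follows the
#'   volume's current parametrization.
#' @param n_out Number of angular bins of the output (default: same).
#' @return A [correlation_volume()] in the other parametrization.
#' @export
convert_psi_eta <- function(cv, k = Inf,
                            direction = NULL, n_out = cv$n_ang) {
  stopifnot(inherits(cv, "correlation_volume"))
  if (is.null(direction))
    direction <- if (cv$angular == "psi") "psi_to_eta" else "eta_to_psi"
  direction <- match.arg(direction, c("psi_to_eta", "eta_to_psi"))
  src_ok <- if (direction == "psi_to_eta") "psi" else "eta"
  if (cv$angular != src_ok)
    stop(sprintf("volume is in %s parametrization; cannot apply %s",
                 cv$angular, direction), call. = FALSE)
  if (!is.infinite(k) && k <= cv$q_max / 2)
    stop("Ewald geometry undefined: need k > q_max / 2", call. = FALSE)
  n_q <- cv$n_q
  qc <- (seq_len(n_q) - 0.5) * cv$q_max / n_q
  th <- if (is.infinite(k)) rep(pi / 2, n_q) else ewald_theta(qc, k)
  psi_g <- (seq_len(if (direction == "psi_to_eta") cv$n_ang else n_out) - 0.5) *
    pi / (if (direction == "psi_to_eta") cv$n_ang else n_out)
  eta_g <- -1 + (seq_len(if (direction == "psi_to_eta") n_out else cv$n_ang) - 0.5) *
    (2 / (if (direction == "psi_to_eta") n_out else cv$n_ang))
  out <- array(0, c(n_q, n_q, n_out))
  for (i in seq_len(n_q)) for (j in seq_len(n_q)) {
    cc <- cos(th[i]) * cos(th[j]); ss <- sin(th[i]) * sin(th[j])
    if (direction == "psi_to_eta") {
      # eta(psi) is monotone in psi; invert and resample. Eta values outside
      # the Ewald-reachable band [cc - ss, cc + ss] carry no signal.
      x <- (eta_g - cc) / ss
      reach <- abs(x) <= 1
      psi_of_eta <- acos(pmin(pmax(x, -1), 1))
      f <- stats::splinefun(psi_g, cv$values[i, j, ], method = "fmm")
      jac <- 1 / pmax(ss * sin(psi_of_eta), .Machine$double.eps)
      out[i, j, reach] <- (f(psi_of_eta) * jac * (qc[i] * qc[j]))[reach]
    } else {
      # interpolate the smooth psi-frame values: divide the eta-frame
      # density by the (singular) Jacobian before resampling
      x <- (eta_g - cc) / ss
      reach <- abs(x) <= 1
      psi_of_eta <- acos(pmin(pmax(x, -1), 1))
      smooth <- cv$values[i, j, ] *
        pmax(ss * sin(psi_of_eta), .Machine$double.eps) / (qc[i] * qc[j])
      # constant continuation outside the reachable band: those knots are
      # never evaluated for valid outputs, but a hard jump there would ring
      # through the spline into the band interior
      if (any(reach) && !all(reach)) {
        lo <- min(which(reach)); hi <- max(which(reach))
        if (lo > 1) smooth[seq_len(lo - 1)] <- smooth[lo]
        if (hi < length(smooth)) smooth[(hi + 1):length(smooth)] <- smooth[hi]
      }
      f <- stats::splinefun(eta_g, smooth, method = "fmm")
      eta_of_psi <- pmin(pmax(cc + ss * cos(psi_g), -1), 1)
      out[i, j, ] <- f(eta_of_psi)
    }
  }
  correlation_volume(out, cv$q_max,
                     if (direction == "psi_to_eta") "eta" else "psi")
}
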