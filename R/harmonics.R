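#' Spherical intensity volume
#'
#' The reciprocal-space intensity function I(q, theta, phi) sampled on
#' `n_q` radial shells and a Driscoll-Healy equiangular angular grid:
#' `theta_j = pi * j / n_theta` (j = 0..n_theta-1),
#' `phi_k = 2 * pi * k / n_phi` (k = 0..n_phi-1), with `n_phi = 2 * n_theta`.
#' On this grid the spherical-harmonic transform is exactly invertible for
#' band-limited functions up to degree `n_l = n_theta / 2`.
#'
#' Voxel values are intensity per quadrature weight: a Bragg peak (a delta
#' function in reciprocal space) placed at a voxel carries its integrated
#' intensity divided by the voxel's quadrature weight, so that surface
#' integrals and harmonic coefficients come out right.
#'
#' @param values `n_q x n_theta x n_phi` numeric array (or a conformable
#'   `n_q x (n_theta*n_phi)` matrix plus `n_theta`).
#' @param q_max Radial cutoff in 1/Angstrom.
#' @param n_theta Number of theta samples (needed when `values` is a matrix).
#' @return A `spherical_intensity` object.
#' @export
spherical_intensity <- function(values, q_max, n_theta = NULL) {
  if (is.matrix(values)) {
    if (is.null(n_theta)) stop("n_theta required for matrix input", call. = FALSE)
    nphi <- ncol(values) / n_theta
    values <- array(values, dim = c(nrow(values), n_theta, nphi))
  }
  d <- dim(values)
  if (length(d) != 3 || d[3] != 2 * d[2])
    stop("grid convention violated: need n_q x n_theta x (2*n_theta) array",
         call. = FALSE)
  structure(list(values = values, q_max = q_max,
                 n_q = d[1], n_theta = d[2], n_phi = d[3]),
            class = "spherical_intensity")
}

#' @export
print.spherical_intensity <- function(x, ...) {
  cat(sprintf("spherical intensity: n_q=%d n_theta=%d n_phi=%d q_max=%.3f\n",
              x$n_q, x$n_theta, x$n_phi, x$q_max))
  invisible(x)
}

# flatten to n_q x (n_theta*n_phi); column index = (iphi-1)*n_theta + itheta
si_matrix <- function(si) {
  matrix(si$values, si$n_q, si$n_theta * si$n_phi)
}

#' Driscoll-Healy quadrature weights
#'
#' Weights `w_j` for the colatitude samples `theta_j = pi*j/n_theta` such that
#' `sum_j w_j f(theta_j)` equals `integral_0^pi f(theta) sin(theta) dtheta`
#' exactly for trigonometric polynomials up to the grid's band limit. The
#' `j = 0` (pole) weight is exactly zero.
#'
#' @param n_theta Even number of theta samples.
#' @return Numeric vector of length `n_theta` (sums to 2).
#' @export
dh_weights <- function(n_theta) {
  if (n_theta %% 2 != 0) stop("n_theta must be even", call. = FALSE)
  b <- n_theta / 2
  th <- pi * (0:(n_theta - 1)) / n_theta
  kk <- 2 * (0:(b - 1)) + 1
  vapply(th, function(t) (4 / n_theta) * sin(t) * sum(sin(kk * t) / kk),
         numeric(1))
}

# cache of real spherical-harmonic bases keyed by "n_theta:n_l"
.sh_cache <- new.env(parent = emptyenv())

# Real orthonormal spherical harmonics (no Condon-Shortley phase) evaluated
# on the Driscoll-Healy grid, as an (n_l^2) x (n_theta*n_phi) matrix, plus
# the (l, m) index table and the full quadrature weight per grid point.
sh_basis <- function(n_theta, n_l = n_theta / 2) {
  key <- paste0(n_theta, ":", n_l)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  if (n_l > n_theta / 2)
    stop("n_l exceeds the Driscoll-Healy band limit n_theta/2", call. = FALSE)
  n_phi <- 2L * n_theta
  th <- pi * (0:(n_theta - 1)) / n_theta
  ph <- 2 * pi * (0:(n_phi - 1)) / n_phi
  x <- cos(th)
  idx <- do.call(rbind, lapply(0:(n_l - 1), function(l) cbind(l = l, m = -l:l)))
  Y <- matrix(0, nrow(idx), n_theta * n_phi)
  for (l in 0:(n_l - 1)) {
    P <- if (l == 0) matrix(1, 1, n_theta) else pracma::legendre(l, x)
    for (m in -l:l) {
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      # pracma::legendre carries the Condon-Shortley phase; strip it
      pth <- (-1)^am * P[am + 1, ] * nrm
      f <- if (m > 0) sqrt(2) * cos(m * ph)
           else if (m < 0) sqrt(2) * sin(am * ph)
           else rep(1, n_phi)
      Y[which(idx[, 1] == l & idx[, 2] == m), ] <- as.vector(outer(pth, f))
    }
  }
  wvec <- as.vector(outer(dh_weights(n_theta), rep(2 * pi / n_phi, n_phi)))
  out <- list(Y = Y, idx = idx, wvec = wvec, n_theta = n_theta,
              n_phi = n_phi, n_l = n_l)
  .sh_cache[[key]] <- out
  out
}

#' Harmonic coefficients container
#'
#' Real spherical-harmonic coefficients I_lm(q) for each radial shell, stored
#' as an `n_q x n_l^2` matrix whose columns follow the (l, m) table in
#' `idx` (l ascending, m from -l to l).
#'
#' @param coef `n_q x n_l^2` matrix.
#' @param n_l Band limit (degrees 0..n_l-1).
#' @param q_max Radial cutoff.
#' @return A `harmonic_coefficients` object.
#' @export
harmonic_coefficients <- function(coef, n_l, q_max = NA_real_) {
  idx <- do.call(rbind, lapply(0:(n_l - 1), function(l) cbind(l = l, m = -l:l)))
  stopifnot(ncol(coef) == nrow(idx))
  structure(list(coef = coef, idx = idx, n_l = n_l,
                 n_q = nrow(coef), q_max = q_max),
            class = "harmonic_coefficients")
}

#' Forward spherical-harmonic transform
#'
#' Projects each radial shell of a [spherical_intensity()] onto the real
#' orthonormal spherical harmonics using Driscoll-Healy quadrature:
#' `I_lm(q) = sum_jk w_j (2*pi/n_phi) I(q, theta_j, phi_k) Y_lm(theta_j, phi_k)`.
#' Exact inverse of [sht_inverse()] for band-limited input (degree < n_l).
#'
#' @param si A [spherical_intensity()].
#' @param n_l Band limit; default the grid maximum `n_theta / 2`.
#' @return A [harmonic_coefficients()] object.
#' @export
sht_forward <- function(si, n_l = si$n_theta / 2) {
  stopifnot(inherits(si, "spherical_intensity"))
  bs <- sh_basis(si$n_theta, n_l)
  V <- si_matrix(si)
  coef <- t(bs$Y %*% (t(V) * bs$wvec))
  harmonic_coefficients(coef, n_l, si$q_max)
}

#' Inverse spherical-harmonic transform
#'
#' Synthesises `I(q, theta, phi) = sum_lm I_lm(q) Y_lm(theta, phi)` on the
#' Driscoll-Healy grid.
#'
#' @param coeffs A [harmonic_coefficients()] object.
#' @param n_theta Number of theta samples of the output grid (must admit the
#'   coefficients' band limit: `n_theta >= 2 * n_l`).
#' @return A [spherical_intensity()].
#' @export
sht_inverse <- function(coeffs, n_theta = 2 * coeffs$n_l) {
  stopifnot(inherits(coeffs, "harmonic_coefficients"))
  if (n_theta < 2 * coeffs$n_l)
    stop("n_theta too small for the coefficient band limit", call. = FALSE)
  bs <- sh_basis(n_theta, coeffs$n_l)
  V <- coeffs$coef %*% bs$Y
  spherical_intensity(V, coeffs$q_max, n_theta = n_theta)
}

#' Legendre design matrix for the correlation expansion
#'
#' `F[k, l+1] = P_l(eta_k)` on the centres of `n_eta` uniform bins spanning
#' `[-1, 1]`. Column `l = 0` is all ones.
#'
#' @param n_eta Number of eta bins.
#' @param n_l Number of Legendre degrees (0..n_l-1).
#' @return `n_eta x n_l` matrix of class `legendre_matrix` with the bin grid
#'   in attribute `eta`.
#' @export
legendre_matrix <- function(n_eta, n_l) {
  eta <- -1 + (seq_len(n_eta) - 0.5) * (2 / n_eta)
  Fm <- vapply(0:(n_l - 1), function(l) {
    if (l == 0) rep(1, n_eta) else pracma::legendre(l, eta)[1, ]
  }, numeric(n_eta))
  attr(Fm, "eta") <- eta
  class(Fm) <- c("legendre_matrix", class(Fm))
  Fm
}

#' Harmonic order matrices container
#'
#' The per-degree coupling `B(q1, q2, l)` between spherical-harmonic
#' coefficients of an intensity volume, stored as an `n_q x n_q x n_l` array.
#'
#' @param values `n_q x n_q x n_l` array.
#' @param q_max Radial cutoff.
#' @param l_max_used Highest degree with (possibly) nonzero entries plus one;
#'   defaults to `n_l`.
#' @return A `harmonic_order_matrices` object.
#' @export
harmonic_order_matrices <- function(values, q_max = NA_real_,
                                    l_max_used = dim(values)[3]) {
  stopifnot(length(dim(values)) == 3, dim(values)[1] == dim(values)[2])
  structure(list(values = values, n_q = dim(values)[1], n_l = dim(values)[3],
                 q_max = q_max, l_max_used = l_max_used),
            class = "harmonic_order_matrices")
}

#' Harmonic order matrices from harmonic coefficients
#'
#' `B(q1, q2, l) = sum_m I_lm(q1) I_lm(q2)`: symmetric and positive
#' semi-definite in (q1, q2) for every degree.
#'
#' @param coeffs A [harmonic_coefficients()] object.
#' @return A [harmonic_order_matrices()] object.
#' @export
b_from_coeffs <- function(coeffs) {
  stopifnot(inherits(coeffs, "harmonic_coefficients"))
  n_q <- coeffs$n_q; n_l <- coeffs$n_l
  B <- array(0, c(n_q, n_q, n_l))
  for (l in 0:(n_l - 1)) {
    A <- coeffs$coef[, coeffs$idx[, 1] == l, drop = FALSE]
    B[, , l + 1] <- A %*% t(A)
  }
  harmonic_order_matrices(B, coeffs$q_max)
}

#' Harmonic order matrices from a correlation volume
#'
#' Solves `C(q1, q2, .) = F %*% B(q1, q2, .)` for every (q1, q2) pair with the
#' Moore-Penrose pseudo-inverse of the Legendre matrix `F`. With
#' `normalize = TRUE` (default) the solution is divided by `2 * pi * d_eta`
#' (`d_eta = 2 / n_eta`), which puts `B` on the same scale as
#' [b_from_coeffs()] applied to the delta-peak intensity volume that produced
#' the correlation: the Legendre completeness expansion of the histogrammed
#' delta function contributes `(2l+1)/2 * d_eta * P_l`, while the addition
#' theorem in Eq.-(8) form contributes `(2l+1)/(4*pi) * P_l`; the ratio is
#' the degree-independent constant `2 * pi * d_eta`.
#'
#' @param cv A [correlation_volume()] in eta parametrization.
#' @param Fm A [legendre_matrix()] with `n_eta` rows; its column count sets
#'   the recovered band limit.
#' @param normalize Apply the `1 / (2*pi*d_eta)` scale (see above).
#' @param svd_tol Relative singular-value cutoff for the pseudo-inverse.
#' @return A [harmonic_order_matrices()] object.
#' @export
b_from_correlation <- function(cv, Fm, normalize = TRUE, svd_tol = 1e-10) {
  stopifnot(inherits(cv, "correlation_volume"))
  if (cv$angular != "eta")
    stop("correlation volume must be in eta parametrization", call. = FALSE)
  n_l <- ncol(Fm)
  if (cv$n_ang < n_l)
    stop("underdetermined system: n_eta < n_l", call. = FALSE)
  if (nrow(Fm) != cv$n_ang)
    stop("Legendre matrix rows must match the eta sampling", call. = FALSE)
  Fp <- pinv_tol(unclass(Fm), svd_tol)
  n_q <- cv$n_q
  B <- array(0, c(n_q, n_q, n_l))
  for (i in seq_len(n_q)) {
    B[i, , ] <- cv$values[i, , ] %*% t(Fp)
  }
  if (normalize) B <- B / (2 * pi * (2 / cv$n_ang))
  harmonic_order_matrices(B, cv$q_max)
}

# Moore-Penrose pseudo-inverse with a relative singular-value cutoff
pinv_tol <- function(A, rel_tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rel_tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Synthesise a correlation volume from harmonic order matrices
#'
#' The forward model inverted by [b_from_correlation()]:
#' `C(q1, q2, eta_k) = 2*pi*d_eta * sum_l F[k, l] B(q1, q2, l)` (the scale
#' factor is dropped when `normalize = FALSE`).
#'
#' @param B A [harmonic_order_matrices()] object.
#' @param Fm A [legendre_matrix()] with at least `B$n_l` columns.
#' @param normalize Match the normalization of [b_from_correlation()].
#' @return A [correlation_volume()] in eta parametrization.
#' @export
correlation_from_b <- function(B, Fm, normalize = TRUE) {
  stopifnot(inherits(B, "harmonic_order_matrices"))
  n_eta <- nrow(Fm)
  Fuse <- unclass(Fm)[, seq_len(B$n_l), drop = FALSE]
  vals <- array(0, c(B$n_q, B$n_q, n_eta))
  for (i in seq_len(B$n_q)) vals[i, , ] <- B$values[i, , ] %*% t(Fuse)
  if (normalize) vals <- vals * (2 * pi * (2 / n_eta))
  correlation_volume(vals, q_max = B$q_max, angular = "eta")
}

#' Zero harmonic order matrices above a degree cutoff
#'
#' @param B A [harmonic_order_matrices()] object.
#' @param l_cut First degree to zero; degrees `0..l_cut-1` survive.
#' @return The truncated object (with `l_max_used = l_cut`).
#' @export
truncate_b <- function(B, l_cut) {
  stopifnot(inherits(B, "harmonic_order_matrices"))
  if (l_cut < 0 || l_cut > B$n_l)
    stop("l_cut outside the allocated degree range", call. = FALSE)
  if (l_cut < B$n_l) B$values[, , (l_cut + 1):B$n_l] <- 0
  B$l_max_used <- l_cut
  B
}
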