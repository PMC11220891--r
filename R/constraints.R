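#' Map Bragg peaks to spherical-grid voxel indices
#'
#' Nearest-voxel assignment in each spherical coordinate:
#' `round(q / dq)` style binning for theta and phi (with phi wraparound) and
#' the radial bin of [correlate_3d()] for q. Peaks that would round to the
#' theta = 0 pole row (whose Driscoll-Healy quadrature weight is exactly
#' zero and which therefore cannot carry intensity) are assigned to the
#' adjacent row; the same applies at the south-pole end, where the grid stops
#' one step short of pi.
#'
#' @param peaks A [bragg_peaks()] list.
#' @param n_q,n_theta Grid dimensions (`n_phi = 2 * n_theta`).
#' @param q_max Radial cutoff.
#' @return Data frame with 1-based indices `iq`, `itheta`, `iphi`.
#' @export
peak_voxel_index <- function(peaks, n_q, n_theta, q_max) {
  n_phi <- 2L * n_theta
  qm <- peaks$q_mag
  th <- acos(pmin(pmax(peaks$qz / qm, -1), 1))
  ph <- atan2(peaks$qy, peaks$qx) %% (2 * pi)
  iq <- q_bin(qm, q_max, n_q)
  ith <- round(th / (pi / n_theta)) %% n_theta + 1L
  ith[th > pi - pi / (2 * n_theta)] <- n_theta  # wrapped south-pole cases
  ith[ith == 1L] <- 2L                          # zero-weight pole row
  iph <- round(ph / (2 * pi / n_phi)) %% n_phi + 1L
  data.frame(iq = iq, itheta = as.integer(ith), iphi = as.integer(iph))
}

# Voxel block (cubic in index space) around each mapped peak: q and theta
# clamped to the valid range, phi wrapped; duplicates from clamping removed.
# Returns a list of lists with $qs (q rows) and $cc (flattened angular
# columns, (iphi-1)*n_theta + itheta).
peak_blocks <- function(vox, width, n_q, n_theta) {
  hw <- (width - 1L) %/% 2L
  n_phi <- 2L * n_theta
  off <- -hw:hw
  lapply(seq_len(nrow(vox)), function(p) {
    qs <- unique(pmax(1L, pmin(n_q, vox$iq[p] + off)))
    ts <- unique(pmax(2L, pmin(n_theta, vox$itheta[p] + off)))
    ps <- (vox$iphi[p] + off - 1L) %% n_phi + 1L
    list(qs = qs, cc = as.vector(outer(ts, (ps - 1L) * n_theta, "+")))
  })
}

#' Binary support mask from known Bragg peak positions
#'
#' Every reflection of the cell inside `q_max` is mapped to its nearest
#' spherical-grid voxel and surrounded by a cubic (in index space) block of
#' `width` voxels per axis. The mask reports the fraction of set voxels and
#' the number of peak pairs whose blocks share at least one voxel (the
#' sampling-collision diagnostic).
#'
#' @param cell A [unit_cell()], or a [bragg_peaks()] list to support directly.
#' @param q_max Radial cutoff.
#' @param n_q,n_theta Grid dimensions.
#' @param width Odd positive block width in voxels.
#' @return A `support_mask` object: logical `n_q x n_theta x n_phi` array
#'   `mask`, the peak voxel table, block list, `fill_fraction` and
#'   `overlap_pairs`.
#' @export
build_support_mask <- function(cell, q_max, n_q, n_theta, width = 5) {
  if (width < 1 || width %% 2 != 1)
    stop("support width must be odd and positive", call. = FALSE)
  peaks <- if (inherits(cell, "bragg_peaks")) cell
           else enumerate_hkl(cell, q_max)
  n_phi <- 2L * n_theta
  vox <- peak_voxel_index(peaks, n_q, n_theta, q_max)
  blocks <- peak_blocks(vox, width, n_q, n_theta)
  mask <- matrix(FALSE, n_q, n_theta * n_phi)
  flat <- lapply(blocks, function(b)
    as.vector(outer(b$qs, (b$cc - 1L) * n_q, "+")))
  for (p in seq_along(blocks)) mask[flat[[p]]] <- TRUE
  # overlapping peak pairs: count via shared voxels
  occ <- unlist(flat)
  dup <- unique(occ[duplicated(occ)])
  overlap_pairs <- 0L
  if (length(dup)) {
    hit <- vapply(flat, function(f) any(f %in% dup), logical(1))
    ids <- which(hit)
    for (a in seq_along(ids)) {
      fa <- flat[[ids[a]]]
      for (b in seq_len(a - 1L)) {
        if (any(fa %in% flat[[ids[b]]])) overlap_pairs <- overlap_pairs + 1L
      }
    }
  }
  structure(list(mask = array(mask, c(n_q, n_theta, n_phi)),
                 vox = vox, blocks = blocks, width = width,
                 n_q = n_q, n_theta = n_theta, n_phi = n_phi,
                 q_max = q_max, peaks = peaks,
                 fill_fraction = mean(mask),
                 overlap_pairs = overlap_pairs),
            class = "support_mask")
}

#' @export
print.support_mask <- function(x, ...) {
  cat(sprintf(
    "support mask: %d peaks, width %d, %.2f%% voxels set, %d overlapping pairs\n",
    nrow(x$vox), x$width, 100 * x$fill_fraction, x$overlap_pairs))
  invisible(x)
}

#' Support + positivity projection
#'
#' `P_s(I) = max(I, 0) * M` elementwise: intensity is retained only inside
#' the support blocks and negative values are set to zero. Exactly
#' idempotent.
#'
#' @param si A [spherical_intensity()].
#' @param mask A [build_support_mask()] result on the same grid.
#' @return The projected [spherical_intensity()].
#' @export
support_project <- function(si, mask) {
  stopifnot(inherits(si, "spherical_intensity"), inherits(mask, "support_mask"))
  if (!all(dim(si$values) == dim(mask$mask)))
    stop("intensity and mask shapes differ", call. = FALSE)
  si$values <- pmax(si$values, 0) * mask$mask
  si
}

#' Per-degree eigendecomposition of harmonic order matrices
#'
#' Spectral decomposition of each symmetric `B(:, :, l)`; negative
#' eigenvalues (numerical noise: B is positive semi-definite in exact
#' arithmetic) are clamped to zero. Eigenvector signs follow a deterministic
#' convention: the largest-magnitude component of each vector is positive.
#'
#' @param B A [harmonic_order_matrices()] object.
#' @param sym_tol Maximum allowed relative asymmetry of each slice.
#' @return An `eigen_basis` object: per degree, orthonormal eigenvector
#'   matrix `u` (columns, descending eigenvalues) and eigenvalues `lambda`.
#' @export
eigendecompose_b <- function(B, sym_tol = 1e-8) {
  stopifnot(inherits(B, "harmonic_order_matrices"))
  scale <- max(abs(B$values), 1e-300)   # near-zero slices carry only noise
  per_l <- lapply(seq_len(B$n_l), function(li) {
    M <- B$values[, , li]
    asym <- max(abs(M - t(M)))
    if (asym > sym_tol * scale)
      stop(sprintf("B slice l=%d is not symmetric (asymmetry %.3g)",
                   li - 1L, asym), call. = FALSE)
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    u <- e$vectors
    for (n in seq_len(ncol(u))) {
      piv <- which.max(abs(u[, n]))
      if (u[piv, n] < 0) u[, n] <- -u[, n]
    }
    list(u = u, lambda = pmax(e$values, 0))
  })
  structure(list(per_l = per_l, n_q = B$n_q, n_l = B$n_l, q_max = B$q_max),
            class = "eigen_basis")
}

#' Expand harmonic coefficients in the eigenvector basis (kappa expansion)
#'
#' `K_{lm,n} = sum_q I_lm(q) u_{l,n}(q)`: the radial profile of each (l, m)
#' coefficient projected onto the eigenvectors of `B(:, :, l)`.
#'
#' @param coeffs A [harmonic_coefficients()] object.
#' @param basis An [eigendecompose_b()] result with matching `n_q`, `n_l`.
#' @return A `kappa_coefficients` object (list of `n_modes x (2l+1)` matrices
#'   per degree).
#' @export
kappa_expand <- function(coeffs, basis) {
  stopifnot(inherits(coeffs, "harmonic_coefficients"),
            inherits(basis, "eigen_basis"))
  if (coeffs$n_q != basis$n_q || coeffs$n_l != basis$n_l)
    stop("coefficient and basis dimensions differ", call. = FALSE)
  K <- lapply(seq_len(coeffs$n_l), function(li) {
    A <- coeffs$coef[, coeffs$idx[, 1] == li - 1L, drop = FALSE]
    t(basis$per_l[[li]]$u) %*% A
  })
  structure(list(K = K, n_l = coeffs$n_l, n_q = coeffs$n_q,
                 q_max = coeffs$q_max),
            class = "kappa_coefficients")
}

#' Rebuild harmonic coefficients from kappa coefficients
#'
#' `I_lm(q) = sum_n K_{lm,n} u_{l,n}(q)`. For coefficients lying in the
#' eigenvector span, `kappa_inverse(kappa_expand(.))` is the identity; in
#' general it is the orthogonal projection onto the span.
#'
#' @param kappa A [kappa_expand()] result.
#' @param basis The matching [eigendecompose_b()] basis.
#' @return A [harmonic_coefficients()] object.
#' @export
kappa_inverse <- function(kappa, basis) {
  stopifnot(inherits(kappa, "kappa_coefficients"),
            inherits(basis, "eigen_basis"))
  n_l <- kappa$n_l
  idx <- do.call(rbind, lapply(0:(n_l - 1), function(l) cbind(l, -l:l)))
  coef <- matrix(0, kappa$n_q, nrow(idx))
  for (li in seq_len(n_l)) {
    coef[, idx[, 1] == li - 1L] <- basis$per_l[[li]]$u %*% kappa$K[[li]]
  }
  harmonic_coefficients(coef, n_l, kappa$q_max)
}

#' Eigenvalue scaling of kappa coefficients (the modulus-constraint core)
#'
#' For each degree l and eigenvector n, the m-vector `K_{l., n}` is rescaled
#' to have norm `sqrt(lambda_{l,n})`:
#' `K'_{lm,n} = sqrt(lambda_{l,n}) * K_{lm,n} / ||K_{l.,n}||`.
#' Coefficients consistent with `B` already satisfy
#' `||K_{l.,n}||^2 = u' B u = lambda_{l,n}`, so they are fixed points. A zero
#' norm or zero eigenvalue yields zero, never NaN.
#'
#' @param kappa A [kappa_expand()] result.
#' @param basis The matching [eigendecompose_b()] basis.
#' @return The rescaled `kappa_coefficients`.
#' @export
scale_kappa <- function(kappa, basis) {
  stopifnot(inherits(kappa, "kappa_coefficients"),
            inherits(basis, "eigen_basis"))
  for (li in seq_len(kappa$n_l)) {
    K <- kappa$K[[li]]
    nrm <- sqrt(rowSums(K^2))
    scl <- ifelse(nrm > 0, sqrt(basis$per_l[[li]]$lambda) / nrm, 0)
    kappa$K[[li]] <- K * scl
  }
  kappa
}

#' Modulus-constraint projection
#'
#' Makes an intensity volume's spherical-harmonic coefficients consistent
#' with the harmonic order matrices, via the eigenvector (kappa) expansion,
#' with both lossy-expansion residual corrections:
#'
#' 1. forward SHT to `I_lm(q)` (band limit `n_l`); the above-band-limit grid
#'    residual `I_Delta = I - synth(I_lm)` is retained;
#' 2. kappa expansion onto the eigenvectors of B; the out-of-span coefficient
#'    residual `I_lm_Delta = I_lm - kappa_inverse(kappa_expand(I_lm))` is
#'    retained;
#' 3. eigenvalue scaling of the kappa coefficients;
#' 4. kappa inverse, plus the coefficient residual (if enabled);
#' 5. inverse SHT, plus the grid residual (if enabled).
#'
#' With both corrections disabled the output is exactly band-limited and
#' lies exactly in the eigenvector span.
#'
#' @param si A [spherical_intensity()].
#' @param basis An [eigendecompose_b()] result (its `n_l` sets the band
#'   limit, at most `n_theta / 2`).
#' @param keep_grid_residual,keep_coeff_residual Toggle the two lossy-path
#'   corrections (both TRUE by default).
#' @return The projected [spherical_intensity()].
#' @export
modulus_project <- function(si, basis, keep_grid_residual = TRUE,
                            keep_coeff_residual = TRUE) {
  stopifnot(inherits(si, "spherical_intensity"), inherits(basis, "eigen_basis"))
  if (basis$n_q != si$n_q)
    stop("basis and intensity q sampling differ", call. = FALSE)
  n_l <- basis$n_l
  bs <- sh_basis(si$n_theta, n_l)
  V <- si_matrix(si)
  coef <- t(bs$Y %*% (t(V) * bs$wvec))          # forward SHT
  low <- coef %*% bs$Y                          # low-pass synthesis
  grid_resid <- V - low
  out_coef <- matrix(0, si$n_q, ncol(coef))
  for (li in seq_len(n_l)) {
    l <- li - 1L
    cols <- which(bs$idx[, 1] == l)
    A <- coef[, cols, drop = FALSE]
    u <- basis$per_l[[li]]$u
    lam <- basis$per_l[[li]]$lambda
    K <- t(u) %*% A
    coeff_resid <- A - u %*% K                  # out-of-span part
    nrm <- sqrt(rowSums(K^2))
    scl <- ifelse(nrm > 0, sqrt(lam) / nrm, 0)
    rebuilt <- u %*% (K * scl)
    if (keep_coeff_residual) rebuilt <- rebuilt + coeff_resid
    out_coef[, cols] <- rebuilt
  }
  Vout <- out_coef %*% bs$Y
  if (keep_grid_residual) Vout <- Vout + grid_resid
  si$values <- array(Vout, dim = dim(si$values))
  si
}
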