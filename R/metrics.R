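#' Extract per-peak intensities from a spherical intensity volume
#'
#' Integrates the volume over each peak's support block. With
#' `weighted = TRUE` (default) the sum is quadrature-weighted, i.e. a true
#' surface-measure integral: a delta peak placed with [place_peaks()] is
#' recovered exactly. `weighted = FALSE` gives the plain voxel sum.
#'
#' @param si A [spherical_intensity()].
#' @param mask A [build_support_mask()] result carrying the peak list and
#'   block geometry.
#' @param weighted Quadrature-weighted (TRUE) or plain (FALSE) block sums.
#' @return The mask's [bragg_peaks()] list with extracted intensities.
#' @export
extract_peak_intensities <- function(si, mask, weighted = TRUE) {
  stopifnot(inherits(si, "spherical_intensity"), inherits(mask, "support_mask"))
  if (!all(dim(si$values) == dim(mask$mask)))
    stop("intensity and mask shapes differ", call. = FALSE)
  V <- si_matrix(si)
  wvec <- sh_basis(si$n_theta)$wvec
  out <- mask$peaks
  out$intensity <- vapply(mask$blocks, function(b) {
    blk <- V[b$qs, b$cc, drop = FALSE]
    if (weighted) sum(sweep(blk, 2, wvec[b$cc], "*")) else sum(blk)
  }, numeric(1))
  out
}

#' Place Bragg peak intensities on a spherical grid
#'
#' The inverse of [extract_peak_intensities()]: each peak's integrated
#' intensity is deposited at its nearest voxel, divided by that voxel's
#' quadrature weight (a delta function carried by a quadrature grid).
#' Peaks sharing a voxel accumulate.
#'
#' @param peaks A [bragg_peaks()] list with intensities.
#' @param n_q,n_theta Grid dimensions.
#' @param q_max Radial cutoff.
#' @return A [spherical_intensity()].
#' @export
place_peaks <- function(peaks, n_q, n_theta, q_max) {
  stopifnot(inherits(peaks, "bragg_peaks"))
  n_phi <- 2L * n_theta
  vox <- peak_voxel_index(peaks, n_q, n_theta, q_max)
  wvec <- sh_basis(n_theta)$wvec
  V <- matrix(0, n_q, n_theta * n_phi)
  cc <- (vox$iphi - 1L) * n_theta + vox$itheta
  for (p in seq_len(nrow(vox))) {
    V[vox$iq[p], cc[p]] <- V[vox$iq[p], cc[p]] +
      peaks$intensity[p] / wvec[cc[p]]
  }
  spherical_intensity(V, q_max, n_theta = n_theta)
}

#' Crystallographic R factor
#'
#' `R = sum | sqrt(I_obs) - sqrt(I_calc) | / sum sqrt(I_obs)`: the standard
#' structure-factor amplitude discrepancy, computed over all Bragg peaks.
#' Zero for identical inputs; sensitive to a relative scale. An optional
#' least-squares amplitude scale (`refine_scale = TRUE`, off by default)
#' rescales `I_calc` before comparison.
#'
#' @param i_obs,i_calc Numeric intensity vectors of equal length (matched
#'   peak order), or [bragg_peaks()] lists.
#' @param refine_scale Apply a least-squares amplitude scale to `i_calc`.
#' @return Dimensionless scalar.
#' @export
r_factor <- function(i_obs, i_calc, refine_scale = FALSE) {
  if (inherits(i_obs, "bragg_peaks")) i_obs <- i_obs$intensity
  if (inherits(i_calc, "bragg_peaks")) i_calc <- i_calc$intensity
  if (length(i_obs) != length(i_calc))
    stop("peak sets differ in length", call. = FALSE)
  a <- sqrt(pmax(i_obs, 0))
  b <- sqrt(pmax(i_calc, 0))
  if (refine_scale) {
    if (sum(b^2) == 0) stop("all-zero calculated amplitudes", call. = FALSE)
    b <- b * sum(a * b) / sum(b^2)
  }
  den <- sum(a)
  if (den == 0) stop("undefined metric: zero observed amplitude sum",
                     call. = FALSE)
  sum(abs(a - b)) / den
}

#' R_iso between independent recoveries
#'
#' Symmetric amplitude discrepancy between two intensity solutions:
#' `R_iso = sum | sqrt(I_i) - sqrt(I_j) | / (0.5 * sum (sqrt(I_i) + sqrt(I_j)))`.
#' Zero for identical runs; low values indicate convergence of independent
#' runs to a uniform solution.
#'
#' @param i_run,j_run Intensity vectors or [bragg_peaks()] lists on the same
#'   peak set.
#' @return Dimensionless scalar.
#' @export
r_iso <- function(i_run, j_run) {
  if (inherits(i_run, "bragg_peaks")) i_run <- i_run$intensity
  if (inherits(j_run, "bragg_peaks")) j_run <- j_run$intensity
  if (length(i_run) != length(j_run))
    stop("peak sets differ in length", call. = FALSE)
  a <- sqrt(pmax(i_run, 0))
  b <- sqrt(pmax(j_run, 0))
  den <- 0.5 * sum(a + b)
  if (den == 0) stop("undefined metric: all-zero amplitudes", call. = FALSE)
  sum(abs(a - b)) / den
}

#' Mean atomic displacement between matched coordinate sets
#'
#' Mean over atoms of the Euclidean distance `|T_i - P_i|` between target
#' and probe positions (Cartesian Angstrom, correspondence by input order).
#'
#' @param target,probe `n x 3` numeric matrices (or data frames) of atom
#'   positions with matched order.
#' @return Mean displacement in Angstrom.
#' @export
mean_atomic_displacement <- function(target, probe) {
  target <- as.matrix(target); probe <- as.matrix(probe)
  if (!all(dim(target) == dim(probe)) || ncol(target) != 3)
    stop("coordinate sets must be matched n x 3 matrices", call. = FALSE)
  mean(sqrt(rowSums((target - probe)^2)))
}
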