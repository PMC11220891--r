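#' Bragg peak list
#'
#' A data frame of Bragg reflections: integer Miller indices, the Cartesian
#' reciprocal vector, its magnitude and an intensity. The class carries the
#' generating `q_max` as an attribute.
#'
#' @param h,k,l Integer Miller indices.
#' @param q_vec n x 3 matrix of Cartesian reciprocal vectors (1/Angstrom).
#' @param intensity Non-negative intensities (arbitrary units); default 0.
#' @param q_max The enumeration cutoff the list was built with.
#' @return A `bragg_peaks` data frame with columns `h, k, l, qx, qy, qz,
#'   q_mag, intensity`.
#' @export
bragg_peaks <- function(h, k, l, q_vec, intensity = 0, q_max = NULL) {
  q_vec <- matrix(q_vec, ncol = 3)
  df <- data.frame(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                   qx = q_vec[, 1], qy = q_vec[, 2], qz = q_vec[, 3],
                   q_mag = sqrt(rowSums(q_vec^2)),
                   intensity = rep_len(intensity, length(h)))
  if (any(df$h == 0 & df$k == 0 & df$l == 0))
    stop("the (0,0,0) reflection is not a Bragg peak", call. = FALSE)
  if (anyDuplicated(df[, c("h", "k", "l")]))
    stop("duplicate (h,k,l) entries", call. = FALSE)
  if (any(df$intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  attr(df, "q_max") <- q_max
  class(df) <- c("bragg_peaks", class(df))
  df
}

#' Enumerate the reciprocal lattice inside a resolution sphere
#'
#' All integer triples (h,k,l), excluding the origin, whose reciprocal vector
#' `h a* + k b* + l c*` has magnitude `<= q_max` (inclusive boundary). The
#' search box per axis is `|h| <= ceiling(q_max * a / (2*pi) * margin)` (the
#' exact bound is `q_max * a / (2*pi)`; the margin is a safety factor for
#' oblique cells), then filtered by the exact magnitude.
#'
#' @param cell A [unit_cell()].
#' @param q_max Cutoff magnitude in 1/Angstrom.
#' @param max_count Error out if the search box exceeds this many candidate
#'   triples (guards accidental huge enumerations).
#' @param margin Index search box safety factor.
#' @return A [bragg_peaks()] data frame with zero intensities.
#' @export
enumerate_hkl <- function(cell, q_max, max_count = 2e7, margin = 1.2) {
  stopifnot(inherits(cell, "unit_cell"))
  if (q_max <= 0) stop("q_max must be positive", call. = FALSE)
  rb <- reciprocal_basis(cell)
  hm <- ceiling(q_max * cell$a / (2 * pi) * margin)
  km <- ceiling(q_max * cell$b / (2 * pi) * margin)
  lm <- ceiling(q_max * cell$c / (2 * pi) * margin)
  ncand <- (2 * hm + 1) * (2 * km + 1) * (2 * lm + 1)
  if (ncand > max_count)
    stop(sprintf("enumeration box holds %.3g candidate triples (> max_count %.3g)",
                 ncand, max_count), call. = FALSE)
  g <- as.matrix(expand.grid(h = -hm:hm, k = -km:km, l = -lm:lm,
                             KEEP.OUT.ATTRS = FALSE))
  qv <- g %*% rb
  qm <- sqrt(rowSums(qv^2))
  keep <- qm <= q_max & !(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0)
  bragg_peaks(g[keep, 1], g[keep, 2], g[keep, 3], qv[keep, , drop = FALSE],
              intensity = 0, q_max = q_max)
}

#' Toy atomic model
#'
#' A minimal scatterer description used by the synthetic structure-factor
#' generator: fractional coordinates in the unit cell and a dimensionless
#' per-atom scattering weight (no form factors, no thermal motion).
#'
#' @param frac n x 3 matrix of fractional coordinates in `[0, 1)`.
#' @param weight Positive scattering weights (recycled).
#' @param element Optional element labels.
#' @return An `atomic_model` data frame with columns `element, x, y, z, weight`.
#' @export
atomic_model <- function(frac, weight = 1, element = "X") {
  frac <- matrix(frac, ncol = 3) %% 1
  n <- nrow(frac)
  if (n < 1) stop("at least one atom required", call. = FALSE)
  weight <- rep_len(weight, n)
  if (any(weight <= 0)) stop("weights must be positive", call. = FALSE)
  structure(data.frame(element = rep_len(element, n),
                       x = frac[, 1], y = frac[, 2], z = frac[, 3],
                       weight = weight),
            class = c("atomic_model", "data.frame"))
}

#' Structure-factor intensities of a toy atomic model
#'
#' Computes `I_hkl = |F_hkl|^2` with
#' `F_hkl = sum_j w_j exp(2 pi i (h x_j + k y_j + l z_j))`
#' for every reflection in `peaks`. Friedel pairs get equal intensity by
#' construction.
#'
#' @param model An [atomic_model()].
#' @param peaks A [bragg_peaks()] list (intensities are overwritten).
#' @return The peak list with intensities filled in.
#' @export
structure_factor_intensities <- function(model, peaks) {
  stopifnot(inherits(model, "atomic_model"), inherits(peaks, "bragg_peaks"))
  # phase matrix: n_peaks x n_atoms
  ph <- outer(peaks$h, model$x) + outer(peaks$k, model$y) +
    outer(peaks$l, model$z)
  fre <- (cos(2 * pi * ph) %*% model$weight)[, 1]
  fim <- (sin(2 * pi * ph) %*% model$weight)[, 1]
  peaks$intensity <- fre^2 + fim^2
  peaks
}
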