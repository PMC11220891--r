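#' Recover Bragg peak intensities with the iterative projection algorithm
#'
#' End-to-end driver: build the modulus constraint from harmonic order
#' matrices (truncated at `l_cut`), the support constraint from the known
#' peak positions, run the ER/HIO recipe from a random start, and extract
#' per-peak intensities from the final iterate.
#'
#' The harmonic order matrices come either from `B` directly (e.g. a fixture
#' bundle's self-consistent matrices) or from a measured correlation volume
#' via [b_from_correlation()].
#'
#' @param peaks [bragg_peaks()] list giving the support positions (its
#'   intensities, if any, are used as the R-factor reference unless
#'   `reference` overrides them).
#' @param B [harmonic_order_matrices()], or NULL to extract from
#'   `correlation`.
#' @param correlation Optional [correlation_volume()] (used when `B` is NULL).
#' @param n_theta Angular sampling of the iterate grid.
#' @param l_cut Harmonic cutoff (degrees `>= l_cut` are zeroed in B).
#' @param support_width Odd support block width.
#' @param recipe Recipe string or [parse_recipe()] object.
#' @param beta HIO feedback parameter (used when `recipe` is a string).
#' @param seed RNG seed for the random initial intensity.
#' @param reference Optional reference intensities for the R-factor trace.
#' @return The [run_recipe()] `run_state`, plus `mask` and `basis`.
#' @export
fxs_recover <- function(peaks, B = NULL, correlation = NULL,
                        n_theta = 32, l_cut = n_theta / 2,
                        support_width = 3, recipe = "40HIO,4ER x3",
                        beta = 0.9, seed = 1, reference = NULL) {
  stopifnot(inherits(peaks, "bragg_peaks"))
  if (is.null(B)) {
    if (is.null(correlation))
      stop("need either B or a correlation volume", call. = FALSE)
    Fm <- legendre_matrix(correlation$n_ang, n_theta / 2)
    B <- b_from_correlation(correlation, Fm)
  }
  q_max <- B$q_max
  if (is.na(q_max)) q_max <- max(peaks$q_mag)
  B <- truncate_b(B, l_cut)
  basis <- eigendecompose_b(B)
  mask <- build_support_mask(peaks, q_max, B$n_q, n_theta, support_width)
  init <- random_init(B$n_q, n_theta, q_max, seed)
  if (is.null(reference) && any(peaks$intensity > 0)) reference <- peaks
  st <- run_recipe(init, if (is.character(recipe)) parse_recipe(recipe, beta)
                         else recipe,
                   basis, mask, reference = reference)
  st$mask <- mask
  st$basis <- basis
  st
}
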