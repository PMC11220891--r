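#' Reference unit cells of the three benchmark crystals
#'
#' The triclinic silver nitrate / ligand complex, the monoclinic
#' aluminophosphate and the orthorhombic dipeptide precursor used as
#' small-molecule benchmarks.
#'
#' @return Named list of three [unit_cell()] objects:
#'   `silver_nitrate`, `aluminophosphate`, `dipeptide`.
#' @export
table1_cells <- function() {
  list(
    silver_nitrate   = unit_cell(5.187, 10.722, 12.636, 82.315, 78.712, 79.952),
    aluminophosphate = unit_cell(7.8783, 10.46890, 16.0680, 90, 95.1470, 90),
    dipeptide        = unit_cell(9.9400, 14.9395, 17.876, 90, 90, 90)
  )
}

# the toy study cells, one per lattice kind (small-molecule scale)
toy_cell <- function(kind) {
  switch(kind,
    cubic        = unit_cell(6.4, 6.4, 6.4, 90, 90, 90),
    triclinic    = unit_cell(5.1, 7.3, 9.2, 81, 96, 103),
    monoclinic   = unit_cell(5.6, 8.1, 10.3, 90, 97, 90),
    orthorhombic = unit_cell(5.9, 8.7, 11.2, 90, 90, 90),
    stop("unknown cell kind", call. = FALSE))
}

#' Synthetic toy-crystal fixture bundle
#'
#' Builds an internally consistent test case for the recovery algorithm: a
#' small unit cell, a random asymmetric atomic motif, its `|F_hkl|^2` Bragg
#' intensities on the enumerated reciprocal lattice, the 3D correlation
#' volume of that peak list, the ground-truth intensity volume on the
#' spherical grid, the harmonic order matrices of that ground truth (the
#' self-consistent modulus-constraint input), and the Bragg support mask.
#'
#' Defaults mirror a desk-scale study: `n_q = 32`, `n_theta = 32`
#' (`n_phi = 64`), `n_eta = 128`, `q_max = 2.2` (about 60 reflections for
#' the triclinic cell: sparse enough that width-3 support blocks do not
#' overlap at `n_q = 32`, entering the overlap regime when `n_q` is halved).
#'
#' @param seed Integer seed controlling the atomic motif.
#' @param n_atoms Number of atoms in the motif (`>= 1`).
#' @param cell_kind One of `"cubic"`, `"triclinic"`, `"monoclinic"`,
#'   `"orthorhombic"`.
#' @param q_max Enumeration cutoff (1/Angstrom).
#' @param n_q,n_theta,n_eta Sampling parameters.
#' @param support_width Odd support block width in voxels.
#' @param max_peaks Error if the enumeration exceeds this count.
#' @return A `fixture_bundle` list: `cell`, `model`, `peaks`,
#'   `correlation`, `truth` (spherical intensity), `B`
#'   (harmonic order matrices of the truth), `mask`, and the sampling
#'   parameters.
#' @export
make_toy_crystal <- function(seed = 1, n_atoms = 5, cell_kind = "triclinic",
                             q_max = 2.2, n_q = 32, n_theta = 32,
                             n_eta = 128, support_width = 3,
                             max_peaks = 20000) {
  stopifnot(n_atoms >= 1)
  cell <- toy_cell(cell_kind)
  peaks <- enumerate_hkl(cell, q_max)
  if (nrow(peaks) > max_peaks)
    stop(sprintf("q_max enumerates %d peaks (> max_peaks %d)",
                 nrow(peaks), max_peaks), call. = FALSE)
  if (nrow(peaks) < 10)
    stop("q_max too small: fewer than 10 reflections", call. = FALSE)
  set.seed(seed)
  model <- atomic_model(matrix(stats::runif(3 * n_atoms), n_atoms, 3),
                        weight = stats::runif(n_atoms, 0.5, 2))
  peaks <- structure_factor_intensities(model, peaks)
  corr <- correlate_3d(peaks, n_q, n_eta, q_max)
  truth <- place_peaks(peaks, n_q, n_theta, q_max)
  B <- b_from_coeffs(sht_forward(truth))
  mask <- build_support_mask(peaks, q_max, n_q, n_theta, support_width)
  structure(list(cell = cell, model = model, peaks = peaks,
                 correlation = corr, truth = truth, B = B, mask = mask,
                 n_q = n_q, n_theta = n_theta, n_eta = n_eta,
                 q_max = q_max, support_width = support_width,
                 seed = seed),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(
    "toy crystal bundle: %d atoms, %d peaks (q_max=%.2f), n_q=%d n_theta=%d\n",
    nrow(x$model), nrow(x$peaks), x$q_max, x$n_q, x$n_theta))
  invisible(x)
}
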