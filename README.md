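# braggfxs

Recovery of crystal Bragg-peak intensities from fluctuation X-ray
scattering (FXS) angular correlation functions, by iterative projection.

## What this solves, and for whom

Serial crystallography needs one indexable crystal per shot; powder
diffraction needs enough crystals for smooth rings. In between sits a large
class of "powder-like" measurements — several small crystals per exposure —
where neither method works. FXS analysis side-steps indexing entirely: the
angular intensity correlation function accumulated over many such exposures,

    C(q1, q2, eta) = sum over ordered peak pairs of I_i * I_j
                     binned by (|q_i|, |q_j|, eta = cos angle(q_i, q_j)),

converges to a rotationally invariant three-dimensional statistic of the
crystal's reciprocal-space intensity. Given `C` and the unit-cell parameters
(hence the positions of all Bragg peaks inside a resolution cutoff
`q_max = 2*pi/d`), this package recovers the individual peak intensities
`I_hkl`, the quantities a crystallographer needs for structure solution.

The engine is an iterative projection algorithm on an intensity volume
`I(q, theta, phi)` sampled on a Driscoll–Healy grid:

* **Modulus constraint** `P_m`: expanding
  `I = sum_lm I_lm(q) Y_lm(theta, phi)`, the correlation determines the
  harmonic order matrices `B(q1, q2, l) = sum_m I_lm(q1) I_lm(q2)` through a
  Legendre decomposition, `C = 2*pi*d_eta * sum_l P_l(eta) B_l`, inverted
  with a Moore–Penrose pseudo-inverse. `P_m` rescales the coefficients of
  the current iterate in the eigenbasis of each `B_l` so their quadratic
  form matches the measurement, with residual corrections for the lossy
  band-limit and eigenspan truncations.
* **Support constraint** `P_s`: intensity is kept only in small voxel blocks
  around the known Bragg positions and negatives are clamped to zero.

The constraints are alternated in error-reduction (ER, `I' = P_s(P_m(I))`)
and hybrid input–output (HIO, negative feedback `I - beta*P_m(I)` outside
the satisfied region, `beta = 0.9`) recipes such as `"20HIO,2ER x5"`.
Recovery quality is measured with the crystallographic R factor on
amplitudes, `R = sum|sqrt(I_obs) - sqrt(I_calc)| / sum sqrt(I_obs)`, the
analogous `R_iso` between independent runs, and the mean atomic displacement
between coordinate sets.

See `vignettes/bragg-intensity-recovery.Rmd` for the full method
description, conventions and sampling analysis.

## Worked example

```r
library(braggfxs)

## reciprocal geometry of the triclinic silver nitrate benchmark cell
cells <- table1_cells()
round(sqrt(rowSums(reciprocal_basis(cells$silver_nitrate)^2)), 4)
#>     a*     b*     c*
#> 1.2499 0.5983 0.5098          # |c*| = 0.51 1/Angstrom, the closest peak spacing
nrow(enumerate_hkl(cells$silver_nitrate, 9))
#> [1] 8324                      # reflections with |q| <= 9 1/Angstrom

## a synthetic 5-atom triclinic crystal, its correlation volume, support
## mask and self-consistent harmonic order matrices
fb <- make_toy_crystal(seed = 42)
fb
#> toy crystal bundle: 5 atoms, 62 peaks (q_max=2.20), n_q=32 n_theta=32
fb$mask
#> support mask: 62 peaks, width 3, 2.36% voxels set, 0 overlapping pairs

## recover the 62 peak intensities from a random start
basis <- eigendecompose_b(truncate_b(fb$B, 16))
init  <- random_init(fb$n_q, fb$n_theta, fb$q_max, seed = 1)
st <- run_recipe(init, parse_recipe("40HIO,4ER x3"), basis, fb$mask,
                 reference = fb$peaks)
st
#> run state: 132 iterations, final R = 0.0329
round(st$trace[c(1, 44, 88, 132)], 4)
#> [1] 0.8595 0.0889 0.0533 0.0329   # R falls from random start to < 0.05
head(cbind(recovered = st$recovered$intensity,
           true = fb$peaks$intensity), 3)
#>      recovered   true
#> [1,]    15.595 15.654
#> [2,]     4.875  5.007
#> [3,]    16.943 15.466
```

The final R factor of 0.033 means the recovered amplitudes deviate from the
ground truth by about 3% on average — comparable to a well-refined
small-molecule data set, and achieved from uniform random noise in 132
iterations. Independent seeds converge to the same solution
(pairwise `r_iso` below 0.05).

A command-line interface (`inst/cli/braggfxs.R`) exposes the same pipeline
as `enumerate`, `simulate`, `correlate`, `recover` and `metrics`
subcommands, with reflection lists as `h k l I` text, volumes in a binary
array container with JSON sidecar headers, YAML run configuration and
JSON-lines iteration telemetry.

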