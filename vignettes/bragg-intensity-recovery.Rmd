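---
title: "Recovering Bragg peak intensities from fluctuation scattering correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering Bragg peak intensities from fluctuation scattering correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braggfxs)
```

## The problem

Fluctuation X-ray scattering (FXS) measures angular correlations between
pairs of points in diffraction patterns, averaged over many exposures of
randomly oriented samples. For an ensemble of crystals, the Bragg peaks of
each exposure correlate into a three-dimensional function
$C(q_1, q_2, \eta)$: the summed products of peak intensities at scattering
magnitudes $q_1$ and $q_2$, binned by the cosine $\eta$ of the angle between
the scattering vectors. The correlation function can be accumulated from
"powder-like" samples — too many crystals per shot for indexing, too few for
clean powder rings — and it retains far more structural information than a
powder pattern.

`braggfxs` implements the inverse step: given $C(q_1, q_2, \eta)$ and the
unit-cell parameters (hence the known positions of all Bragg peaks inside a
resolution cutoff), recover the individual Bragg peak *intensities*. The
engine is an iterative projection algorithm of the Fienup family (error
reduction and hybrid input–output) acting on a 3D reciprocal-space intensity
volume $I(q, \theta, \phi)$, alternating between

* a **modulus constraint** $P_m$ — make the volume's spherical-harmonic
  coefficients consistent with the harmonic order matrices
  $B(q_1, q_2, l)$ extracted from the measured correlation, and
* a **support constraint** $P_s$ — keep intensity only in small blocks
  around the known Bragg positions, and clamp negatives to zero.

## From the correlation to the harmonic order matrices

Expanding $I(q,\theta,\phi) = \sum_{lm} I_{lm}(q)\, Y_{lm}(\theta,\phi)$ in
real orthonormal spherical harmonics (no Condon–Shortley phase; any
consistent orthonormal basis works because only quadratic forms in the
coefficients enter), the correlation decomposes over Legendre polynomials:

$$C(q_1, q_2, \eta) \;=\; c \sum_l P_l(\eta)\, B(q_1, q_2, l), \qquad
B(q_1, q_2, l) = \sum_m I_{lm}(q_1)\, I_{lm}(q_2).$$

`b_from_correlation()` solves this linear system per $(q_1, q_2)$ with the
Moore–Penrose pseudo-inverse of the Legendre design matrix
$F_{kl} = P_l(\eta_k)$ ($F$ is tall: the $\eta$ grid is much finer than the
harmonic cutoff; a relative singular-value cutoff of $10^{-10}$ guards
degenerate grids only).

The constant $c$ deserves a note, because it fixes the absolute scale of the
recovered intensities. The correlator (`correlate_3d()`) is an unnormalised
histogram of $I_i I_j$ products over $\eta$ bins of width
$\Delta\eta = 2/n_\eta$, with self-pairs included (the double sum is
unrestricted; a switch excludes them for sensitivity checks). Writing each
binned pair through the Legendre completeness relation
$\delta(\eta - \eta_0) = \sum_l \tfrac{2l+1}{2} P_l(\eta) P_l(\eta_0)$ and
each product of harmonics at two directions through the addition theorem
$\sum_m Y_{lm}(\Omega_1) Y_{lm}(\Omega_2) = \tfrac{2l+1}{4\pi} P_l(\eta_{12})$
gives $c = 2\pi\,\Delta\eta$, independent of $l$. With this normalisation,
$B$ from the correlation sits on exactly the same scale as $B$ computed from
the coefficients of the gridded peak volume — so the recovered intensities
come out in the same units as the inputs, and the $R$ factor needs no scale
refinement.

## The grid and the delta-function convention

The intensity volume lives on $n_q$ radial shells and a Driscoll–Healy
equiangular grid: $\theta_j = \pi j / n_\theta$, $\phi_k = 2\pi k / n_\phi$
with $n_\phi = 2 n_\theta$. On this grid the spherical-harmonic transform is
exactly invertible for band limits $l < n_l = n_\theta / 2$
(`sht_forward()` / `sht_inverse()`; round-trip error on band-limited fields
is at machine precision, and a Parseval identity test guards the quadrature
weights).

A Bragg peak is a delta function in reciprocal space. A delta carried by a
quadrature grid must be stored as *integrated intensity divided by the
voxel's quadrature weight*, otherwise every surface integral — including the
harmonic analysis the whole method rests on — is wrong by the local weight.
`place_peaks()` and `extract_peak_intensities()` adopt this convention
(extraction is the quadrature-weighted sum over a peak's support block, so
placement followed by extraction is exact; a `weighted = FALSE` option gives
plain voxel sums for diagnostics). Two grid subtleties follow:

* the $\theta = 0$ pole row has Driscoll–Healy weight exactly zero and can
  carry no intensity; peaks rounding to it are assigned to the adjacent row;
* the grid stops one step short of $\theta = \pi$, so near-south-pole peaks
  map to the last row.

## The modulus constraint in detail

For each degree $l$, $B(\cdot,\cdot,l)$ is symmetric positive semi-definite
and is eigendecomposed once (`eigendecompose_b()`; negative eigenvalues are
numerical noise and are clamped at zero; eigenvector signs follow a
deterministic largest-component-positive convention). $P_m$ then runs:

1. forward SHT; the above-band-limit **grid residual**
   $I^\Delta = I - \mathrm{synth}(I_{lm})$ is set aside;
2. $\kappa$ expansion: project each radial profile $I_{lm}(\cdot)$ onto the
   eigenvectors $u_{l,n}$, $K_{lm,n} = \sum_q I_{lm}(q) u_{l,n}(q)$; the
   out-of-span **coefficient residual** is set aside;
3. eigenvalue scaling: each $m$-vector $K_{l\cdot,n}$ is rescaled to norm
   $\sqrt{\lambda_{l,n}}$. Coefficients already consistent with $B$ satisfy
   $\lVert K_{l\cdot,n}\rVert^2 = u^\top B u = \lambda_{l,n}$, so they are
   fixed points — this is the property that pins down the algebraic form of
   the scaling. Zero norms and zero eigenvalues map to zero, never NaN.
4. $\kappa$ inverse plus the coefficient residual; inverse SHT plus the grid
   residual.

Both residual corrections are on by default and individually switchable;
with both off the output is exactly band-limited and lies exactly in the
measured eigenspan (useful for ablation tests). Degrees at and above the
cutoff `l_cut` are zeroed in $B$ before decomposition, which makes $P_m$
annihilate them — at production scale the high-degree matrices carry little
signal and truncating them improves reconstructions.

The support constraint is elementwise: `max(I, 0) * M`, with `M` built from
cubic (in index space) blocks of odd width around each mapped peak
(`build_support_mask()`, which also reports the fraction of set voxels and
the count of overlapping peak-pair blocks — the sampling-collision
diagnostic). $P_s$ is exactly idempotent.

## Iterative schemes

Error reduction composes the projections, $I' = P_s(P_m(I))$, and decreases
its error monotonically into the nearest minimum. Hybrid input–output keeps
the $P_m$ output where the support-and-positivity constraint is already
satisfied (voxels where $P_s(P_m(I)) = P_m(I)$) and applies the negative
feedback $I - \beta P_m(I)$ elsewhere, escaping local minima; $\beta = 0.9$
throughout, following common phase-retrieval practice. Recipes are strings
like `"20HIO,2ER x5"` (`parse_recipe()`), and `run_recipe()` records the
crystallographic $R$ factor of the support-projected iterate at every
iteration when a reference peak list is available. Runs are deterministic
given the seed of the uniform $[-1, 1]$ random start.

Quality metrics follow crystallographic convention on amplitudes:

$$R = \frac{\sum \left|\sqrt{I_\mathrm{obs}} - \sqrt{I_\mathrm{calc}}\right|}
           {\sum \sqrt{I_\mathrm{obs}}}, \qquad
R_\mathrm{iso} = \frac{\sum \left|\sqrt{I_i} - \sqrt{I_j}\right|}
     {\tfrac12 \sum (\sqrt{I_i} + \sqrt{I_j})},$$

plus the mean atomic displacement between matched coordinate sets. No scale
is refined inside $R$ by default (a least-squares amplitude scale is
available but off), since the pipeline's normalisation already preserves
scale end to end.

## Sampling requirements, and what the synthetic fixtures do and do not show

The method's accuracy is governed by two sampling ratios.

**Radial:** the bin width $q_\mathrm{max}/n_q$ must stay below the smallest
reciprocal-axis magnitude or adjacent peaks fall into shared support voxels
and their intensities blend. The package reproduces this regime directly:
halving $n_q$ on the toy fixture until `overlap_pairs > 0` strictly degrades
the median final $R$ (from ~0.04 through ~0.11 to worse than 0.3 in the
acceptance suite).

**Angular:** a voxel subtends $\Delta\theta = \pi/n_\theta$, and
$P_l$ of a voxel-rounded direction differs from $P_l$ of the true direction
by $O(l\,\Delta\theta)$. At production sampling this product is small
($l_\mathrm{cut}\,\Delta\theta \approx 45 \cdot \pi/500 \approx 0.28$), but
at desk scale with $n_\theta = 32$ and $l_\mathrm{cut} = 16$ it is $\pi/2$:
the harmonic order matrices extracted from an exact-geometry correlation
then disagree with those of *any* gridded representation of the same peaks
by 10–25% at high degree, and recoveries through that route plateau near
$R \approx 0.12$ regardless of iteration count. This is a property of the
coarse grid, not of the algorithm.

The synthetic fixture bundles (`make_toy_crystal()`) therefore carry the
**self-consistent** harmonic order matrices of the gridded ground truth
(`b_from_coeffs()` of the placed peak volume) as the modulus-constraint
input, alongside the raw correlation volume of the exact peak list. The
self-consistent route isolates the algorithm's convergence behaviour —
random starts reach $R < 0.05$ and agree pairwise to
$R_\mathrm{iso} < 0.05$ — while the correlation route (tested separately for
two-route consistency on voxel-centre peak sets, where the only error is
$\eta$ binning) shows the honest desk-scale sampling limit. Passing the
desk-scale tests demonstrates correct machinery and the right qualitative
sampling behaviour; it does not demonstrate production-scale accuracy on
experimental correlations, which additionally face convergence of the 2D
pattern average, peak widths, and noise — all outside this package's scope.

The $\eta$ sampling matters too: the histogrammed correlation cannot
localise $\eta$ better than $\Delta\eta$, and $P_l$ varies on scale
$\sim 1/l^2$ near $\eta = \pm 1$ (where self-pairs and Friedel pairs pile
up). The production ratio $n_\eta / l_\mathrm{cut} \approx 128$ is a good
guide; two-route consistency tests here use $n_\eta = 4096$ for
$l_\mathrm{cut} = 8$ and see sub-2% agreement.

## Study conditions of the toy fixture

Chosen once, to mirror a small-molecule crystal at desk scale, and used by
the test suite as fixed study conditions:

| parameter | value | note |
|---|---|---|
| cell | triclinic, $a,b,c = 5.1, 7.3, 9.2$ Å; $\alpha,\beta,\gamma = 81°, 96°, 103°$ | small-molecule scale, no accidental orthogonality |
| motif | 5 atoms, uniform$(0.5, 2)$ weights | point scatterers, $I = |F|^2$ |
| $q_\mathrm{max}$ | 2.2 Å$^{-1}$ | 62 reflections; no support overlap at $n_q = 32$, overlap when $n_q$ is halved twice |
| grid | $n_q = 32$, $n_\theta = 32$, $n_\phi = 64$, $n_\eta = 128$ | seconds-scale full suites |
| support width | 3 voxels | odd, cubic in index space |
| recipe | `"40HIO,4ER x3"`, $\beta = 0.9$ | HIO bulk with ER polishing |

Production-scale defaults ($n_q = 300$, $n_\eta = 5760$, $n_\theta = 500$,
$l_\mathrm{cut} = 45$, width 5, `"120HIO"`) live in the run-configuration
defaults (`validate_config()`); they are hours-scale and meant for the CLI,
not the test suite.

## Numerical choices

* $\eta = \hat q_1 \cdot \hat q_2$ is clamped to $[-1, 1]$; the Dirac delta
  of the correlator is nearest-bin assignment with the top edges of the $q$
  and $\eta$ ranges clamped into the last bin; no occupancy normalisation
  (the unnormalised accumulation is what the $2\pi\,\Delta\eta$ constant
  accounts for).
* The $\psi \leftrightarrow \eta$ conversion (`convert_psi_eta()`) uses the
  Ewald relation $\theta(q) = \pi/2 + \arcsin(q/2k)$, the $|q_1||q_2|$
  curvature factor and the density Jacobian
  $|d\psi/d\eta| = 1/(\sin\theta_1 \sin\theta_2 \sin\psi)$. The smooth
  $\psi$-frame values are interpolated (cubic spline) and the singular
  Jacobian applied analytically at the target grid; outside the
  Ewald-reachable $\eta$ band the output is zero and the interpolant is
  continued constantly so the band edge does not ring into the interior.
  Round trips are exact to $\sim 10^{-10}$ in the flat-Ewald limit and to
  $\sim 10^{-7}$ away from the band edge at finite $k$.
* Ties and edge cases in peak-to-voxel mapping: $\phi$ wraps; $\theta$ and
  $q$ block indices are clamped to the grid and de-duplicated, so boundary
  peaks are never double-counted in masks or extraction.
* `correlate_3d()` accumulates per bin in pair order with double-precision
  grouped sums, which keeps it bit-identical to the brute-force double loop
  (an acceptance-level property).

## Limitations

No space-group or Friedel symmetry constraints are imposed on the intensity
volume (odd-degree harmonics are retained everywhere; for Friedel-symmetric
inputs their correlation content vanishes and the machinery handles them as
zeros). No detector-level (pixel) correlations, polarisation, solid-angle or
background corrections; no peak-width modelling; no structure refinement
downstream of the recovered intensities. The spherical-harmonic basis is
dense, so memory grows as $n_l^2 \times n_\theta n_\phi$ — fine at desk
scale, deliberately simple rather than fast at production scale.
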