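---
title: "Classifying and reconstructing mixed-species XFEL diffraction patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and reconstructing mixed-species XFEL diffraction patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spimix)
```

## The problem

In single-particle imaging (SPI) at an X-ray free-electron laser, isolated
particles are injected into the focused beam in random orientations and each
pulse records one 2D photon-counting diffraction pattern — a curved slice,
cut by the Ewald sphere, through the particle's 3D diffraction intensity
$I(\mathbf q) = |F(\mathbf q)|^2$.  Assembling a 3D intensity requires
estimating the unknown orientation of every pattern.  When the sample is a
*mixture* — an oligomerization equilibrium, or a complex that partially
dissociates after purification — each pattern additionally has an unknown
species label, and single-species orientation-recovery methods break down.

`spimix` implements a template-aided, one-step answer: 3D intensities
computed from *predicted* structures (e.g. structure-prediction models of
each candidate species) serve as initial templates; every pattern is
simultaneously classified, oriented and merged; the merged intensities
replace the templates; and the loop repeats until assignments stabilize.

## The forward model

Each atom is an isotropic Gaussian peak of $Z$ electrons with width
$\sigma$ (default `r default_atom_sigma` Å).  Its Fourier transform is
analytic, so the structure factor of a model at *any* reciprocal point is

$$F(\mathbf q) = e^{-2\pi^2\sigma^2 q^2}\sum_a Z_a\, o_a\,
  e^{2\pi i\, \mathbf q \cdot \mathbf r_a},$$

evaluated exactly at the non-uniform Ewald-sphere coordinates of every
pixel — the closed form plays the role a non-uniform FFT plays for general
densities, with no gridding or interpolation error.  A gridded-density
direct Fourier sum and an FFT route are retained as independent
cross-checks of this kernel.

Reciprocal space uses the crystallographic convention
$q = 2\sin\theta/\lambda$ with resolution $d = 1/q$; with a 1 Å beam, a
512×512 detector with 300 µm pixels reaches 6.6 Å at the edge at 0.5 m
camera length and 13.1 Å at 1 m.

The expected photon count in a pixel of solid angle $\Omega$ is
$\langle k\rangle = J\, r_e^2\, \Omega\, |F(R\mathbf q)|^2$ for fluence $J$
(photons per unit area of the focal spot), classical electron radius
$r_e$, and particle orientation $R$; recorded counts are Poisson draws.
The beam is treated as unpolarized — no polarization factor is applied (a
deliberate simplification; all correlations downstream are
scale-invariant, so a smooth multiplicative factor would not change
classification).  Pulse-to-pulse fluence jitter is Gaussian with relative
width 10% by default, resampled when a draw is non-positive.  A central
square beam stop (10×10 pixels by default) is masked and excluded from
every correlation.

## Orientations

Orientations are intrinsic zyz Euler triples, $R = R_z(\alpha) R_y(\beta)
R_z(\gamma)$, with the beam along $+z$: $(\alpha,\beta)$ choose the slicing
direction and $\gamma$ is an in-plane rotation of the pattern.  Rotating
the particle about the beam axis rotates its Ewald slice rigidly in the
detector plane *exactly*, even on the curved sphere, which is what makes
the polar-coordinate FFT search over $\gamma$ exact rather than a
small-angle approximation.

The search grid covers slice directions with rings of constant $\beta$
spaced by an angular step $\delta$, each carrying
$\lceil 2\pi\sin\beta/\delta\rceil$ equispaced $\alpha$ values — a
quasi-uniform areal density.  **The grid covers the full sphere.**  For
intensities obeying Friedel symmetry the true redundancy of a single
pattern is the in-plane rotation $\gamma \to \gamma+\pi$ (in the
flat-Ewald limit), *not* the antipodal direction: slicing from $-\mathbf m$
yields the mirror image of the slice from $+\mathbf m$, which for a chiral
particle is not reachable by any in-plane rotation.  We verified
numerically that restricting $\beta$ to a half-sphere mis-orients patterns
whose true direction lies in the omitted half (gross orientation errors,
far beyond the grid spacing — the test suite exercises this) and corrupts
the merge, while the full-sphere grid recovers them to within the grid
spacing.  A `half = TRUE` option retains the restricted grid for
experimentation.

## Matching and classification

Per iteration:

1. Patterns and templates are downsampled by two (2×2 photon-count
   summing, preserving Poisson statistics; 2×2×2 intensity mean-binning)
   to raise signal-to-noise and cut cost.
2. Each template is sliced at every grid direction, directly onto a polar
   lattice on the Ewald sphere (trilinear interpolation in the volume).
   The lattice's radial range excludes the beam-stop footprint and the
   detector corners, so its validity mask is angularly invariant by
   construction.
3. Each pattern (bilinearly resampled onto the same polar lattice) is
   correlated with each slice at all `n_theta` in-plane rotations at once:
   every masked sum entering the per-shift Pearson coefficient (joint
   count, both means, both second moments, the cross term) is a cyclic
   cross-correlation along the angular axis, evaluated by FFT.  This
   equals the brute-force shift-and-correlate loop to machine precision —
   a property the test suite asserts directly — and when both validity
   masks are angularly invariant all sums but the cross term collapse to
   constants, which the implementation exploits without changing the
   result.  A correlation only enters the maximization if at least half
   the polar bins are jointly valid (`min_valid_frac`): a Pearson
   coefficient over a small surviving subset, maximized over tens of
   thousands of candidate orientations, is upward-biased by selection, and
   without this minimum-overlap rule slices through sparsely covered
   regions of a freshly merged template can win spuriously and destabilize
   the iteration.
4. For each pattern the best correlation per template, $CC_{\max}(n, m)$,
   is ranked; the pattern is assigned to the top template only if the
   margin over the runner-up *strictly* exceeds a threshold (default
   0.02), otherwise it stays unclassified for this iteration.  Every
   pattern is re-evaluated every iteration, so early mistakes are
   correctable.
5. Classified patterns are merged per class: each unmasked pixel's photon
   count is deposited at its rotated Ewald position $R\mathbf q$ by
   trilinear scattering; voxel values are the weight-normalized *mean* of
   deposits (classes differ 4× in size; a mean keeps intensities on a
   common scale), then Friedel-symmetrized.  Voxels no pattern touched are
   marked missing, and slices through them are invalid in later
   correlations rather than being filled with fabricated intensity.
   Fluence variation is *not* corrected per pattern before merging (a
   config option exists to do so); Pearson correlation is insensitive to
   the smooth radial factors this leaves in the volume.
6. The loop stops when the fraction of patterns whose class or orientation
   changed drops below `stop_tol` (default 0.001) or after `max_iter`
   (default 10) iterations.

Tie-breaks in the argmax resolve to the lowest shift index, then the
lowest grid-direction index, so runs are bit-for-bit reproducible.  A run
in which every pattern is unclassified aborts with a diagnostic (threshold
too strict or templates too poor).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.02 | minimum $CC^1_{\max}-CC^2_{\max}$ margin to classify |
| `delta_deg` | 6 (full scale), 10 (toy) | orientation-grid angular step, degrees |
| `n_theta` | 256 (full scale), 64 (toy) | in-plane angles searched by FFT; power of two |
| `oversample` | 2 | reciprocal-grid voxels per detector pixel step |
| `atom_sigma` | 1.0 Å | Gaussian atom width of the forward model |
| `max_iter`, `stop_tol` | 10, 0.001 | outer-loop control |
| `jitter_sd` | 0.10 | relative pulse-energy jitter |

The reconstruction grid must balance two opposing errors.  It should
sample the finest *speckle* of the largest species with several voxels —
coarser grids blur the merged templates by trilinear smoothing and erode
the classification margins — while every extra factor of refinement
divides the number of Ewald-sheet contributions per voxel by about eight,
eventually leaving merged volumes riddled with missing voxels for a
desk-scale class of ~100 patterns.  `oversample = 2` gives the toy
tetramer ~5 voxels per speckle with adequate sheet coverage; the residual
sparse-slice selection bias is handled by the minimum-overlap rule
(`min_valid_frac`, above).  Polar bins are weighted uniformly in the
correlation (no radial/area weighting).

## The synthetic study and what it does (not) show

The package ships a deterministic toy study mirroring a
monomer/dimer/tetramer mixture: a 50-pseudo-atom blob (9 Å-radius cloud of
carbons), a dimer of two rigid displaced/rotated copies, and a tetramer of
two dimer copies; a 64×64-pixel detector at 1 Å wavelength whose edge
resolution (≈6.3 Å) is a few times the blob feature size; the same 10×10
beam stop, 10% jitter and 0.02 threshold as the full-scale conditions; 600
patterns in a 4:2:1 ratio; templates built from models perturbed by a
smooth correlated displacement field scaled to coordinate RMSDs of 1, 2
and 3 Å (emulating prediction error, which grows with assembly size).
The photon budget (2×10¹⁷ photons per pulse into a 0.1 µm focus) is chosen
so that the central-speckle counts of these ~300–1200-electron toys match
those of full-size proteins under the full-scale beam parameters; with 60×
fewer patterns and 64× fewer pixels than the full-scale study, per-pattern
counts must carry more information for the desk-scale run to sit in the
algorithm's working regime.

Problem sizes were chosen so the complete study — simulation, template
construction, ten iterations, evaluation — runs in roughly ten minutes on
one CPU core: a 10° grid (422 directions), 64 in-plane angles, 94³
reciprocal voxels after downsampling.

What passing the toy study shows: the geometry bookkeeping, the
orientation search, the margin classifier and the merge jointly recover
species labels (≥95% accuracy), orientations (median error below the grid
spacing) and per-species 3D intensities from realistically noisy mixed
data with imperfect templates.  What it does not show: robustness to
background scattering, detector artifacts, polarization, multi-particle
hits, or conformational heterogeneity within a species — none of which the
generator emulates — nor performance at full experimental scale, which
requires the full-scale structure inputs (deposited experimental and predicted models) and multi-hour compute.

## Numerical and metric choices

* **Pearson with masks.** The per-shift renormalization under the joint
  validity mask is exact; a single-normalization FFT correlation would be
  biased wherever masks clip the overlap.  Correlations are undefined
  (treated as $-\infty$) when fewer than two pixels overlap or either side
  has zero variance, with a relative round-off guard on the variance.
* **Interpolation.** Trilinear for volume slicing and merging, bilinear
  for the polar transform.  Exactness is reserved for the forward model
  (analytic structure factors); matching tolerates interpolation, and the
  tests quantify it (noiseless pattern vs. slice of its own volume:
  CC > 0.999).
* **Shell correlation and resolution.** Pearson per spherical shell,
  missing voxels excluded pairwise, shells with fewer than 10 pairs
  reported missing.  The resolution is the first crossing below CC = 0.5
  *after the curve has first attained 0.5* (linear interpolation in $q$):
  the lowest covered shells can sit below 0.5 spuriously — near the beam
  stop they are partially covered, and for a compact particle they carry
  almost no angular contrast, making a thin-shell Pearson ill-conditioned
  — and the quantity of interest is where established correlation is
  lost.  Curves that never drop report the band limit; at the toy's
  64-pixel scale the monomer is in this censored regime, so resolution
  orderings are only meaningful among species whose curves actually decay
  (tetramer vs. dimer reproduces the stronger-signal-resolves-better
  ordering).
* **Merge fidelity.** The merge-reproduces-truth closure is checked at
  full detector sampling and outside the beam-stop annulus: 2×2 binning
  deposits block sums at the binned pixel center (an irreducible ~1-pixel
  smoothing), and shells overlapping the beam-stop exclusion are partially
  covered, so only the un-binned, fully covered region isolates the
  machinery being tested (there, every shell exceeds CC 0.99).
* **Gimbal lock** in Euler recovery resolves to $\gamma = 0$; recovered
  orientations are compared to truth by geodesic SO(3) distance minimized
  over the $\gamma+\pi$ Friedel mate.
* **Missing HDF5.** Pattern sets use a single-file binary container
  (magic + JSON header + little-endian arrays) with the same logical
  layout as the usual HDF5 dataset scheme; volumes are MRC2014 with the
  reciprocal step recorded in the cell fields.

## Known limitations

* Desk-scale stability: with only 600 patterns the iteration is sensitive
  to the quality of the initial templates in a way a tens-of-thousands
  pattern study is not.  Across repeated draws of the 1–3 Å perturbation
  field, some realizations give smoothly converging runs while others
  oscillate around the margin threshold (borderline patterns degrade the
  template they join, pushing their cohort back below the margin) or
  stall with a large unclassified fraction.  The shipped study uses a
  fixed perturbation realization, as befits fixed predicted-structure
  inputs; scaling the pattern count up is the real cure.
* Chirality: intensities are invariant to Friedel inversion, so recovered
  orientations (and hence handedness-sensitive statements) are defined
  only up to the in-plane Friedel mate.
* The iteration refines templates by plain averaging; there is no
  probabilistic weighting of orientation assignments (an EM-style
  extension would replace the argmax with a posterior).
* Phase retrieval (real-space density reconstruction) is out of scope; the
  product is one 3D diffraction intensity per species.
* The threshold schedule is fixed by default; a decaying schedule is
  available but off, the conservative default.
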