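---
title: "Guided PET reconstruction with multi-modality kernels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided PET reconstruction with multi-modality kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trikem)
```

This vignette is the package's account of the science it implements: the
statistical model, the kernel construction, the synthetic phantom that
stands in for scanner data, the numerical choices, and the places where the
design was genuinely open and a decision had to be made.

## The reconstruction model

Emission data are Poisson counts `y_i` with expectation `ȳ_i = [A x]_i +
b_i`, where `x` is the voxelized activity, `A` the acquisition model and
`b` a known additive background (a stand-in for scatter and randoms, which
this package accepts as given rather than estimating). The
maximum-likelihood EM update, run over ordered subsets of projection
angles, is the standard workhorse. Its kernelized form represents the image
through a sparse kernel matrix built from *guidance* images,

$$x = K\alpha, \qquad
\alpha \leftarrow \frac{\alpha}{K^T A_s^T 1}\; K^T A_s^T\!\left(
\frac{y_s}{A_s K \alpha + b_s}\right),$$

so the EM machinery is untouched and all guidance enters through `K`.
Row `j` of `K` holds Gaussian similarity weights between voxel `j` and the
voxels `l` of a fixed axis-aligned window:

$$k_{jl} = \exp\!\left(-\frac{\|d_{jl}\|^2}{2\sigma_d^2}\right)
\prod_m \exp\!\left(-\frac{(g_{mj}-g_{ml})^2}{2\sigma_m^2}\right),$$

with `d_jl` the voxel-index offset and `g_m` the m-th guidance image after
feature normalization (division by its standard deviation over its non-zero
support, so the edge parameters are dimensionless). One guidance image
gives the single-modality kernel (KEM); several are *multiplexed* by
multiplying their feature factors under one shared spatial factor (MKEM).
The *hybrid* variants (HKEM, MHKEM) additionally multiply in a factor of
the same Gaussian form computed from the current image estimate `z = Kα`,
with width `σ_p · sd(z)` (the SD again over the non-zero support), and this
factor is recomputed before **every** sub-iteration. Because the initial
coefficient image is uniform and the kernel rows are normalized, the first
hybrid kernel is exactly the guidance kernel; because the sparsity pattern
is fixed by the window, hybrid re-weighting never changes the structure.

The point of the hybrid factor is robustness: a feature present in the
emission data but absent from the guidance (a "PET-unique" lesion, or a
sphere deliberately erased from the CT prior) is protected by the
image-update factor, whereas plain KEM smooths it toward the guidance. The
acceptance suite demonstrates exactly this mechanism on the phantom.

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `window` | neighborhood size per axis | voxels | 5 |
| `sigma_d` | spatial kernel width | voxel indices | 5 |
| `sigma_c` | CT edge width | SD units | 0.5 (PET stage), 1 (SPECT stage) |
| `sigma_s` | SPECT edge width | SD units | 3 |
| `sigma_p` | iterative (image-update) edge width | SD units | 1 (PET stage), 0.1 (SPECT stage) |
| `n_subsets` | ordered subsets | — | 9 |
| `n_iterations` | full iterations | — | 30 |
| post-filter | Gaussian FWHM on saved OSEM images | mm | 7 |

The kernel defaults are the optimized values for this two-stage setting;
`parameter_sweep()` reproduces the optimization protocol (RC and background
CoV per iteration for each value of one parameter) if different conditions
require re-tuning. The 7-mm post-filter is applied only to the saved images
of the OSEM modes: the comparison design filters OSEM to bring its noise
into the range of the kernel methods, which are left unfiltered.

Small `σ` values make the corresponding edge factor selective (strong edge
preservation, more noise); large values disable it — `σ → ∞` reduces the
hybrid methods to their KEM counterparts and any kernel to the spatial one,
limits that are asserted in the tests.

## The synthetic phantom and what it does (not) emulate

`make_nema_phantom()` builds a NEMA-IEC-style object: six hot spheres of
10–37 mm diameter with equal activity concentration on a 114.4-mm ring, a
51-mm cold cylindrical insert, a cold (zero-activity) water background, and
a water/lung/air attenuation map. Voxelization is by voxel-centre
inclusion; partial-volume effects then arise from the acquisition model's
resolution blur, as in a real scan, not from the voxelizer.
`make_ct_prior()` renders a pseudo-CT with attenuation-derived contrast in
which the spheres are visible structures, and erases a chosen subset of
them (default S2–S4) to create a controlled spatial inconsistency between
guidance and emission truth. `make_spect_guidance()` provides a SPECT-like
guidance image directly (blur, coarse grid, Poisson perturbation) for
experiments that bypass the two-stage pipeline.

The acquisition model is a deliberate desk-scale stand-in: a 2D
parallel-beam projector applied slice-by-slice in 3D, an image-space
Gaussian PSF, full-path attenuation for both PET-like and SPECT-like
geometries (depth-dependent SPECT attenuation and collimator response are
scanner physics beyond this package), a flat additive background, and no
time-of-flight. The algorithms under test are projector-agnostic, so their
relative behavior — guidance benefit, hybrid protection of guidance-absent
features, noise/recovery trade-offs — transfers; absolute recovery values,
artifact morphology from real collimators, and anything involving scatter
spectra do not. Passing tests therefore validate the algorithmic claims on
synthetic data, not scanner-quantitative accuracy.

The default two-stage profile is a 2D slice through the sphere plane:
SPECT stage on a 128² grid at 4 mm with 15-mm system resolution and 5·10⁵
counts, PET stage on a 160² grid at 2 mm with 5-mm resolution, 2·10⁵ counts
and a 20% flat background — an extremely low-statistics PET regime. The
SPECT stage runs 10 full iterations (its HKEM-CT reconstruction is a
guidance image, not an endpoint); the PET stage runs 30 and saves every
iteration for the RC/CoV curves. The test suite uses a 96² / 2.5 mm
single-stage variant of the same phantom where full curves are needed
quickly, and small two-sphere phantoms for unit tests.

## Numerical choices

- **Coordinates.** Voxel indices are 0-based with the centre of voxel
  `(i,j,k)` at `origin + (i+½, j+½, k+½)·voxel_size`; one rule shared by
  the projector, the phantom voxelizer and the VOI masks.
- **Projector.** Joseph's method (march over voxel planes of the dominant
  axis, linear interpolation across, weight = per-plane path length),
  assembled once into a sparse matrix; backprojection is the stored
  transpose, so adjointness holds to machine precision. A consequence of
  any interpolating projector on a voxel grid: projections of a voxelized
  disc agree across arbitrary angles only to the discretization level
  (about a percent here); they agree to machine precision for angle sets
  mapped onto themselves by the grid symmetry, and the tests check both
  regimes.
- **Resolution model and filters.** Separable Gaussian as explicit banded
  matrices with reflective (half-sample symmetric) boundaries, which
  preserves image totals; kernels specified by FWHM in mm and converted per
  axis, so anisotropic grids get isotropic physical blur.
- **Overlap resampling.** Axis-separable interval-overlap weights — exact
  volume-weighted averaging for axis-aligned grids, conserving total
  activity over the common support; used for all grid changes, including
  up-sampling the stage-1 SPECT image to the PET grid.
- **EM degeneracies.** Bins with zero expectation and zero counts
  contribute nothing; zero expectation against positive counts is an
  error; coefficients with zero subset sensitivity are frozen at zero;
  non-negativity is preserved by construction. The Poisson log-likelihood
  is evaluated on the full data at each saved iteration; monotonicity is
  asserted only for full EM (one subset), as OSEM does not guarantee it.
- **Counts calibration.** The simulator scales the noise-free sinogram to
  the requested count level and records the factor; reconstructions are
  divided by it so saved images are in activity-concentration units and RC
  is computed directly against the phantom truth.
- **Matched-CoV comparison.** Nearest saved iteration to the reference CoV,
  ties to the earlier iteration — algorithms are compared at saved
  iterations, not interpolated ones.
- **CoV convention.** Sample (n−1) standard deviation. With the cold
  (zero-activity) background the background VOI mean is small, so CoV
  values are large in absolute terms; they are used as a relative noise
  axis, which is how the matched-CoV comparisons read them.

## Open design points and how they were settled

Three aspects of the kernel are not uniquely determined by the setting and
were fixed as follows. *Multiplexing rule:* modalities compose by
element-wise product of their feature factors under one shared spatial
factor — the simplest associative composition; sum or feature-concatenation
variants would be straightforward alternatives. *Spatial distances* are in
voxel-index units (not mm), making `sigma_d = 5` mean the same fraction of
the window on both stage grids. *Row normalization* is on by default: it
makes a uniform coefficient image reproduce a uniform image exactly, gives
the clean OSEM-reduction property (window 1 ⇒ identity kernel) and the
flux-preservation tests. The feature vector is the single voxel intensity —
no patches — and all window voxels are kept (no k-nearest pruning). The
SPECT-stage and PET-stage reconstructions use identical kernel scheduling;
only the hyper-parameter values differ. In the two-stage pipeline the
guidance chain means "SPECT guidance" is really SPECT/CT information: the
stage-1 image was itself reconstructed with CT guidance.

For the equal-size comparison in the acceptance suite (recovery of a
sphere erased from the CT prior versus an equally sized sphere that was
kept), the standard sphere set contains no two equal diameters, so the test
phantom duplicates the 17-mm sphere and erases one copy — the mechanism
under test is unchanged, but the comparison becomes exact rather than a
comparison across different sphere sizes.

## Limitations

No scanner system models, no time-of-flight, no scatter/randoms estimation
(the additive term is an input), no DICOM, no registration — guidance is
assumed co-registered, which is the premise of a triple-modality scanner.
Patient-cohort statistics are out of scope; the package's evaluation is the
phantom RC/CoV protocol plus reference-image intensity scaling
(`scale_to_reference()`) for externally calibrated comparisons.
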