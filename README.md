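# trikem

Triple-modality kernelized EM reconstruction for emission tomography.

## The problem

Therapeutic radionuclides such as ⁹⁰Y produce very poor emission images:
PET data have extremely low counts and bremsstrahlung SPECT has low
resolution, so activity in small structures is underestimated by
partial-volume effects, which in turn degrades dosimetry and treatment
monitoring. When PET, SPECT and CT of the same object are available, the
side modalities can be used — not as data, but as *guidance* — to shape the
reconstruction of the PET data.

`trikem` implements this family of guided reconstructions for R users:

- **MLEM / OSEM** — the classic Poisson update, with an optional image-space
  PSF resolution model and Gaussian post-filter;
- **KEM** — the image is parameterized as `x = Kα`, where the sparse kernel
  matrix `K` carries Gaussian similarity weights computed from one or more
  guidance images over a fixed voxel neighborhood:

  `k_jl = exp(−‖d_jl‖² / 2σ_d²) · Π_m exp(−(g_mj − g_ml)² / 2σ_m²)`

  with `d_jl` the spatial offset (voxel units) and `g_m` the m-th
  feature-normalized guidance image (CT: `σ_c`, SPECT: `σ_s`);
- **HKEM** — a *hybrid* factor built the same way from the evolving
  reconstruction itself (edge parameter `σ_p`) multiplies the guidance
  kernel before every sub-iteration, protecting features absent from the
  guidance;
- **MHKEM** — several guidance modalities multiplexed into one kernel
  (product of feature factors under a shared spatial factor) plus the
  hybrid factor.

The EM update acts on the coefficients:

`α ← α / (Kᵀ Aᵀ 1) ⊙ Kᵀ Aᵀ ( y / (A K α + b) )`

where `A` is an attenuated parallel-beam projector with an image-space
Gaussian resolution model, `y` the measured sinogram and `b` a known
additive background. With `K = I` this is exactly OSEM.

Everything needed to exercise the method end to end is generated in code: a
digital NEMA-IEC-style phantom (six hot spheres of 10–37 mm on a cold
background with a cold cylindrical insert), its attenuation map,
deliberately manipulated CT priors with selected spheres erased, SPECT-like
guidance, Poisson count simulation, and the evaluation protocol — per-sphere
recovery coefficient `RC = AC_measured / AC_true` and background coefficient
of variation `CoV = 100 · SD/mean`, compared between algorithms at matched
background noise.

## Worked example

Reconstruct simulated low-count PET data of the NEMA-style phantom with and
without SPECT guidance, and compare recovery at matched background noise:

```r
library(trikem)

grid   <- image_grid(c(96, 96), 2.5)            # 2D slice, 2.5 mm voxels
bundle <- make_nema_phantom(nema_phantom_spec(grid))
model  <- system_model(parallel_geometry(96, 96, 2.5), grid,
                       mu = bundle$attenuation, psf_fwhm_mm = 5)
data   <- simulate_counts(bundle$activity, model, total_counts = 2e5,
                          seed = 101, background_fraction = 0.2)
spect  <- make_spect_guidance(bundle, fwhm_mm = 15, counts_scale = 5e5,
                              seed = 102)

hkem <- run_reconstruction(recon_config("hkem-spect"), data, model,
                           guidance = list(spect = spect))
osem <- run_reconstruction(recon_config("osem-nopsf"), data, model)

rep_h <- rc_cov_curve(hkem, bundle)
rep_o <- rc_cov_curve(osem, bundle)
compare_at_matched_cov(rep_h, rep_o,
                       min(max(rep_h$cov_bgr), max(rep_o$cov_bgr)))
```

```
  voi      rc_a      rc_b iteration_a iteration_b    cov_a    cov_b algorithm_a algorithm_b
1  S1 0.7733169 0.4269139          20          30 114.1982 114.5545  hkem-spect  osem-nopsf
2  S2 0.9675636 0.5926071          20          30 114.1982 114.5545  hkem-spect  osem-nopsf
3  S3 0.8827197 0.6639840          20          30 114.1982 114.5545  hkem-spect  osem-nopsf
4  S4 0.9132096 0.7242166          20          30 114.1982 114.5545  hkem-spect  osem-nopsf
5  S5 0.9079322 0.7710513          20          30 114.1982 114.5545  hkem-spect  osem-nopsf
6  S6 0.9477747 0.8385069          20          30 114.1982 114.5545  hkem-spect  osem-nopsf
```

Read: at the iterations where both algorithms reach a background CoV of
about 114%, SPECT-guided HKEM recovers 77% of the true concentration in the
smallest (10 mm) sphere against 43% for unguided, post-filtered OSEM — the
partial-volume loss shrinks for every sphere, most dramatically for the
small ones. `autoplot(dplyr::bind_rows(rep_h, rep_o))` draws the RC-vs-CoV
curves behind this table.

The full two-stage pipeline — SPECT data reconstructed with CT-guided HKEM,
up-sampled by overlap interpolation, then used as PET-stage guidance — is
one call:

```r
res <- run_pipeline(pipeline_config(algorithm = "hkem-spect", seed = 1),
                    out_dir = "out")   # metrics.csv, NIfTI images, manifest
```

A command-line wrapper with `simulate`, `reconstruct`, `analyze`, `sweep`
and `pipeline` subcommands is installed at `inst/cli/trimodal`.

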