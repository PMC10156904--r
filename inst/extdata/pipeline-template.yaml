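# Commented template for the two-stage triple-modality pipeline.
# Every key is optional; omitted keys take the package defaults shown here.
# Use with: trimodal pipeline --config this-file.yaml --out DIR
#       or: run_pipeline(read_pipeline_config("this-file.yaml"))

# PET-stage algorithm: osem-nopsf | osem | kem-ct | kem-spect | mkem |
#                      hkem-ct | hkem-spect | mhkem
algorithm: hkem-spect

# one global seed; per-stage simulation seeds are derived from it
seed: 1

# sphere ids erased from the CT guidance image (spatial inconsistency)
removed_ct_spheres: [S2, S3, S4]

# iteration schedule (full iterations x ordered subsets)
pet_iterations: 30
spect_iterations: 10
n_subsets: 9

# count statistics: expected totals and flat PET background fraction
pet_counts: 2.0e5
spect_counts: 5.0e5
pet_background_fraction: 0.2

# reconstruction grids (2D slice through the sphere plane)
pet_grid_n: 160
pet_voxel_mm: 2
spect_grid_n: 128
spect_voxel_mm: 4

# acquisition: projection angles and system resolution (image-space FWHM)
n_angles: 120
pet_psf_fwhm_mm: 5
spect_psf_fwhm_mm: 15

# PET-stage kernel hyper-parameters (sigmas in SD units, sigma_d in voxels)
pet_kernel:
  window: 5
  sigma_p: 1      # iterative (image-update) edge
  sigma_s: 3      # SPECT edge
  sigma_c: 0.5    # CT edge
  sigma_d: 5      # spatial width
  normalize_rows: true

# SPECT-stage (HKEM-CT) kernel hyper-parameters
spect_kernel:
  window: 5
  sigma_p: 0.1    # iterative (SPECT image-update) edge
  sigma_c: 1
  sigma_d: 5

# phantom geometry; grid defaults to the PET grid
phantom:
  body_radius_mm: 110
  sphere_diameters_mm: [10, 13, 17, 22, 28, 37]
  ring_radius_mm: 57.2
  concentration: 1
  background_concentration: 0   # cold background
  insert_diameter_mm: 51
  bgr_diameter_mm: 37

# keep per-iteration PET images (needed for RC/CoV curves)
save_every_iteration: true
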