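# Two-stage triple-modality pipeline: (1) simulate SPECT-like data and
# reconstruct them with HKEM guided by the (manipulated) CT; (2) up-sample
# that SPECT reconstruction to the PET grid by overlap interpolation and use
# it (and/or the CT) as side information for the PET-stage reconstruction.

#' Pipeline configuration
#'
#' The default desk-scale profile is a 2D slice through the sphere plane:
#' a 128^2 grid at 4 mm for the SPECT stage and a 160^2 grid at 2 mm for the
#' PET stage, 120 angles each, 5e5 SPECT counts and 2e5 PET counts (a very
#' low-statistics PET regime), 9 subsets. Kernel defaults follow the
#' optimized values: SPECT stage `sigma` (iterative) 0.1, CT 1, spatial 5;
#' PET stage `sigma_p` 1, SPECT 3, CT 0.5, spatial 5.
#'
#' @param algorithm PET-stage algorithm (see [recon_config()]).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param removed_ct_spheres sphere ids erased from the CT prior.
#' @param pet_iterations,spect_iterations full iterations per stage.
#' @param n_subsets ordered subsets (both stages).
#' @param pet_counts,spect_counts expected total counts per stage.
#' @param pet_background_fraction flat additive background fraction of the
#'   PET counts (randoms/scatter stand-in).
#' @param pet_grid_n,pet_voxel_mm,spect_grid_n,spect_voxel_mm grid profiles.
#' @param n_angles projection angles (both stages).
#' @param pet_psf_fwhm_mm,spect_psf_fwhm_mm system resolution models.
#' @param phantom optional [nema_phantom_spec()]; default: NEMA layout on
#'   the PET grid.
#' @param pet_kernel,spect_kernel [kernel_spec()]s for the two stages;
#'   defaults are the optimized PET-stage and SPECT-stage values.
#' @param save_every_iteration keep per-iteration PET images (needed for
#'   the RC/CoV report; on by default).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(algorithm = "hkem-spect",
                            seed = 1,
                            removed_ct_spheres = c("S2", "S3", "S4"),
                            pet_iterations = 30,
                            spect_iterations = 10,
                            n_subsets = 9,
                            pet_counts = 2e5,
                            spect_counts = 5e5,
                            pet_background_fraction = 0.2,
                            pet_grid_n = 160, pet_voxel_mm = 2,
                            spect_grid_n = 128, spect_voxel_mm = 4,
                            n_angles = 120,
                            pet_psf_fwhm_mm = 5,
                            spect_psf_fwhm_mm = 15,
                            phantom = NULL,
                            pet_kernel = kernel_spec(),
                            spect_kernel = kernel_spec(window = 5,
                                                       sigma_p = 0.1,
                                                       sigma_c = 1,
                                                       sigma_d = 5),
                            save_every_iteration = TRUE) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  pet_grid <- image_grid(c(pet_grid_n, pet_grid_n), pet_voxel_mm)
  spect_grid <- image_grid(c(spect_grid_n, spect_grid_n), spect_voxel_mm)
  if (is.null(phantom)) phantom <- nema_phantom_spec(pet_grid)
  structure(
    list(algorithm = algorithm, seed = seed,
         removed_ct_spheres = removed_ct_spheres,
         pet_iterations = as.integer(pet_iterations),
         spect_iterations = as.integer(spect_iterations),
         n_subsets = as.integer(n_subsets),
         pet_counts = pet_counts, spect_counts = spect_counts,
         pet_background_fraction = pet_background_fraction,
         pet_grid = pet_grid, spect_grid = spect_grid,
         n_angles = as.integer(n_angles),
         pet_psf_fwhm_mm = pet_psf_fwhm_mm,
         spect_psf_fwhm_mm = spect_psf_fwhm_mm,
         phantom = phantom,
         pet_kernel = pet_kernel, spect_kernel = spect_kernel,
         save_every_iteration = isTRUE(save_every_iteration)),
    class = "pipeline_config"
  )
}

#' Run the two-stage triple-modality pipeline
#'
#' Stages: (1) build the phantom and the manipulated CT prior; (2) simulate
#' SPECT-like counts on the coarse grid and reconstruct them with HKEM-CT;
#' (3) up-sample the SPECT reconstruction to the PET grid with overlap
#' interpolation; (4) simulate PET-like counts; (5) reconstruct with the
#' configured PET-stage algorithm using the stage-1 SPECT image and/or the
#' CT as guidance; (6) compute the RC/CoV report. Fully reproducible given
#' the config's seed. If `out_dir` is given, writes `metrics.csv`, the final
#' images (NIfTI), per-iteration PET images when requested, and a
#' `manifest.json` echoing the configuration and derived seeds.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return List with `bundle`, `ct_prior`, `spect_recon`, `spect_guidance`,
#'   `pet_data`, `pet_recon`, `report`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  seeds <- list(spect = derive_seed(config$seed, 1),
                pet = derive_seed(config$seed, 2))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  bundle <- stage("phantom", make_nema_phantom(config$phantom))
  ct_prior <- stage("phantom",
                    make_ct_prior(bundle, config$removed_ct_spheres))

  needed <- algorithm_guidance(config$algorithm)
  run_spect_stage <- "spect" %in% needed
  spect_recon <- NULL
  spect_guidance <- NULL
  if (run_spect_stage) {
    spect_stage <- stage("spect-simulation", {
      act_s <- resample_overlap(bundle$activity, config$spect_grid)
      mu_s <- resample_overlap(bundle$attenuation, config$spect_grid)
      geom_s <- parallel_geometry(config$n_angles,
                                  config$spect_grid$shape[1],
                                  config$spect_grid$voxel_size[1], "SPECT")
      model_s <- system_model(geom_s, config$spect_grid, mu = mu_s,
                              psf_fwhm_mm = config$spect_psf_fwhm_mm)
      data_s <- simulate_counts(act_s, model_s, config$spect_counts,
                                seed = seeds$spect)
      list(model = model_s, data = data_s)
    })
    spect_recon <- stage("spect-reconstruction", {
      cfg1 <- recon_config("hkem-ct",
                           n_subsets = config$n_subsets,
                           n_iterations = config$spect_iterations,
                           kernel = config$spect_kernel,
                           save_every_iteration = FALSE)
      ct_s <- resample_overlap(ct_prior, config$spect_grid)
      run_reconstruction(cfg1, spect_stage$data, spect_stage$model,
                         guidance = list(ct = ct_s))
    })
    spect_guidance <- stage("spect-upsampling", {
      resample_overlap(spect_recon$final, config$pet_grid)
    })
  }

  pet_stage <- stage("pet-simulation", {
    mu_p <- if (grids_equal(bundle$attenuation$grid, config$pet_grid)) {
      bundle$attenuation
    } else {
      resample_overlap(bundle$attenuation, config$pet_grid)
    }
    act_p <- if (grids_equal(bundle$activity$grid, config$pet_grid)) {
      bundle$activity
    } else {
      resample_overlap(bundle$activity, config$pet_grid)
    }
    geom_p <- parallel_geometry(config$n_angles, config$pet_grid$shape[1],
                                config$pet_grid$voxel_size[1], "PET")
    model_p <- system_model(geom_p, config$pet_grid, mu = mu_p,
                            psf_fwhm_mm = config$pet_psf_fwhm_mm)
    data_p <- simulate_counts(act_p, model_p, config$pet_counts,
                              seed = seeds$pet,
                              background_fraction =
                                config$pet_background_fraction)
    list(model = model_p, data = data_p)
  })

  pet_recon <- stage("pet-reconstruction", {
    cfg2 <- recon_config(config$algorithm,
                         n_subsets = config$n_subsets,
                         n_iterations = config$pet_iterations,
                         kernel = config$pet_kernel,
                         save_every_iteration = config$save_every_iteration)
    guidance <- list()
    if ("ct" %in% needed) guidance$ct <- ct_prior
    if ("spect" %in% needed) guidance$spect <- spect_guidance
    run_reconstruction(cfg2, pet_stage$data, pet_stage$model, guidance)
  })

  report <- stage("metrics", rc_cov_curve(pet_recon, bundle))

  manifest <- list(
    package_version = as.character(utils::packageVersion("trikem")),
    algorithm = config$algorithm,
    seed = config$seed,
    derived_seeds = seeds,
    guidance = as.list(needed),
    removed_ct_spheres = as.list(config$removed_ct_spheres),
    n_subsets = config$n_subsets,
    pet_iterations = config$pet_iterations,
    spect_iterations = config$spect_iterations,
    pet_counts = config$pet_counts,
    spect_counts = config$spect_counts,
    pet_background_fraction = config$pet_background_fraction,
    pet_grid = list(shape = config$pet_grid$shape,
                    voxel_mm = config$pet_grid$voxel_size),
    spect_grid = list(shape = config$spect_grid$shape,
                      voxel_mm = config$spect_grid$voxel_size),
    n_angles = config$n_angles,
    pet_psf_fwhm_mm = config$pet_psf_fwhm_mm,
    spect_psf_fwhm_mm = config$spect_psf_fwhm_mm
  )

  if (!is.null(out_dir)) {
    stage("outputs", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_voi_report(report, file.path(out_dir, "metrics.csv"))
      write_volume(pet_recon$final, file.path(out_dir, "pet_final.nii.gz"))
      write_volume(ct_prior, file.path(out_dir, "ct_prior.nii.gz"))
      if (!is.null(spect_guidance)) {
        write_volume(spect_guidance,
                     file.path(out_dir, "spect_guidance.nii.gz"))
      }
      if (config$save_every_iteration) {
        for (it in seq_along(pet_recon$images)) {
          if (!is.null(pet_recon$images[[it]])) {
            write_volume(pet_recon$images[[it]],
                         file.path(out_dir, sprintf("iter_%03d.nii.gz", it)))
          }
        }
      }
      readr::write_csv(tidy(pet_recon), file.path(out_dir, "loglik.csv"))
      write_truth_json(bundle, file.path(out_dir, "truth.json"))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  list(bundle = bundle, ct_prior = ct_prior, spect_recon = spect_recon,
       spect_guidance = spect_guidance, pet_data = pet_stage$data,
       pet_model = pet_stage$model, pet_recon = pet_recon,
       report = report, manifest = manifest)
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; unknown keys
#' are rejected. An empty file yields the default configuration. A
#' `phantom:` mapping holds [nema_phantom_spec()] arguments (its grid
#' defaults to the PET grid); `pet_kernel:` / `spect_kernel:` mappings hold
#' [kernel_spec()] arguments (`window`, `sigma_p`, `sigma_s`, `sigma_c`,
#' `sigma_d`, `normalize_rows`).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("pet_kernel", "spect_kernel")) {
    if (!is.null(raw[[k]]) && !inherits(raw[[k]], "kernel_spec")) {
      raw[[k]] <- do.call(kernel_spec, raw[[k]])
    }
  }
  if (!is.null(raw$phantom) && !inherits(raw$phantom, "phantom_spec")) {
    ph <- raw$phantom
    if (is.null(ph$grid)) {
      n <- if (is.null(raw$pet_grid_n)) {
        formals(pipeline_config)$pet_grid_n
      } else {
        raw$pet_grid_n
      }
      vox <- if (is.null(raw$pet_voxel_mm)) {
        formals(pipeline_config)$pet_voxel_mm
      } else {
        raw$pet_voxel_mm
      }
      ph$grid <- image_grid(c(n, n), vox)
    }
    if (!is.null(ph$mu)) ph$mu <- unlist(ph$mu)
    raw$phantom <- do.call(nema_phantom_spec, ph)
  }
  do.call(pipeline_config, raw)
}
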