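# Digital NEMA-IEC-style phantom: a water cylinder holding six hot spheres
# on a ring and a cold cylindrical lung-equivalent insert in the centre,
# with a cold (water, zero activity) background. The voxelization rule is
# voxel-centre inclusion against the analytic shapes; partial-volume effects
# then come from the acquisition model's resolution blur, as in a real scan.

#' Specification of a NEMA-IEC-style phantom
#'
#' Defaults reproduce the standard IEC body-phantom layout: six hot spheres
#' of 10-37 mm diameter on a 114.4 mm ring, a 51 mm cold cylindrical insert
#' at the centre, equal activity concentration in all spheres, and a cold
#' (zero-activity) water background. Attenuation defaults are water-like for
#' the body, lung-like for the insert, zero for air (1/mm at 511 keV).
#'
#' @param grid an [image_grid()] (2D slice through the sphere centres, or
#'   3D with the sphere plane at z = 0).
#' @param body_radius_mm radius of the water cylinder.
#' @param sphere_diameters_mm hot-sphere diameters; labelled S1..Sn from the
#'   smallest to the largest diameter.
#' @param ring_radius_mm radius of the circle the sphere centres sit on.
#' @param sphere_angles_deg angular positions of the spheres (degrees, same
#'   order as `sphere_diameters_mm`).
#' @param concentration common activity concentration in the spheres
#'   (arbitrary concentration units).
#' @param background_concentration activity concentration of the body
#'   background (default 0: cold background).
#' @param insert_diameter_mm diameter of the cold central insert; `NULL`
#'   or 0 for no insert.
#' @param mu named attenuation coefficients (1/mm): `body`, `insert`, `air`.
#' @param bgr_diameter_mm diameter of the background reference VOI.
#' @param bgr_center_mm centre of the background VOI; default places it on
#'   the sphere plane between two spheres, clear of insert and body wall.
#' @return An object of class `phantom_spec`.
#' @export
nema_phantom_spec <- function(grid,
                              body_radius_mm = 110,
                              sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
                              ring_radius_mm = 57.2,
                              sphere_angles_deg = seq(0, by = 60,
                                                      length.out = length(sphere_diameters_mm)),
                              concentration = 1,
                              background_concentration = 0,
                              insert_diameter_mm = 51,
                              mu = c(body = 0.0096, insert = 0.0029, air = 0),
                              bgr_diameter_mm = 37,
                              bgr_center_mm = NULL) {
  if (!inherits(grid, "image_grid")) stop("`grid` must be an image_grid",
                                          call. = FALSE)
  nd <- grid_ndim(grid)
  if (any(sphere_diameters_mm <= 0)) stop("sphere diameters must be > 0",
                                          call. = FALSE)
  if (concentration < 0 || background_concentration < 0) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (length(sphere_angles_deg) != length(sphere_diameters_mm)) {
    stop("one angle per sphere required", call. = FALSE)
  }
  theta <- sphere_angles_deg * pi / 180
  centers <- cbind(ring_radius_mm * cos(theta), ring_radius_mm * sin(theta))
  if (nd == 3L) centers <- cbind(centers, 0)
  spheres <- tibble::tibble(
    id = paste0("S", rank(sphere_diameters_mm, ties.method = "first")),
    diameter_mm = sphere_diameters_mm,
    center = lapply(seq_len(nrow(centers)), function(i) centers[i, ]),
    concentration = concentration
  )
  # spheres inside the body
  r <- spheres$diameter_mm / 2
  d_center <- sqrt(centers[, 1]^2 + centers[, 2]^2)
  if (any(d_center + r > body_radius_mm)) {
    stop("sphere(s) ", paste(spheres$id[d_center + r > body_radius_mm],
                             collapse = ", "),
         " extend outside the body", call. = FALSE)
  }
  # pairwise non-overlap (spheres and insert)
  n <- nrow(spheres)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      dij <- sqrt(sum((centers[i, 1:2] - centers[j, 1:2])^2))
      if (dij < r[i] + r[j]) {
        stop("spheres ", spheres$id[i], " and ", spheres$id[j], " overlap",
             call. = FALSE)
      }
    }
  }
  insert_r <- if (is.null(insert_diameter_mm) || insert_diameter_mm <= 0) {
    0
  } else {
    insert_diameter_mm / 2
  }
  if (insert_r > 0 && any(d_center - r < insert_r)) {
    stop("sphere(s) overlap the central insert", call. = FALSE)
  }
  if (is.null(bgr_center_mm)) {
    bgr_radial <- min(85, body_radius_mm - bgr_diameter_mm / 2 - 2)
    bgr_center_mm <- c(bgr_radial * cos(pi / 6), bgr_radial * sin(pi / 6))
    if (nd == 3L) bgr_center_mm <- c(bgr_center_mm, 0)
  }
  structure(
    list(grid = grid,
         body_radius_mm = body_radius_mm,
         spheres = spheres,
         insert_radius_mm = insert_r,
         background_concentration = background_concentration,
         mu = mu,
         bgr_diameter_mm = bgr_diameter_mm,
         bgr_center_mm = bgr_center_mm),
    class = "phantom_spec"
  )
}

# logical mask of voxels whose centre lies inside the analytic sphere
# (circle in 2D): the single voxelization rule shared with VOI masks
sphere_mask_ <- function(grid, center, diameter) {
  coords <- voxel_center_coords(grid)
  nd <- grid_ndim(grid)
  center <- rep_len(center, nd)
  d2 <- Reduce(`+`, lapply(seq_len(nd), function(a) (coords[[a]] - center[a])^2))
  d2 <= (diameter / 2)^2
}

# infinite cylinder along z (disc in 2D), centred on (cx, cy)
cylinder_mask_ <- function(grid, center_xy, radius) {
  coords <- voxel_center_coords(grid)
  d2 <- (coords[[1]] - center_xy[1])^2 + (coords[[2]] - center_xy[2])^2
  d2 <= radius^2
}

#' Build the voxelized phantom, attenuation map and truth VOIs
#'
#' Voxel values equal the sphere concentration inside each sphere (by the
#' voxel-centre rule), the background concentration elsewhere inside the
#' body, and 0 in the insert and outside the body. The attenuation map uses
#' the spec's `mu` values. Truth masks (one per sphere, plus the background
#' VOI) reproduce the true concentrations exactly by construction.
#'
#' @param spec a [nema_phantom_spec()].
#' @return An object of class `phantom_bundle` with elements `activity`,
#'   `attenuation`, `masks` (named list, `S1`..`Sn` and `BGR`), `truth`
#'   (tibble: voi, diameter_mm, true_concentration) and `spec`.
#' @export
make_nema_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be a phantom_spec", call. = FALSE)
  }
  grid <- spec$grid
  body <- cylinder_mask_(grid, c(0, 0), spec$body_radius_mm)
  act <- array(0, dim = grid$shape)
  att <- array(spec$mu[["air"]], dim = grid$shape)
  act[body] <- spec$background_concentration
  att[body] <- spec$mu[["body"]]
  if (spec$insert_radius_mm > 0) {
    ins <- cylinder_mask_(grid, c(0, 0), spec$insert_radius_mm)
    act[ins] <- 0
    att[ins] <- spec$mu[["insert"]]
  }
  masks <- list()
  for (i in seq_len(nrow(spec$spheres))) {
    m <- sphere_mask_(grid, spec$spheres$center[[i]],
                      spec$spheres$diameter_mm[i])
    act[m] <- spec$spheres$concentration[i]
    masks[[spec$spheres$id[i]]] <- m
  }
  masks <- masks[order(names(masks))]
  masks$BGR <- sphere_mask_(grid, spec$bgr_center_mm, spec$bgr_diameter_mm)
  truth <- tibble::tibble(
    voi = spec$spheres$id,
    diameter_mm = spec$spheres$diameter_mm,
    true_concentration = spec$spheres$concentration
  )
  truth <- truth[order(truth$voi), ]
  structure(
    list(activity = volume_image(act, grid, "activity-concentration"),
         attenuation = volume_image(att, grid, "attenuation"),
         masks = masks,
         truth = truth,
         spec = spec),
    class = "phantom_bundle"
  )
}

#' CT-like guidance image with selected spheres removed
#'
#' Produces a pseudo-CT with attenuation-derived contrast (body 1000, insert
#' scaled by its attenuation, air 0) in which the hot spheres are visible as
#' higher-valued structures, emulating the contrast of sphere walls. The
#' listed spheres are replaced by the surrounding body value, introducing a
#' deliberate spatial inconsistency between the guidance and the emission
#' truth; the default removes the mid-sized spheres S2, S3 and S4.
#'
#' @param bundle a [make_nema_phantom()] result.
#' @param removed_sphere_ids character vector of sphere ids to erase from
#'   the CT (e.g. `c("S2", "S3", "S4")`); may be empty.
#' @return A [volume_image()] with `units = "arbitrary"`.
#' @export
make_ct_prior <- function(bundle, removed_sphere_ids = c("S2", "S3", "S4")) {
  if (!inherits(bundle, "phantom_bundle")) {
    stop("`bundle` must be a phantom_bundle", call. = FALSE)
  }
  spec <- bundle$spec
  sphere_ids <- spec$spheres$id
  unknown <- setdiff(removed_sphere_ids, sphere_ids)
  if (length(unknown) > 0L) {
    stop("unknown sphere id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grid <- spec$grid
  body_value <- 1000
  ct <- array(0, dim = grid$shape)
  body <- cylinder_mask_(grid, c(0, 0), spec$body_radius_mm)
  ct[body] <- body_value
  if (spec$insert_radius_mm > 0) {
    ins <- cylinder_mask_(grid, c(0, 0), spec$insert_radius_mm)
    ct[ins] <- body_value * spec$mu[["insert"]] / spec$mu[["body"]]
  }
  kept <- setdiff(sphere_ids, removed_sphere_ids)
  for (id in kept) {
    ct[bundle$masks[[id]]] <- body_value + 100
  }
  volume_image(ct, grid, "arbitrary")
}

#' SPECT-like guidance image from the phantom truth
#'
#' A shortcut for experiments that bypass the full two-stage pipeline: the
#' true activity is blurred to SPECT-like resolution, resampled to a coarse
#' grid, and Poisson-perturbed at the requested count scale. Deterministic
#' given `seed`; as `counts_scale` grows the output converges to the blurred
#' truth.
#'
#' @param bundle a [make_nema_phantom()] result.
#' @param fwhm_mm SPECT-like resolution blur (> 0).
#' @param grid coarse target grid; default halves the native resolution.
#' @param counts_scale total expected counts in the image (> 0).
#' @param seed RNG seed.
#' @return A non-negative [volume_image()] with `units = "arbitrary"`.
#' @export
make_spect_guidance <- function(bundle, fwhm_mm = 15, grid = NULL,
                                counts_scale = 5e5, seed = 1) {
  if (!inherits(bundle, "phantom_bundle")) {
    stop("`bundle` must be a phantom_bundle", call. = FALSE)
  }
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0) {
    stop("`fwhm_mm` must be > 0", call. = FALSE)
  }
  if (!is.finite(counts_scale) || counts_scale <= 0) {
    stop("`counts_scale` must be > 0", call. = FALSE)
  }
  src <- bundle$activity
  if (is.null(grid)) {
    grid <- image_grid(ceiling(src$grid$shape / 2),
                       src$grid$voxel_size * 2,
                       src$grid$origin)
  }
  blurred <- gaussian_filter(src, fwhm_mm)
  coarse <- resample_overlap(blurred, grid)
  total <- sum(coarse$values)
  if (total <= 0) stop("phantom has no activity to image", call. = FALSE)
  scale <- counts_scale / total
  noisy <- with_local_seed(seed, {
    stats::rpois(length(coarse$values), coarse$values * scale) / scale
  })
  volume_image(array(noisy, grid$shape), grid, "arbitrary")
}

#' Write the phantom truth (VOI centres, diameters, concentrations) as JSON
#'
#' @param bundle a [make_nema_phantom()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(bundle, path) {
  spec <- bundle$spec
  truth <- list(
    vois = lapply(seq_len(nrow(spec$spheres)), function(i) {
      list(id = spec$spheres$id[i],
           center_mm = spec$spheres$center[[i]],
           diameter_mm = spec$spheres$diameter_mm[i],
           true_concentration = spec$spheres$concentration[i])
    }),
    background_voi = list(center_mm = spec$bgr_center_mm,
                          diameter_mm = spec$bgr_diameter_mm),
    background_concentration = spec$background_concentration
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
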