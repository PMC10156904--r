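# Parallel-beam acquisition model. The ray operator is assembled once per
# geometry/grid pair as an explicit sparse matrix (Joseph's method: march
# over voxel planes of the dominant axis, linear interpolation along the
# other, weight = intersection length per plane), so the backprojector is
# the exact transpose and adjointness holds to machine precision. In 3D the
# 2D in-plane operator is applied slice by slice; the resolution model is an
# image-space separable Gaussian applied inside both A and its transpose.

#' Parallel-beam acquisition geometry
#'
#' Angles are uniform over `[0, pi)`; radial bins are centred on the origin
#' with the given width. Sinogram rows are angle-major (radial index fastest
#' within an angle).
#'
#' @param n_angles number of projection angles (`>= 1`).
#' @param n_radial number of radial bins.
#' @param bin_width_mm radial bin width in mm (`> 0`).
#' @param modality `"PET"` or `"SPECT"` (informational tag).
#' @return An object of class `parallel_geometry`.
#' @export
parallel_geometry <- function(n_angles, n_radial, bin_width_mm,
                              modality = c("PET", "SPECT")) {
  modality <- match.arg(modality)
  n_angles <- as.integer(n_angles)
  n_radial <- as.integer(n_radial)
  if (n_angles < 1L) stop("`n_angles` must be >= 1", call. = FALSE)
  if (n_radial < 1L) stop("`n_radial` must be >= 1", call. = FALSE)
  if (!is.finite(bin_width_mm) || bin_width_mm <= 0) {
    stop("`bin_width_mm` must be > 0", call. = FALSE)
  }
  structure(
    list(n_angles = n_angles,
         angles = (seq_len(n_angles) - 1L) * pi / n_angles,
         n_radial = n_radial,
         bin_width_mm = bin_width_mm,
         modality = modality),
    class = "parallel_geometry"
  )
}

radial_centers <- function(geometry) {
  (seq_len(geometry$n_radial) - (geometry$n_radial + 1) / 2) *
    geometry$bin_width_mm
}

# sparse ray matrix for a 2D grid: rows angle-major, columns x-fastest
joseph_matrix <- function(geometry, grid) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  dx <- grid$voxel_size[1]; dy <- grid$voxel_size[2]
  ox <- grid$origin[1]; oy <- grid$origin[2]
  xc <- axis_centers(grid, 1)
  yc <- axis_centers(grid, 2)
  s <- radial_centers(geometry)
  nr <- geometry$n_radial
  ti <- tj <- tx <- vector("list", geometry$n_angles)
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    u <- c(cos(th), sin(th))    # detector axis
    v <- c(-sin(th), cos(th))   # ray direction
    if (abs(v[1]) >= abs(v[2])) {
      # march over x planes, interpolate in y
      tpar <- outer(-s * u[1], xc, `+`) / v[1]        # [bin, plane]
      pos <- tpar * v[2] + s * u[2]
      f <- (pos - oy) / dy - 0.5
      plane0 <- rep(0:(nx - 1L), each = nr)
      step <- dx / abs(v[1])
      ortho_n <- ny
      col_of <- function(i_plane, i_ortho) i_plane + i_ortho * nx + 1L
    } else {
      # march over y planes, interpolate in x
      tpar <- outer(-s * u[2], yc, `+`) / v[2]
      pos <- tpar * v[1] + s * u[1]
      f <- (pos - ox) / dx - 0.5
      plane0 <- rep(0:(ny - 1L), each = nr)
      step <- dy / abs(v[2])
      ortho_n <- nx
      col_of <- function(i_plane, i_ortho) i_ortho + i_plane * nx + 1L
    }
    i0 <- floor(f)
    w1 <- f - i0
    bins <- rep(seq_len(nr), times = length(f) / nr)
    rows <- (a - 1L) * nr + bins
    # lower tap
    ok0 <- i0 >= 0 & i0 <= ortho_n - 1L & w1 < 1
    # upper tap
    i1 <- i0 + 1L
    ok1 <- i1 >= 0 & i1 <= ortho_n - 1L & w1 > 0
    ti[[a]] <- c(rows[ok0], rows[ok1])
    tj[[a]] <- c(col_of(plane0[ok0], as.integer(i0[ok0])),
                 col_of(plane0[ok1], as.integer(i1[ok1])))
    tx[[a]] <- c((1 - w1[ok0]) * step, w1[ok1] * step)
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(geometry$n_angles * nr, nx * ny))
}

counts_dim <- function(geometry, grid) {
  if (grid_ndim(grid) == 3L) {
    c(geometry$n_angles, geometry$n_radial, grid$shape[3])
  } else {
    c(geometry$n_angles, geometry$n_radial)
  }
}

# apply ray matrix slice-by-slice: image array -> counts array
ray_forward_ <- function(A, values, geometry, grid) {
  nr <- geometry$n_radial
  na <- geometry$n_angles
  if (grid_ndim(grid) == 2L) {
    p <- as.numeric(A %*% as.numeric(values))
    t(matrix(p, nrow = nr, ncol = na))
  } else {
    nz <- grid$shape[3]
    out <- array(0, c(na, nr, nz))
    for (z in seq_len(nz)) {
      p <- as.numeric(A %*% as.numeric(values[, , z]))
      out[, , z] <- t(matrix(p, nrow = nr, ncol = na))
    }
    out
  }
}

ray_back_ <- function(tA, bins, geometry, grid) {
  nr <- geometry$n_radial
  if (grid_ndim(grid) == 2L) {
    v <- as.numeric(tA %*% as.numeric(t(bins)))
    array(v, grid$shape)
  } else {
    nz <- grid$shape[3]
    out <- array(0, grid$shape)
    for (z in seq_len(nz)) {
      out[, , z] <- as.numeric(tA %*% as.numeric(t(bins[, , z])))
    }
    out
  }
}

blur_values_ <- function(values, blur) {
  if (is.null(blur)) return(values)
  for (a in seq_along(blur)) {
    if (!is.null(blur[[a]])) values <- apply_along_axis(values, blur[[a]], a)
  }
  values
}

# transpose blur; per-axis matrices are applied with t(); symmetric kernels
# with reflective boundaries make this numerically equal to the forward blur,
# but the explicit transpose keeps adjointness exact by construction
blur_values_t_ <- function(values, blur) {
  if (is.null(blur)) return(values)
  for (a in rev(seq_along(blur))) {
    if (!is.null(blur[[a]])) {
      values <- apply_along_axis(values, Matrix::t(blur[[a]]), a)
    }
  }
  values
}

#' Attenuated parallel-beam system model
#'
#' Bundles the geometry, the reconstruction grid, the precomputed sparse ray
#' operator, the per-bin attenuation factors derived from `mu`, and the
#' image-space Gaussian resolution model. The forward model is
#' `y = att * A (B x)` with `B` the resolution blur; the backprojector is its
#' exact transpose.
#'
#' @param geometry a [parallel_geometry()].
#' @param grid the reconstruction [image_grid()] (2D, or 3D processed slice
#'   by slice in-plane).
#' @param mu optional attenuation map (a [volume_image()] in 1/mm on `grid`).
#' @param psf_fwhm_mm image-space resolution FWHM in mm (0 = no resolution
#'   model).
#' @return An object of class `system_model`.
#' @export
system_model <- function(geometry, grid, mu = NULL, psf_fwhm_mm = 0) {
  if (!inherits(geometry, "parallel_geometry")) {
    stop("`geometry` must be a parallel_geometry", call. = FALSE)
  }
  if (!inherits(grid, "image_grid")) {
    stop("`grid` must be an image_grid", call. = FALSE)
  }
  if (!is.finite(psf_fwhm_mm) || psf_fwhm_mm < 0) {
    stop("`psf_fwhm_mm` must be >= 0", call. = FALSE)
  }
  A <- joseph_matrix(geometry, grid)
  tA <- Matrix::t(A)
  blur <- NULL
  if (psf_fwhm_mm > 0) {
    sigma_mm <- fwhm_to_sigma(psf_fwhm_mm)
    blur <- lapply(seq_len(grid_ndim(grid)), function(a) {
      n <- grid$shape[a]
      if (n == 1L) return(NULL)
      gaussian_blur_matrix(n, sigma_mm / grid$voxel_size[a])
    })
  }
  model <- structure(
    list(geometry = geometry, grid = grid, A = A, tA = tA, blur = blur,
         psf_fwhm_mm = psf_fwhm_mm, mu = mu, att = NULL),
    class = "system_model"
  )
  if (!is.null(mu)) {
    model$att <- attenuation_factors(mu, model)
  }
  model
}

#' Per-bin attenuation factors from an attenuation map
#'
#' Computes `exp(-integral of mu along the full line of response)` with the
#' same ray operator as the projector (no resolution blur). The full-path
#' formula is used for both PET-like and SPECT-like geometries; factors lie
#' in `(0, 1]`.
#'
#' @param mu a [volume_image()] of attenuation coefficients (1/mm) on the
#'   model grid.
#' @param model a [system_model()].
#' @return Array of factors shaped like the sinogram.
#' @export
attenuation_factors <- function(mu, model) {
  stopifnot_volume(mu)
  if (!grids_equal(mu$grid, model$grid)) {
    stop("`mu` must live on the model grid", call. = FALSE)
  }
  if (any(mu$values < 0)) stop("`mu` must be non-negative", call. = FALSE)
  line_int <- ray_forward_(model$A, mu$values, model$geometry, model$grid)
  exp(-line_int)
}

#' Forward projection
#'
#' Applies the resolution blur, then the attenuated line integrals. Linear
#' and non-negativity preserving.
#'
#' @param image a [volume_image()] on the model grid.
#' @param model a [system_model()].
#' @return Sinogram array (`n_angles` x `n_radial`, plus a slice axis in 3D).
#' @export
forward_project <- function(image, model) {
  stopifnot_volume(image)
  if (!grids_equal(image$grid, model$grid)) {
    stop("image grid does not match the model grid", call. = FALSE)
  }
  vals <- blur_values_(image$values, model$blur)
  p <- ray_forward_(model$A, vals, model$geometry, model$grid)
  if (!is.null(model$att)) p <- p * model$att
  p
}

#' Backprojection (exact adjoint of the forward projection)
#'
#' @param bins sinogram array shaped like a [forward_project()] result.
#' @param model a [system_model()].
#' @return A [volume_image()] on the model grid.
#' @export
back_project <- function(bins, model) {
  expected <- counts_dim(model$geometry, model$grid)
  bins <- as.array(bins)
  if (!identical(as.integer(dim(bins)), as.integer(expected))) {
    stop("sinogram shape mismatch: expected ",
         paste(expected, collapse = " x "), call. = FALSE)
  }
  if (!is.null(model$att)) bins <- bins * model$att
  vals <- ray_back_(model$tA, bins, model$geometry, model$grid)
  vals <- blur_values_t_(vals, model$blur)
  volume_image(vals, model$grid, "arbitrary")
}

#' Angle-interleaved subset partition
#'
#' Angle `i` (1-based) is assigned to subset `((i - 1) mod n_subsets) + 1`,
#' so subset sizes differ by at most one and each subset samples the angular
#' range evenly. Subsets are processed in index order.
#'
#' @param geometry a [parallel_geometry()].
#' @param n_subsets number of subsets, `1 <= n_subsets <= n_angles`.
#' @return List of integer vectors of angle indices.
#' @export
partition_subsets <- function(geometry, n_subsets) {
  n_subsets <- as.integer(n_subsets)
  if (n_subsets < 1L || n_subsets > geometry$n_angles) {
    stop("`n_subsets` must be between 1 and n_angles (",
         geometry$n_angles, ")", call. = FALSE)
  }
  lapply(seq_len(n_subsets), function(k) {
    seq.int(k, geometry$n_angles, by = n_subsets)
  })
}

#' Sinogram container
#'
#' Measured (or simulated) counts plus the geometry, the additive background
#' term per bin, a subset partition and the calibration factor that converts
#' reconstructed intensities back to activity-concentration units.
#'
#' @param geometry a [parallel_geometry()].
#' @param counts non-negative array (`n_angles` x `n_radial` [x `n_slices`]).
#' @param background additive expected-background term per bin (scalar or
#'   array of the same shape; `>= 0`).
#' @param subsets subset partition (default: a single subset of all angles).
#' @param calibration counts-per-concentration scale recorded by the
#'   simulator (1 for pre-calibrated data).
#' @param seed optional RNG seed used to generate the counts (metadata).
#' @return An object of class `projection_data`.
#' @export
projection_data <- function(geometry, counts, background = 0, subsets = NULL,
                            calibration = 1, seed = NULL) {
  counts <- as.array(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be finite and non-negative", call. = FALSE)
  }
  if (dim(counts)[1] != geometry$n_angles ||
      dim(counts)[2] != geometry$n_radial) {
    stop("`counts` shape does not match the geometry", call. = FALSE)
  }
  if (length(background) == 1L) {
    background <- array(background, dim(counts))
  }
  background <- as.array(background)
  storage.mode(background) <- "double"
  if (!identical(dim(background), dim(counts))) {
    stop("`background` must be scalar or match the counts shape",
         call. = FALSE)
  }
  if (any(background < 0)) stop("`background` must be >= 0", call. = FALSE)
  if (is.null(subsets)) subsets <- partition_subsets(geometry, 1L)
  all_angles <- sort(unlist(subsets))
  if (!identical(as.integer(all_angles), seq_len(geometry$n_angles))) {
    stop("subsets must be disjoint and cover all angles", call. = FALSE)
  }
  structure(
    list(geometry = geometry, counts = counts, background = background,
         subsets = subsets, calibration = calibration, seed = seed),
    class = "projection_data"
  )
}

#' @export
print.projection_data <- function(x, ...) {
  cat("<projection_data> ", x$geometry$modality, ", ",
      x$geometry$n_angles, " angles x ", x$geometry$n_radial, " bins, ",
      length(x$subsets), " subset(s), total counts ",
      format(sum(x$counts), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Simulate Poisson counts through the system model
#'
#' The noise-free sinogram of the activity image is scaled so that the
#' expected total equals `total_counts * (1 - background_fraction)`, a flat
#' background accounting for the remaining fraction is added, and
#' independent Poisson counts are drawn. Deterministic given `seed`.
#'
#' @param activity a [volume_image()] on the model grid.
#' @param model a [system_model()].
#' @param total_counts requested expected total number of counts (`> 0`).
#' @param seed RNG seed.
#' @param background_fraction fraction of `total_counts` contributed by a
#'   flat additive background (scatter/randoms stand-in), in `[0, 1)`.
#' @return A [projection_data()] whose `background` holds the known additive
#'   term and whose `calibration` records the applied count scale.
#' @export
simulate_counts <- function(activity, model, total_counts, seed = 1,
                            background_fraction = 0) {
  if (!is.finite(total_counts) || total_counts <= 0) {
    stop("`total_counts` must be > 0", call. = FALSE)
  }
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("`background_fraction` must be in [0, 1)", call. = FALSE)
  }
  ybar <- forward_project(activity, model)
  tot <- sum(ybar)
  scale <- if (tot > 0) total_counts * (1 - background_fraction) / tot else 1
  b <- array(total_counts * background_fraction / length(ybar), dim(ybar))
  expected <- ybar * scale + b
  y <- with_local_seed(seed, stats::rpois(length(expected), expected))
  projection_data(model$geometry, array(y, dim(expected)), background = b,
                  calibration = scale, seed = seed)
}

#' Sensitivity image (EM denominator)
#'
#' Backprojection of ones over the given subset's angles (attenuation
#' included): `t(A_s) 1`. Zero only where the subset's rays never intersect.
#'
#' @param model a [system_model()].
#' @param subset integer vector of angle indices (default: all angles).
#' @return A [volume_image()].
#' @export
sensitivity <- function(model, subset = NULL) {
  ones <- array(0, counts_dim(model$geometry, model$grid))
  if (is.null(subset)) subset <- seq_len(model$geometry$n_angles)
  if (grid_ndim(model$grid) == 2L) {
    ones[subset, ] <- 1
  } else {
    ones[subset, , ] <- 1
  }
  back_project(ones, model)
}
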