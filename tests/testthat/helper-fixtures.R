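# Shared fixtures: everything is generated in code at test time.

# small two-sphere phantom for fast unit tests
mini_phantom <- function(n = 32, vox = 2.5) {
  g <- image_grid(c(n, n), vox)
  spec <- nema_phantom_spec(
    g,
    body_radius_mm = 35,
    sphere_diameters_mm = c(10, 14),
    ring_radius_mm = 18,
    sphere_angles_deg = c(0, 180),
    insert_diameter_mm = 8,
    bgr_diameter_mm = 10,
    bgr_center_mm = c(-12, -20)
  )
  make_nema_phantom(spec)
}

mini_model <- function(bundle, n_angles = 24, psf_fwhm_mm = 4,
                       attenuated = TRUE) {
  g <- bundle$activity$grid
  geom <- parallel_geometry(n_angles, g$shape[1], g$voxel_size[1])
  system_model(geom, g,
               mu = if (attenuated) bundle$attenuation else NULL,
               psf_fwhm_mm = psf_fwhm_mm)
}

# full six-sphere NEMA-style layout on a compact 2D grid
compact_nema <- function(n = 96, vox = 2.5, ...) {
  g <- image_grid(c(n, n), vox)
  make_nema_phantom(nema_phantom_spec(g, ...))
}

compact_model <- function(bundle, n_angles = 96, psf_fwhm_mm = 5) {
  g <- bundle$activity$grid
  geom <- parallel_geometry(n_angles, g$shape[1], g$voxel_size[1])
  system_model(geom, g, mu = bundle$attenuation, psf_fwhm_mm = psf_fwhm_mm)
}

# independent brute-force kernel oracle: for every voxel j, scan all voxel
# subscripts of the window around j and accumulate Gaussian weights into a
# dense matrix; shares no sparse-assembly machinery with the implementation
dense_kernel_oracle <- function(features, shape, sigmas, sigma_d, window,
                                z = NULL, sigma_p = NULL,
                                normalize_rows = TRUE) {
  nd <- length(shape)
  window <- rep_len(window, nd)
  half <- (window - 1) %/% 2
  n <- prod(shape)
  sub <- arrayInd(seq_len(n), shape)
  strides <- cumprod(c(1, shape[-nd]))
  K <- matrix(0, n, n)
  sdz <- 0
  if (!is.null(z)) {
    support <- z != 0
    sdz <- if (sum(support) >= 2) sd(z[support]) else 0
  }
  for (j in seq_len(n)) {
    rng <- lapply(seq_len(nd), function(a) {
      seq.int(max(1L, sub[j, a] - half[a]), min(shape[a], sub[j, a] + half[a]))
    })
    neigh <- as.matrix(expand.grid(rng))
    lidx <- as.integer(neigh %*% strides) - as.integer(sum(strides)) + 1L
    d2 <- rowSums(sweep(neigh, 2, sub[j, ])^2)
    w <- exp(-d2 / (2 * sigma_d^2))
    for (m in seq_along(features)) {
      w <- w * exp(-(features[[m]][j] - features[[m]][lidx])^2 /
                     (2 * sigmas[m]^2))
    }
    if (!is.null(z) && sdz > 0) {
      w <- w * exp(-(z[j] - z[lidx])^2 / (2 * sigma_p^2 * sdz^2))
    }
    K[j, lidx] <- w
  }
  if (normalize_rows) K <- K / rowSums(K)
  K
}

expect_rel_equal <- function(actual, expected, tol) {
  denom <- max(abs(expected), .Machine$double.xmin)
  expect_lt(max(abs(actual - expected)) / denom, tol)
}
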