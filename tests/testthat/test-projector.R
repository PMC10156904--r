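test_that("forward and back projection are exact adjoints", {
  b <- mini_phantom()
  m <- mini_model(b, n_angles = 20, psf_fwhm_mm = 4, attenuated = TRUE)
  g <- b$activity$grid
  set.seed(123)
  worst <- 0
  for (k in 1:20) {
    x <- volume_image(array(runif(prod(g$shape)), g$shape), g)
    y <- array(runif(m$geometry$n_angles * m$geometry$n_radial),
               c(m$geometry$n_angles, m$geometry$n_radial))
    lhs <- sum(forward_project(x, m) * y)
    rhs <- sum(x$values * back_project(y, m)$values)
    worst <- max(worst, abs(lhs - rhs) / abs(lhs))
  }
  expect_lt(worst, 1e-10)
})

test_that("forward projection is linear and positively homogeneous", {
  b <- mini_phantom()
  m <- mini_model(b, psf_fwhm_mm = 0, attenuated = FALSE)
  g <- b$activity$grid
  zero <- volume_image(array(0, g$shape), g)
  expect_true(all(forward_project(zero, m) == 0))
  set.seed(3)
  x <- volume_image(array(runif(prod(g$shape)), g$shape), g)
  expect_equal(forward_project(volume_image(2.5 * x$values, g), m),
               2.5 * forward_project(x, m), tolerance = 1e-12)
  expect_true(all(forward_project(x, m) >= 0))
  wrong <- volume_image(array(1, c(8, 8)), image_grid(c(8, 8), 2.5))
  expect_error(forward_project(wrong, m), "grid")
})

test_that("a centred disc projects symmetrically", {
  g <- image_grid(c(33, 33), 2)
  disc <- volume_image(
    array(as.numeric(sphere_voi_mask(g, c(0, 0), 40)), g$shape), g
  )
  # exact symmetry for a grid-symmetric angle pair (0 and 90 degrees)
  m2 <- system_model(parallel_geometry(2, 33, 2), g)
  p2 <- forward_project(disc, m2)
  expect_lt(max(abs(p2[1, ] - p2[2, ])) / max(p2), 1e-12)
  # approximate rotational symmetry across a general uniform angle set,
  # probed with a smooth radial profile (voxelized sharp edges agree only
  # to the discretization level)
  cc <- voxel_center_coords(g)
  blob <- volume_image(exp(-(cc[[1]]^2 + cc[[2]]^2) / (2 * 10^2)), g)
  m12 <- system_model(parallel_geometry(12, 33, 2), g)
  p12 <- forward_project(blob, m12)
  spread <- apply(p12, 2, function(col) diff(range(col)))
  expect_lt(max(spread) / max(p12), 0.02)
})

test_that("attenuation factors follow the Beer-Lambert closed form", {
  g <- image_grid(c(24, 24), 2)
  geom <- parallel_geometry(2, 24, 2)  # angles 0 and 90 degrees
  m <- system_model(geom, g)
  mu0 <- volume_image(array(0, g$shape), g, "attenuation")
  expect_true(all(attenuation_factors(mu0, m) == 1))
  # uniform slab: mu = 0.01 / mm over 10 voxel rows (20 mm thick)
  mu_vals <- array(0, g$shape)
  mu_vals[, 8:17] <- 0.01
  mu <- volume_image(mu_vals, g, "attenuation")
  f <- attenuation_factors(mu, m)
  # angle 1 (0 deg): rays run along +y, perpendicular through the slab
  expect_equal(as.numeric(f[1, ]), rep(exp(-0.01 * 20), 24),
               tolerance = 1e-12)
  # doubling mu squares each factor
  f2 <- attenuation_factors(volume_image(2 * mu_vals, g, "attenuation"), m)
  expect_equal(as.numeric(f2), as.numeric(f)^2, tolerance = 1e-12)
  expect_true(all(f > 0 & f <= 1))
})

test_that("subset partition interleaves angles with balanced sizes", {
  geom <- parallel_geometry(120, 64, 4)
  subs <- partition_subsets(geom, 9)
  sizes <- vapply(subs, length, integer(1))
  expect_setequal(unique(sizes), c(14L, 13L))
  expect_equal(sum(sizes == 14L), 3L)
  expect_equal(sort(unlist(subs)), 1:120)
  expect_equal(subs[[1]][1:3], c(1L, 10L, 19L))
  expect_equal(partition_subsets(geom, 1), list(1:120))
  expect_error(partition_subsets(geom, 121), "between")
  expect_error(partition_subsets(geom, 0), "between")
})

test_that("sensitivity decomposes over subsets and respects attenuation", {
  b <- mini_phantom()
  m <- mini_model(b, n_angles = 18, psf_fwhm_mm = 3)
  subs <- partition_subsets(m$geometry, 3)
  s_full <- sensitivity(m)
  s_sum <- Reduce(`+`, lapply(subs, function(s) sensitivity(m, s)$values))
  expect_lt(max(abs(s_full$values - s_sum)) / max(s_full$values), 1e-10)
  # strictly positive well inside the FOV
  centre <- s_full$values[8:24, 8:24]
  expect_true(all(centre > 0))
  # attenuation can only reduce sensitivity
  m0 <- mini_model(b, n_angles = 18, psf_fwhm_mm = 3, attenuated = FALSE)
  expect_true(all(s_full$values <= sensitivity(m0)$values + 1e-12))
})

test_that("count simulation is reproducible and hits the requested total", {
  b <- mini_phantom()
  m <- mini_model(b)
  d1 <- simulate_counts(b$activity, m, 2e5, seed = 4,
                        background_fraction = 0.1)
  d2 <- simulate_counts(b$activity, m, 2e5, seed = 4,
                        background_fraction = 0.1)
  expect_identical(d1$counts, d2$counts)
  expect_lt(abs(sum(d1$counts) - 2e5), 5 * sqrt(2e5))
  # zero activity and zero background give an empty sinogram
  g <- b$activity$grid
  zero <- volume_image(array(0, g$shape), g, "activity-concentration")
  d0 <- simulate_counts(zero, m, 1e4, seed = 1, background_fraction = 0)
  expect_true(all(d0$counts == 0))
  expect_error(simulate_counts(b$activity, m, 0), "> 0")
})

test_that("projection data round-trips through the binary container", {
  b <- mini_phantom()
  m <- mini_model(b)
  d <- simulate_counts(b$activity, m, 5e4, seed = 9,
                       background_fraction = 0.2)
  d$subsets <- partition_subsets(m$geometry, 4)
  path <- tempfile(fileext = ".bin")
  write_projection_data(d, path)
  back <- read_projection_data(path)
  expect_identical(back$counts, d$counts)
  expect_equal(back$background, d$background)
  expect_equal(back$subsets, d$subsets)
  expect_equal(back$calibration, d$calibration)
  expect_equal(back$geometry$n_angles, d$geometry$n_angles)
})

test_that("projection data validates counts and subsets", {
  geom <- parallel_geometry(6, 8, 2)
  expect_error(projection_data(geom, array(-1, c(6, 8))), "non-negative")
  expect_error(projection_data(geom, array(1, c(4, 8))), "shape")
  expect_error(
    projection_data(geom, array(1, c(6, 8)),
                    subsets = list(1:3, 3:6)),
    "disjoint"
  )
})
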