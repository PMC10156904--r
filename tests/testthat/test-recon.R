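test_that("the truth is a fixed point of the noise-free EM update", {
  b <- mini_phantom()
  m <- mini_model(b, psf_fwhm_mm = 3, attenuated = TRUE)
  ybar <- forward_project(b$activity, m)
  d <- projection_data(m$geometry, ybar)
  out <- em_update(b$activity, d, m)
  pos <- b$activity$values > 0
  expect_lt(max(abs(out$values[pos] - b$activity$values[pos]) /
                  b$activity$values[pos]), 1e-12)
  expect_true(all(out$values[!pos] == 0))
})

test_that("one full MLEM iteration conserves counts", {
  b <- mini_phantom()
  m <- mini_model(b, psf_fwhm_mm = 3, attenuated = FALSE)
  d <- simulate_counts(b$activity, m, 1e5, seed = 31)
  g <- b$activity$grid
  init <- volume_image(array(1, g$shape), g)
  x1 <- em_update(init, d, m)
  s <- sensitivity(m)
  expect_lt(abs(sum(s$values * x1$values) - sum(d$counts)) /
              sum(d$counts), 1e-9)
})

test_that("EM update rejects invalid inputs", {
  b <- mini_phantom()
  m <- mini_model(b)
  d <- simulate_counts(b$activity, m, 1e4, seed = 1)
  g <- b$activity$grid
  expect_error(em_update(volume_image(array(-1, g$shape), g), d, m),
               "non-negative")
  # zero expectation against positive counts is a modelling error
  d_bad <- d
  d_bad$counts[] <- 1
  zero <- volume_image(array(0, g$shape), g)
  expect_error(em_update(zero, d_bad, m), "zero expected")
})

test_that("window-1 hybrid KEM reproduces OSEM exactly", {
  b <- mini_phantom()
  m <- mini_model(b, psf_fwhm_mm = 4)
  d <- simulate_counts(b$activity, m, 8e4, seed = 32,
                       background_fraction = 0.1)
  ct <- make_ct_prior(b, character(0))
  cfg_h <- recon_config("hkem-ct", n_subsets = 4, n_iterations = 5,
                        kernel = kernel_spec(window = 1),
                        post_filter_fwhm_mm = 0)
  cfg_o <- recon_config("osem", n_subsets = 4, n_iterations = 5,
                        post_filter_fwhm_mm = 0)
  rh <- run_reconstruction(cfg_h, d, m, guidance = list(ct = ct))
  ro <- run_reconstruction(cfg_o, d, m)
  expect_lt(max(abs(rh$final$values - ro$final$values)) /
              max(ro$final$values), 1e-10)
})

test_that("reconstruction is deterministic and non-negative throughout", {
  b <- mini_phantom()
  m <- mini_model(b)
  d <- simulate_counts(b$activity, m, 5e4, seed = 33,
                       background_fraction = 0.1)
  ct <- make_ct_prior(b, "S1")
  cfg <- recon_config("hkem-ct", n_subsets = 3, n_iterations = 3)
  r1 <- run_reconstruction(cfg, d, m, guidance = list(ct = ct))
  r2 <- run_reconstruction(cfg, d, m, guidance = list(ct = ct))
  expect_identical(r1$final$values, r2$final$values)
  expect_identical(r1$loglik, r2$loglik)
  for (img in r1$images) expect_true(all(img$values >= 0))
})

test_that("MLEM log-likelihood is non-decreasing", {
  b <- mini_phantom()
  m <- mini_model(b, psf_fwhm_mm = 3)
  d <- simulate_counts(b$activity, m, 5e4, seed = 34,
                       background_fraction = 0.1)
  cfg <- recon_config("osem", n_subsets = 1, n_iterations = 20,
                      post_filter_fwhm_mm = 0)
  r <- run_reconstruction(cfg, d, m)
  ll <- r$loglik$logLik
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-length(ll)])))
})

test_that("the sparse KEM update agrees with a dense-matrix oracle", {
  g <- image_grid(c(16, 16), 2)
  spec <- nema_phantom_spec(g, body_radius_mm = 12,
                            sphere_diameters_mm = 8, ring_radius_mm = 0,
                            sphere_angles_deg = 0, insert_diameter_mm = 0,
                            bgr_diameter_mm = 4, bgr_center_mm = c(0, 10))
  b <- make_nema_phantom(spec)
  m <- mini_model(b, n_angles = 12, psf_fwhm_mm = 0, attenuated = FALSE)
  d <- simulate_counts(b$activity, m, 2e4, seed = 35)
  ct <- normalize_feature(make_ct_prior(b, character(0)))
  K <- guidance_kernel(list(ct), sigmas = 1, sigma_d = 5, window = 3)
  set.seed(36)
  alpha <- array(rexp(256), c(16, 16))
  sparse_new <- em_update(alpha, d, m, K = K)
  # dense replay: build A column by column through the model itself
  n <- 256
  A <- matrix(0, 12 * 16, n)
  for (j in seq_len(n)) {
    e <- array(0, c(16, 16)); e[j] <- 1
    A[, j] <- as.numeric(t(forward_project(volume_image(e, g), m)))
  }
  Kd <- as.matrix(K$K)
  y <- as.numeric(t(d$counts))
  bb <- as.numeric(t(d$background))
  av <- as.numeric(alpha)
  ybar <- A %*% (Kd %*% av) + bb
  ratio <- ifelse(ybar > 0, y / ybar, 0)
  num <- t(Kd) %*% (t(A) %*% ratio)
  den <- t(Kd) %*% (t(A) %*% rep(1, nrow(A)))
  dense_new <- ifelse(den > 0, av * num / den, 0)
  expect_lt(max(abs(as.numeric(sparse_new$values) - dense_new)), 1e-10)
})

test_that("uniform-guidance KEM suppresses background noise below OSEM", {
  b <- mini_phantom()
  m <- mini_model(b, psf_fwhm_mm = 0)
  d <- simulate_counts(b$activity, m, 5e4, seed = 37,
                       background_fraction = 0.1)
  g <- b$activity$grid
  flat <- volume_image(array(1, g$shape), g)
  cfg_k <- recon_config("kem-ct", n_subsets = 4, n_iterations = 15)
  cfg_o <- recon_config("osem-nopsf", n_subsets = 4, n_iterations = 15,
                        post_filter_fwhm_mm = 0)
  rk <- run_reconstruction(cfg_k, d, m, guidance = list(ct = flat))
  ro <- run_reconstruction(cfg_o, d, m)
  cov_k <- coefficient_of_variation(rk$final, b$masks$BGR)
  cov_o <- coefficient_of_variation(ro$final, b$masks$BGR)
  expect_lt(cov_k, cov_o)
})

test_that("missing guidance images are reported by name", {
  b <- mini_phantom()
  m <- mini_model(b)
  d <- simulate_counts(b$activity, m, 1e4, seed = 38)
  cfg <- recon_config("mhkem")
  expect_error(run_reconstruction(cfg, d, m, guidance = list()),
               "spect, ct")
})

test_that("reference scaling replays its definition", {
  set.seed(39)
  g <- image_grid(c(12, 12), 2)
  img <- volume_image(array(runif(144), c(12, 12)), g)
  ref <- volume_image(2 * img$values, g)
  out <- scale_to_reference(img, ref)
  expect_equal(out$factor, 2)
  expect_equal(scale_to_reference(img, img)$factor, 1)
  ref2 <- volume_image(array(rexp(144), c(12, 12)), g)
  out2 <- scale_to_reference(img, ref2)
  active <- ref2$values > 0.01 * max(ref2$values)
  idx <- which(active, arr.ind = TRUE)
  box <- array(FALSE, c(12, 12))
  box[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2])] <- TRUE
  expect_lt(abs(sum(out2$image$values[box]) - sum(ref2$values[box])) /
              sum(ref2$values[box]), 1e-12)
  zero <- volume_image(array(0, c(12, 12)), g)
  expect_error(scale_to_reference(zero, ref), "zero")
})

test_that("tidy and glance summarize a reconstruction", {
  b <- mini_phantom()
  m <- mini_model(b)
  d <- simulate_counts(b$activity, m, 2e4, seed = 40)
  r <- run_reconstruction(recon_config("osem", n_iterations = 2,
                                       n_subsets = 2), d, m)
  td <- tidy(r)
  expect_equal(nrow(td), 2L)
  expect_named(td, c("algorithm", "iteration", "logLik"))
  gl <- glance(r)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$algorithm, "osem")
})
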