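test_that("sphere VOI masks follow the voxel-centre rule", {
  g <- image_grid(c(21, 21), 2)
  # tiny VOI centred on a voxel centre: exactly that voxel
  m1 <- sphere_voi_mask(g, c(0, 0), 1.5)
  expect_equal(sum(m1), 1L)
  # 37 mm sphere on a 1 mm grid: voxel count within 3% of analytic volume
  g3 <- image_grid(c(40, 40, 40), 1)
  m37 <- sphere_voi_mask(g3, c(0, 0, 0), 37)
  expect_lt(abs(sum(m37) - 4 / 3 * pi * 18.5^3) / (4 / 3 * pi * 18.5^3),
            0.03)
  expect_error(sphere_voi_mask(g, c(500, 500), 3), "no voxel")
  expect_error(sphere_voi_mask(g, c(0, 0), -1), "> 0")
})

test_that("recovery coefficient is the VOI mean over the truth", {
  g <- image_grid(c(10, 10), 1)
  mask <- sphere_voi_mask(g, c(0, 0), 5)
  truth <- array(8.4, c(10, 10))
  expect_equal(recovery_coefficient(truth, mask, 8.4), 1)
  expect_equal(recovery_coefficient(array(0, c(10, 10)), mask, 8.4), 0)
  expect_equal(recovery_coefficient(array(4.2, c(10, 10)), mask, 8.4), 0.5)
  expect_error(recovery_coefficient(truth, mask, 0), "> 0")
  expect_error(recovery_coefficient(truth, array(FALSE, c(10, 10)), 1),
               "empty")
})

test_that("coefficient of variation matches its definition", {
  g <- image_grid(c(2, 1), 1)
  expect_equal(coefficient_of_variation(array(7, c(4, 1)),
                                        rep(TRUE, 4)), 0)
  vals <- array(c(3, 5), c(2, 1))
  expect_equal(coefficient_of_variation(vals, c(TRUE, TRUE)),
               100 * sqrt(2) / 4, tolerance = 1e-12)
  # scale invariance
  expect_equal(coefficient_of_variation(10 * vals, c(TRUE, TRUE)),
               coefficient_of_variation(vals, c(TRUE, TRUE)))
  expect_error(coefficient_of_variation(array(c(-1, 1), c(2, 1)),
                                        c(TRUE, TRUE)), "zero mean")
  expect_error(coefficient_of_variation(vals, c(TRUE, FALSE)), "at least 2")
})

test_that("the truth image has RC exactly 1 in every sphere VOI", {
  b <- compact_nema()
  g <- b$activity$grid
  for (i in seq_len(nrow(b$spec$spheres))) {
    mask <- sphere_voi_mask(g, b$spec$spheres$center[[i]],
                            b$spec$spheres$diameter_mm[i])
    rc <- recovery_coefficient(b$activity, mask,
                               b$spec$spheres$concentration[i])
    expect_lt(abs(rc - 1), 1e-12)
  }
})

test_that("RC/CoV curves have one row per iteration and VOI", {
  b <- mini_phantom()
  m <- mini_model(b)
  d <- simulate_counts(b$activity, m, 5e4, seed = 51,
                       background_fraction = 0.1)
  r <- run_reconstruction(recon_config("osem", n_subsets = 3,
                                       n_iterations = 4), d, m)
  rep <- rc_cov_curve(r, b)
  expect_equal(nrow(rep), 4L * nrow(b$truth))
  expect_setequal(unique(rep$iteration), 1:4)
  # replay from saved NIfTI equals the in-memory computation
  dir <- tempfile(); dir.create(dir)
  for (it in seq_along(r$images)) {
    write_volume(r$images[[it]], file.path(dir, sprintf("it%02d.nii.gz", it)))
  }
  reread <- lapply(sort(list.files(dir, full.names = TRUE)), read_volume)
  r2 <- r
  r2$images <- reread
  r2$final <- reread[[length(reread)]]
  rep2 <- rc_cov_curve(r2, b)
  expect_equal(rep2$rc, rep$rc)
  expect_equal(rep2$cov_bgr, rep$cov_bgr)
})

test_that("constant image series yields constant report rows", {
  b <- mini_phantom()
  g <- b$activity$grid
  img <- volume_image(array(runif(prod(g$shape), 1, 2), g$shape), g)
  r <- structure(
    list(images = list(img, img, img), final = img,
         loglik = tibble::tibble(iteration = 1:3, logLik = 0),
         algorithm = "osem",
         config = recon_config("osem", n_iterations = 3)),
    class = "recon_result"
  )
  rep <- rc_cov_curve(r, b)
  per_voi <- split(rep$rc, rep$voi)
  for (v in per_voi) expect_equal(length(unique(v)), 1L)
})

test_that("matched-CoV selection picks the nearest earlier iteration", {
  mk <- function(algorithm, covs, rcs) {
    out <- tibble::tibble(
      algorithm = algorithm,
      iteration = rep(seq_along(covs), each = 1L),
      voi = "S1",
      rc = rcs,
      cov_bgr = covs
    )
    class(out) <- c("voi_report", class(out))
    out
  }
  a <- mk("A", c(10, 20, 30), c(0.5, 0.6, 0.7))
  b <- mk("B", c(12, 22, 32), c(0.4, 0.5, 0.6))
  # exact hit
  out <- compare_at_matched_cov(a, b, 20)
  expect_equal(out$iteration_a, 2L)
  # identical reports -> identical selections
  out2 <- compare_at_matched_cov(a, a, 29)
  expect_equal(out2$iteration_a, out2$iteration_b)
  # tie midway between two iterations goes to the earlier one
  tie <- compare_at_matched_cov(mk("A", c(10, 20), c(1, 2)),
                                mk("B", c(10, 20), c(1, 2)), 15)
  expect_equal(tie$iteration_a, 1L)
  expect_error(compare_at_matched_cov(a, b, 500), "outside both")
})

test_that("parameter sweeps are order-independent and hit the KEM limit", {
  b <- mini_phantom()
  m <- mini_model(b)
  d <- simulate_counts(b$activity, m, 5e4, seed = 52,
                       background_fraction = 0.1)
  ct <- make_ct_prior(b, character(0))
  guidance <- list(ct = ct)
  cfg <- recon_config("hkem-ct", n_subsets = 3, n_iterations = 3)
  tab <- parameter_sweep(cfg, "sigma_p", c(0.1, 1e6), d, m, guidance, b)
  tab_rev <- parameter_sweep(cfg, "sigma_p", c(1e6, 0.1), d, m, guidance, b)
  expect_equal(dplyr::arrange(tibble::as_tibble(tab), value, iteration, voi),
               dplyr::arrange(tibble::as_tibble(tab_rev), value, iteration,
                              voi))
  # single value equals a plain run
  one <- parameter_sweep(cfg, "sigma_p", 0.5, d, m, guidance, b)
  cfg05 <- cfg
  cfg05$kernel$sigma_p <- 0.5
  direct <- rc_cov_curve(run_reconstruction(cfg05, d, m, guidance), b)
  expect_equal(one$rc, direct$rc)
  # sigma_p -> infinity reproduces guidance-only KEM; sigma_p = 0.1 differs
  kem <- rc_cov_curve(
    run_reconstruction(recon_config("kem-ct", n_subsets = 3,
                                    n_iterations = 3), d, m, guidance), b)
  rc_inf <- tab$rc[tab$value == 1e6]
  rc_01 <- tab$rc[tab$value == 0.1]
  expect_lt(max(abs(rc_inf - kem$rc)), max(abs(rc_01 - kem$rc)))
  expect_error(parameter_sweep(cfg, "nope", 1, d, m, guidance, b),
               "unknown kernel parameter")
})

test_that("autoplot produces a ggplot of RC against CoV", {
  b <- mini_phantom()
  m <- mini_model(b)
  d <- simulate_counts(b$activity, m, 2e4, seed = 53)
  r <- run_reconstruction(recon_config("osem", n_subsets = 2,
                                       n_iterations = 2), d, m)
  rep <- rc_cov_curve(r, b)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
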