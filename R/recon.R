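# EM reconstruction drivers. All algorithms share one update on kernel
# coefficients alpha (image x = K alpha):
#
#   alpha_new = alpha / (K' A_s' 1) * K' A_s'( y_s / (A_s K alpha + b_s) )
#
# With K = identity this is the classic (OS)MLEM update. KEM variants freeze
# a guidance kernel; hybrid variants (HKEM/MHKEM) multiply in a factor
# derived from the current image estimate, re-computed every sub-iteration.

ALGORITHMS <- c("osem-nopsf", "osem", "kem-ct", "kem-spect", "mkem",
                "hkem-ct", "hkem-spect", "mhkem")

algorithm_guidance <- function(algorithm) {
  switch(algorithm,
         "osem-nopsf" = character(0),
         "osem" = character(0),
         "kem-ct" = "ct",
         "kem-spect" = "spect",
         "mkem" = c("spect", "ct"),
         "hkem-ct" = "ct",
         "hkem-spect" = "spect",
         "mhkem" = c("spect", "ct"))
}

algorithm_is_hybrid <- function(algorithm) {
  algorithm %in% c("hkem-ct", "hkem-spect", "mhkem")
}

#' Reconstruction configuration
#'
#' @param algorithm one of `"osem-nopsf"`, `"osem"`, `"kem-ct"`,
#'   `"kem-spect"`, `"mkem"`, `"hkem-ct"`, `"hkem-spect"`, `"mhkem"`.
#' @param n_subsets ordered subsets per full iteration (default 9).
#' @param n_iterations full iterations (default 30).
#' @param kernel a [kernel_spec()] (ignored by the OSEM modes).
#' @param post_filter_fwhm_mm Gaussian post-filter FWHM applied to the saved
#'   images of the OSEM modes (default 7 mm for OSEM modes, 0 for kernel
#'   modes, matching the comparison design in which kernel reconstructions
#'   are left unfiltered).
#' @param initial_value value of the uniform initial coefficient image.
#' @param save_every_iteration keep the image after every full iteration
#'   (needed for RC/CoV curves).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(algorithm, n_subsets = 9, n_iterations = 30,
                         kernel = kernel_spec(),
                         post_filter_fwhm_mm = NULL,
                         initial_value = 1,
                         save_every_iteration = TRUE) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  n_subsets <- as.integer(n_subsets)
  n_iterations <- as.integer(n_iterations)
  if (n_subsets < 1L || n_iterations < 1L) {
    stop("iteration and subset counts must be >= 1", call. = FALSE)
  }
  if (is.null(post_filter_fwhm_mm)) {
    post_filter_fwhm_mm <- if (algorithm %in% c("osem", "osem-nopsf")) 7 else 0
  }
  if (post_filter_fwhm_mm < 0) {
    stop("`post_filter_fwhm_mm` must be >= 0", call. = FALSE)
  }
  if (initial_value <= 0) stop("`initial_value` must be > 0", call. = FALSE)
  structure(
    list(algorithm = algorithm, n_subsets = n_subsets,
         n_iterations = n_iterations, kernel = kernel,
         post_filter_fwhm_mm = post_filter_fwhm_mm,
         initial_value = initial_value,
         save_every_iteration = isTRUE(save_every_iteration)),
    class = "recon_config"
  )
}

# restriction of the system model to one subset's angles
make_subset_ops <- function(model, angles) {
  nr <- model$geometry$n_radial
  rows <- as.vector(outer(seq_len(nr), (angles - 1L) * nr, `+`))
  A_s <- model$A[rows, , drop = FALSE]
  tA_s <- Matrix::t(A_s)
  sub_geom <- list(n_angles = length(angles), n_radial = nr)
  att_s <- NULL
  if (!is.null(model$att)) {
    att_s <- if (grid_ndim(model$grid) == 2L) {
      model$att[angles, , drop = FALSE]
    } else {
      model$att[angles, , , drop = FALSE]
    }
  }
  fwd <- function(values) {
    p <- ray_forward_(A_s, blur_values_(values, model$blur), sub_geom,
                      model$grid)
    if (!is.null(att_s)) p <- p * att_s
    p
  }
  bwd <- function(bins) {
    if (!is.null(att_s)) bins <- bins * att_s
    blur_values_t_(ray_back_(tA_s, bins, sub_geom, model$grid), model$blur)
  }
  dims <- if (grid_ndim(model$grid) == 2L) {
    c(length(angles), nr)
  } else {
    c(length(angles), nr, model$grid$shape[3])
  }
  sens <- bwd(array(1, dims))
  list(angles = angles, fwd = fwd, bwd = bwd,
       sens = as.numeric(sens), dims = dims)
}

subset_counts_ <- function(data, angles) {
  if (length(dim(data$counts)) == 2L) {
    list(y = data$counts[angles, , drop = FALSE],
         b = data$background[angles, , drop = FALSE])
  } else {
    list(y = data$counts[angles, , , drop = FALSE],
         b = data$background[angles, , , drop = FALSE])
  }
}

# one EM coefficient update on a prepared subset
em_core_ <- function(alpha, K, ops, y, b) {
  x <- as.numeric(K$K %*% alpha)
  ybar <- ops$fwd(array(x, K$grid$shape)) + b
  bad <- ybar == 0 & y > 0
  if (any(bad)) {
    stop("zero expected counts where measured counts are positive; ",
         "the model cannot explain the data", call. = FALSE)
  }
  ratio <- array(0, dim(ybar))
  pos <- ybar > 0
  ratio[pos] <- y[pos] / ybar[pos]
  num <- as.numeric(Matrix::crossprod(K$K, as.numeric(ops$bwd(ratio))))
  den <- as.numeric(Matrix::crossprod(K$K, ops$sens))
  out <- numeric(length(alpha))
  ok <- den > 0
  out[ok] <- alpha[ok] * num[ok] / den[ok]
  out
}

#' One EM (sub-)iteration update
#'
#' Performs a single ordered-subsets EM update of the coefficient image for
#' the given subset of angles. With `K = NULL` (identity kernel) the
#' coefficients are the image itself and this is the classic OSEM update.
#' Coefficients with zero subset sensitivity are frozen at 0; bins with zero
#' expected and zero measured counts contribute nothing, while zero expected
#' counts against positive measured counts raise an error.
#'
#' @param estimate current coefficient image ([volume_image()] or array),
#'   non-negative.
#' @param data a [projection_data()].
#' @param model a [system_model()].
#' @param subset integer vector of angle indices (default: all angles).
#' @param K a `kernel_matrix` or `NULL` for the identity.
#' @return Updated coefficient [volume_image()].
#' @export
em_update <- function(estimate, data, model, subset = NULL, K = NULL) {
  vals <- as_volume_values(estimate)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("current estimate must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(data$counts))) {
    stop("`data$counts` contains non-finite values", call. = FALSE)
  }
  if (is.null(subset)) subset <- seq_len(model$geometry$n_angles)
  if (is.null(K)) K <- identity_kernel(model$grid)
  ops <- make_subset_ops(model, subset)
  yb <- subset_counts_(data, subset)
  out <- em_core_(as.numeric(vals), K, ops, yb$y, yb$b)
  volume_image(array(out, model$grid$shape), model$grid, "arbitrary")
}

poisson_loglik_ <- function(x_vals, model, data) {
  ybar <- forward_project(
    volume_image(array(pmax(x_vals, 0), model$grid$shape), model$grid,
                 "arbitrary"),
    model
  ) + data$background
  y <- data$counts
  pos <- ybar > 0
  if (any(!pos & y > 0)) return(-Inf)
  sum(y[pos] * log(ybar[pos])) - sum(ybar)
}

#' Run an iterative reconstruction
#'
#' Dispatches on the configured algorithm: the OSEM modes use the identity
#' kernel (with `"osem-nopsf"` additionally dropping the model's resolution
#' blur), KEM modes freeze a guidance kernel, and the hybrid modes
#' (HKEM/MHKEM) re-weight the guidance kernel with the evolving image
#' estimate before every sub-iteration. Guidance images are resampled to the
#' reconstruction grid with [resample_overlap()] and feature-normalized over
#' their non-zero support before entering the kernel. Saved images are
#' divided by the data's calibration factor so they are in
#' activity-concentration units; the Gaussian post-filter is applied to the
#' saved images of the OSEM modes only. The run is deterministic given the
#' configuration.
#'
#' @param config a [recon_config()].
#' @param data a [projection_data()].
#' @param model a [system_model()].
#' @param guidance named list of guidance [volume_image()]s; the algorithms
#'   require `ct`, `spect`, or both (see [recon_config()]).
#' @return An object of class `recon_result`: `images` (one per full
#'   iteration), `final`, `loglik` (tibble with the full-data Poisson
#'   log-likelihood per iteration), `algorithm`, `config`.
#' @export
run_reconstruction <- function(config, data, model, guidance = list()) {
  if (!inherits(config, "recon_config")) {
    stop("`config` must be a recon_config", call. = FALSE)
  }
  needed <- algorithm_guidance(config$algorithm)
  missing_g <- setdiff(needed, names(guidance))
  if (length(missing_g) > 0L) {
    stop("algorithm '", config$algorithm, "' requires guidance image(s): ",
         paste(needed, collapse = ", "), " (missing: ",
         paste(missing_g, collapse = ", "), ")", call. = FALSE)
  }
  if (config$algorithm == "osem-nopsf" && !is.null(model$blur)) {
    model$blur <- NULL
  }
  ks <- config$kernel
  if (length(needed) > 0L) {
    prepped <- lapply(guidance[needed], function(im) {
      if (!grids_equal(im$grid, model$grid)) {
        im <- resample_overlap(im, model$grid)
      }
      support <- im$values != 0
      if (sum(support) >= 2L && stats::sd(im$values[support]) > 0) {
        normalize_feature(im)
      } else {
        im  # uniform guidance: feature differences vanish, kernel is spatial
      }
    })
    sigmas <- vapply(needed, function(m) {
      switch(m, spect = ks$sigma_s, ct = ks$sigma_c)
    }, numeric(1))
    Kg <- guidance_kernel(unname(prepped), sigmas, ks$sigma_d,
                          window = ks$window,
                          normalize_rows = ks$normalize_rows)
  } else {
    Kg <- identity_kernel(model$grid)
  }
  hybrid <- algorithm_is_hybrid(config$algorithm)
  subsets <- partition_subsets(model$geometry, config$n_subsets)
  ops <- lapply(subsets, make_subset_ops, model = model)
  ysub <- lapply(subsets, subset_counts_, data = data)

  n_alpha <- grid_nvox(model$grid)
  alpha <- rep(config$initial_value, n_alpha)
  K <- Kg
  x_vals <- as.numeric(Kg$K %*% alpha)
  images <- vector("list", config$n_iterations)
  ll <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    for (s in seq_along(subsets)) {
      if (hybrid) {
        K <- hybrid_factor(
          Kg,
          volume_image(array(x_vals, model$grid$shape), model$grid,
                       "arbitrary"),
          ks$sigma_p
        )
      }
      alpha <- em_core_(alpha, K, ops[[s]], ysub[[s]]$y, ysub[[s]]$b)
      x_vals <- as.numeric(K$K %*% alpha)
    }
    ll[it] <- poisson_loglik_(x_vals, model, data)
    img <- volume_image(array(pmax(x_vals, 0) / data$calibration,
                              model$grid$shape),
                        model$grid, "activity-concentration")
    if (config$post_filter_fwhm_mm > 0) {
      img <- gaussian_filter(img, config$post_filter_fwhm_mm)
    }
    if (config$save_every_iteration || it == config$n_iterations) {
      images[[it]] <- img
    }
  }
  structure(
    list(images = images,
         final = images[[config$n_iterations]],
         loglik = tibble::tibble(iteration = seq_len(config$n_iterations),
                                 logLik = ll),
         algorithm = config$algorithm,
         config = config),
    class = "recon_result"
  )
}

#' @export
print.recon_result <- function(x, ...) {
  cat("<recon_result> ", x$algorithm, ", ", x$config$n_iterations,
      " iteration(s) x ", x$config$n_subsets, " subset(s), final logLik ",
      format(x$loglik$logLik[nrow(x$loglik)]), "\n", sep = "")
  invisible(x)
}

#' Per-iteration log-likelihood trace as a tibble
#'
#' @param x a `recon_result`.
#' @param ... unused.
#' @return Tibble with `algorithm`, `iteration`, `logLik`.
#' @export
tidy.recon_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 iteration = x$loglik$iteration,
                 logLik = x$loglik$logLik)
}

#' One-row summary of a reconstruction
#'
#' @param x a `recon_result`.
#' @param ... unused.
#' @return One-row tibble.
#' @export
glance.recon_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 n_iterations = x$config$n_iterations,
                 n_subsets = x$config$n_subsets,
                 post_filter_fwhm_mm = x$config$post_filter_fwhm_mm,
                 final_logLik = x$loglik$logLik[nrow(x$loglik)])
}

#' Generic for tidy summaries (broom-style)
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic for one-row model summaries (broom-style)
#' @param x object to summarize.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Scale an image to match a reference over its active bounding box
#'
#' Finds the axis-aligned bounding box of the reference's active voxels
#' (values above `threshold` times its maximum), computes
#' `factor = sum(reference over box) / sum(image over box)` and returns the
#' image multiplied by the factor. Mirrors the calibration step used to put
#' reconstructions on the intensity scale of a vendor reference image.
#'
#' @param image a [volume_image()].
#' @param reference a [volume_image()] on the same grid.
#' @param threshold active-voxel threshold as a fraction of the reference
#'   maximum (default 0.01).
#' @return List with `image` (scaled) and `factor`.
#' @export
scale_to_reference <- function(image, reference, threshold = 0.01) {
  stopifnot_volume(image)
  stopifnot_volume(reference)
  if (!grids_equal(image$grid, reference$grid)) {
    stop("`image` and `reference` must share a grid", call. = FALSE)
  }
  active <- reference$values > threshold * max(reference$values)
  if (!any(active)) stop("reference has no active voxels", call. = FALSE)
  idx <- which(active, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1)
  box <- array(FALSE, dim(reference$values))
  ranges <- lapply(seq_len(ncol(idx)), function(a) {
    seq.int(min(idx[, a]), max(idx[, a]))
  })
  box[as.matrix(expand.grid(ranges))] <- TRUE
  denom <- sum(image$values[box])
  if (denom == 0) stop("image sums to zero over the reference box",
                       call. = FALSE)
  factor <- sum(reference$values[box]) / denom
  list(image = with_values(image, image$values * factor), factor = factor)
}
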