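# Sparse kernel matrices for kernelized EM. The reconstruction is
# parameterized as x = K alpha, where K holds, for every voxel j, Gaussian
# similarity weights to the voxels l of a fixed axis-aligned window:
#
#   k_jl = exp(-|d_jl|^2 / (2 sigma_d^2)) *
#          prod_m exp(-(g_mj - g_ml)^2 / (2 sigma_m^2))
#
# with d_jl the spatial offset in voxel-index units and g_m the m-th
# feature-normalized guidance image (CT, SPECT, ...). One guidance image
# gives the single-modality (KEM/HKEM) kernel; two or more are multiplexed
# by taking the product of their feature factors under one shared spatial
# factor (MKEM/MHKEM). The hybrid variants multiply in an extra factor built
# the same way from the evolving reconstruction itself, re-computed every
# sub-iteration; its edge parameter sigma_p is expressed in units of the
# standard deviation of the current estimate over its non-zero support.
# The sparsity pattern is fixed by the window, so hybrid re-weighting never
# changes the structure.

#' Kernel hyper-parameters
#'
#' Defaults are the optimized PET-stage values: a 5x5x5 neighborhood,
#' iterative (PET) edge `sigma_p = 1`, SPECT edge `sigma_s = 3`, CT edge
#' `sigma_c = 0.5` and spatial width `sigma_d = 5` voxels, with row
#' normalization on. The SPECT reconstruction stage uses `sigma_p = 0.1`
#' (iterative SPECT edge) and `sigma_c = 1`.
#'
#' @param window odd window size per axis (scalar or per-axis vector).
#' @param sigma_p iterative (image-update) edge parameter, in SD units.
#' @param sigma_s SPECT guidance edge parameter, in SD units.
#' @param sigma_c CT guidance edge parameter, in SD units.
#' @param sigma_d spatial width, in voxel-index units.
#' @param normalize_rows normalize each kernel row to sum 1 (default TRUE).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(window = 5, sigma_p = 1, sigma_s = 3, sigma_c = 0.5,
                        sigma_d = 5, normalize_rows = TRUE) {
  window <- as.integer(window)
  if (any(window < 1L) || any(window %% 2L == 0L)) {
    stop("`window` entries must be odd and >= 1", call. = FALSE)
  }
  for (s in c(sigma_p, sigma_s, sigma_c, sigma_d)) {
    if (!is.finite(s) || s <= 0) {
      stop("all kernel sigmas must be > 0", call. = FALSE)
    }
  }
  structure(
    list(window = window, sigma_p = sigma_p, sigma_s = sigma_s,
         sigma_c = sigma_c, sigma_d = sigma_d,
         normalize_rows = isTRUE(normalize_rows)),
    class = "kernel_spec"
  )
}

# window offsets as a matrix (one row per offset), for a grid of ndim axes
window_offsets <- function(window, ndim) {
  window <- rep_len(as.integer(window), ndim)
  half <- (window - 1L) %/% 2L
  offs <- expand.grid(lapply(half, function(h) seq.int(-h, h)))
  as.matrix(offs)
}

# for one offset, the (from, to) linear voxel index pairs that stay inside
# the grid; linear indices are 1-based, first axis fastest
offset_pairs <- function(shape, off) {
  nd <- length(shape)
  idx <- lapply(seq_len(nd), function(a) {
    lo <- max(1L, 1L - off[a])
    hi <- min(shape[a], shape[a] - off[a])
    seq.int(lo, hi)
  })
  if (any(vapply(idx, length, integer(1)) == 0L)) return(NULL)
  from_grid <- expand.grid(idx)
  strides <- cumprod(c(1L, shape[-nd]))
  from <- as.integer(as.matrix(from_grid) %*% strides) -
    as.integer(sum(strides)) + 1L
  to <- from + as.integer(sum(off * strides))
  cbind(from, to)
}

#' Fixed-window neighborhood sparsity pattern
#'
#' Voxel `j`'s neighbors are all voxels of the axis-aligned window centred
#' on `j`, truncated at the volume borders; `j` is always its own neighbor.
#' The pattern is symmetric and independent of image content.
#'
#' @param grid an [image_grid()].
#' @param window odd window size per axis.
#' @return A sparse pattern matrix (`ngCMatrix`, voxels x voxels).
#' @export
build_neighborhood <- function(grid, window) {
  offs <- window_offsets(window, grid_ndim(grid))
  tri <- lapply(seq_len(nrow(offs)), function(k) {
    offset_pairs(grid$shape, offs[k, ])
  })
  tri <- do.call(rbind, tri)
  n <- grid_nvox(grid)
  m <- Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = 1, dims = c(n, n))
  methods::as(m, "nMatrix")
}

# assemble triplets (i, j, weight) for the guidance kernel
guidance_triplets_ <- function(images, sigmas, sigma_d, window, grid) {
  nd <- grid_ndim(grid)
  offs <- window_offsets(window, nd)
  feats <- lapply(images, function(im) as.numeric(im$values))
  ti <- tj <- tx <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    pairs <- offset_pairs(grid$shape, offs[k, ])
    if (is.null(pairs)) next
    w <- rep(exp(-sum(offs[k, ]^2) / (2 * sigma_d^2)), nrow(pairs))
    for (m in seq_along(feats)) {
      dg <- feats[[m]][pairs[, 1]] - feats[[m]][pairs[, 2]]
      w <- w * exp(-dg^2 / (2 * sigmas[m]^2))
    }
    ti[[k]] <- pairs[, 1]
    tj[[k]] <- pairs[, 2]
    tx[[k]] <- w
  }
  list(i = unlist(ti), j = unlist(tj), x = unlist(tx))
}

new_kernel_matrix <- function(i, j, w, grid, normalize_rows) {
  n <- grid_nvox(grid)
  K <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  if (normalize_rows) {
    K <- Matrix::Diagonal(x = 1 / Matrix::rowSums(K)) %*% K
    K <- methods::as(K, "CsparseMatrix")
  }
  structure(
    list(i = i, j = j, w = w, K = K, grid = grid,
         normalize_rows = normalize_rows),
    class = "kernel_matrix"
  )
}

#' Guidance kernel matrix (KEM / MKEM building block)
#'
#' Builds the sparse kernel from one or more feature-normalized guidance
#' images on the target grid. One image gives the single-modality kernel;
#' several images are multiplexed by multiplying their feature factors under
#' a single shared spatial factor.
#'
#' @param images list of guidance [volume_image()]s on the target grid,
#'   already passed through [normalize_feature()].
#' @param sigmas numeric vector of edge parameters, one per image (SD units).
#' @param sigma_d spatial width (voxel-index units).
#' @param window odd window size per axis (default 5).
#' @param normalize_rows normalize rows to sum 1 (default TRUE).
#' @return An object of class `kernel_matrix`.
#' @export
guidance_kernel <- function(images, sigmas, sigma_d, window = 5,
                            normalize_rows = TRUE) {
  if (length(images) == 0L) stop("`images` must not be empty", call. = FALSE)
  if (length(sigmas) != length(images)) {
    stop("`sigmas` must have one entry per guidance image", call. = FALSE)
  }
  if (any(sigmas <= 0) || sigma_d <= 0) {
    stop("all sigmas must be > 0", call. = FALSE)
  }
  grid <- images[[1]]$grid
  for (im in images) {
    stopifnot_volume(im)
    if (!grids_equal(im$grid, grid)) {
      stop("all guidance images must share one grid (resample first)",
           call. = FALSE)
    }
  }
  tri <- guidance_triplets_(images, sigmas, sigma_d, window, grid)
  new_kernel_matrix(tri$i, tri$j, tri$x, grid, normalize_rows)
}

#' Spatial-only kernel (uniform guidance limit)
#'
#' @param grid an [image_grid()].
#' @param sigma_d spatial width (voxel-index units).
#' @param window odd window size per axis.
#' @param normalize_rows normalize rows to sum 1.
#' @return A `kernel_matrix`.
#' @export
spatial_kernel <- function(grid, sigma_d, window = 5, normalize_rows = TRUE) {
  tri <- guidance_triplets_(list(), numeric(0), sigma_d, window, grid)
  new_kernel_matrix(tri$i, tri$j, tri$x, grid, normalize_rows)
}

#' Identity kernel (window 1): reduces kernelized EM to plain OSEM
#'
#' @param grid an [image_grid()].
#' @return A `kernel_matrix` whose matrix is the identity.
#' @export
identity_kernel <- function(grid) {
  n <- grid_nvox(grid)
  new_kernel_matrix(seq_len(n), seq_len(n), rep(1, n), grid, FALSE)
}

#' Hybrid factor: re-weight a guidance kernel with the current estimate
#'
#' Multiplies each guidance weight by a Gaussian factor in the difference of
#' the current image estimate at the two voxels, with edge width
#' `sigma_p * sd(z)` where `sd(z)` is taken over the non-zero support of the
#' estimate (so `sigma_p` is in SD units like the guidance sigmas). Rows are
#' re-normalized if the guidance kernel was row-normalized. A uniform
#' estimate (zero SD) leaves the kernel unchanged. The sparsity pattern is
#' inherited unchanged from the guidance kernel.
#'
#' @param K_guidance a `kernel_matrix` from [guidance_kernel()].
#' @param current_estimate a non-negative [volume_image()] on the same grid.
#' @param sigma_p iterative edge parameter (`> 0`).
#' @return A `kernel_matrix` with the same sparsity pattern.
#' @export
hybrid_factor <- function(K_guidance, current_estimate, sigma_p) {
  if (!inherits(K_guidance, "kernel_matrix")) {
    stop("`K_guidance` must be a kernel_matrix", call. = FALSE)
  }
  if (!is.finite(sigma_p) || sigma_p <= 0) {
    stop("`sigma_p` must be > 0", call. = FALSE)
  }
  stopifnot_volume(current_estimate)
  if (!grids_equal(current_estimate$grid, K_guidance$grid)) {
    stop("`current_estimate` must live on the kernel grid", call. = FALSE)
  }
  z <- as.numeric(current_estimate$values)
  if (any(z < 0)) stop("`current_estimate` must be non-negative",
                       call. = FALSE)
  support <- z != 0
  sdz <- if (sum(support) >= 2L) stats::sd(z[support]) else 0
  if (!is.finite(sdz) || sdz == 0) {
    # uniform estimate: factor 1 everywhere
    return(K_guidance)
  }
  dz <- z[K_guidance$i] - z[K_guidance$j]
  w <- K_guidance$w * exp(-dz^2 / (2 * sigma_p^2 * sdz^2))
  new_kernel_matrix(K_guidance$i, K_guidance$j, w, K_guidance$grid,
                    K_guidance$normalize_rows)
}

#' Apply a kernel matrix to a coefficient image: `x = K alpha`
#'
#' @param K a `kernel_matrix`.
#' @param alpha coefficient [volume_image()] (or array) on the kernel grid.
#' @return A [volume_image()].
#' @export
apply_kernel <- function(K, alpha) {
  v <- as.numeric(as_volume_values(alpha))
  out <- as.numeric(K$K %*% v)
  volume_image(array(out, K$grid$shape), K$grid, "arbitrary")
}

#' Apply the transpose of a kernel matrix: `K' y`
#'
#' @param K a `kernel_matrix`.
#' @param image [volume_image()] (or array) on the kernel grid.
#' @return A [volume_image()] of coefficients.
#' @export
apply_kernel_transpose <- function(K, image) {
  v <- as.numeric(as_volume_values(image))
  out <- as.numeric(Matrix::crossprod(K$K, v))
  volume_image(array(out, K$grid$shape), K$grid, "arbitrary")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat("<kernel_matrix> ", nrow(x$K), " voxels, ",
      length(x$w), " non-zeros",
      if (x$normalize_rows) ", row-normalized", "\n", sep = "")
  invisible(x)
}
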