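# Separable Gaussian filtering with reflective (half-sample symmetric)
# boundaries, realised as explicit banded sparse matrices so the projector
# can use the exact transpose in backprojection. With a normalized symmetric
# kernel this boundary choice preserves image totals (the operator is
# diagonalized by the DCT-II), which matters for count-preserving
# post-filtering.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# half-sample symmetric index folding, 0-based in, 1-based out
reflect_index <- function(j, n) {
  r <- j %% (2L * n)
  ifelse(r >= n, 2L * n - 1L - r, r) + 1L
}

# n x n one-dimensional Gaussian blur matrix, sigma in voxel units
gaussian_blur_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(Matrix::Diagonal(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  taps <- stats::dnorm(-r:r, sd = sigma_vox)
  taps <- taps / sum(taps)
  rows <- rep(seq_len(n), each = 2L * r + 1L)
  offs <- rep(-r:r, times = n)
  cols <- reflect_index(rows - 1L + offs, n)
  Matrix::sparseMatrix(i = rows, j = cols, x = taps[offs + r + 1L],
                       dims = c(n, n))
}

#' Gaussian filter with a FWHM given in millimetres
#'
#' The kernel is specified by its full width at half maximum in mm and
#' converted per axis using the voxel sizes, so anisotropic grids get an
#' isotropic physical blur. The discrete kernel is normalized and boundaries
#' are reflective, so image totals are preserved (to ~1e-6 relative).
#' `fwhm_mm = 0` returns the input unchanged.
#'
#' @param image a [volume_image()].
#' @param fwhm_mm full width at half maximum in mm, `>= 0`.
#' @return A [volume_image()] on the same grid.
#' @export
gaussian_filter <- function(image, fwhm_mm) {
  stopifnot_volume(image)
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) {
    stop("`fwhm_mm` must be >= 0", call. = FALSE)
  }
  if (fwhm_mm == 0) return(image)
  sigma_mm <- fwhm_to_sigma(fwhm_mm)
  vals <- image$values
  for (a in seq_len(grid_ndim(image$grid))) {
    n <- image$grid$shape[a]
    if (n == 1L) next
    B <- gaussian_blur_matrix(n, sigma_mm / image$grid$voxel_size[a])
    vals <- apply_along_axis(vals, B, a)
  }
  with_values(image, vals)
}

#' Normalize a guidance image to unit standard deviation
#'
#' Divides the image by the sample (n-1) standard deviation of its values
#' inside `mask`, making the kernel edge parameters (`sigma_c`, `sigma_s`)
#' dimensionless. By default the mask is the non-zero support of the image,
#' so that surrounding air does not dominate the scale.
#'
#' @param image a [volume_image()].
#' @param mask logical array matching the grid, or `NULL` for the non-zero
#'   support. Must select at least 2 voxels with non-zero variance.
#' @return A [volume_image()] whose in-mask standard deviation is 1.
#' @export
normalize_feature <- function(image, mask = NULL) {
  stopifnot_volume(image)
  if (is.null(mask)) mask <- image$values != 0
  mask <- as.logical(mask)
  if (sum(mask) < 2L) {
    stop("`mask` must select at least 2 voxels", call. = FALSE)
  }
  s <- stats::sd(image$values[mask])
  if (!is.finite(s) || s == 0) {
    stop("zero variance inside mask; cannot normalize", call. = FALSE)
  }
  with_values(image, image$values / s, units = "arbitrary")
}
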