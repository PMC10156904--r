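#' Read a volume from a NIfTI-1 file
#'
#' Grid metadata is taken from the header: voxel sizes from `pixdim`, the
#' origin from the translation part of the sform (or qform) affine, and the
#' units tag from the `descrip` field (written by [write_volume()]). The
#' affine maps 0-based voxel indices to voxel-centre mm positions, so the
#' stored translation equals `origin + voxel_size / 2`.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param expect_units optional; if given, error unless the stored units tag
#'   matches.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, expect_units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  attributes(values) <- list(dim = dim(values))
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) {
    stop("only 2D or 3D volumes are supported (got ", nd, "D)", call. = FALSE)
  }
  hdr <- RNifti::niftiHeader(img)
  voxel_size <- hdr$pixdim[seq_len(nd) + 1L]
  if (any(voxel_size <= 0)) {
    stop("non-positive voxel size in NIfTI header of ", path, call. = FALSE)
  }
  aff <- RNifti::xform(img)
  translation <- aff[seq_len(nd), ncol(aff)]
  origin <- translation - voxel_size / 2
  units <- hdr$descrip
  if (!units %in% c("arbitrary", "activity-concentration", "attenuation")) {
    units <- "arbitrary"
  }
  if (!is.null(expect_units) && !identical(units, expect_units)) {
    stop("units mismatch: file carries '", units, "', expected '",
         expect_units, "'", call. = FALSE)
  }
  grid <- image_grid(dim(values), voxel_size, origin)
  volume_image(values, grid, units)
}

#' Write a volume to a NIfTI-1 file
#'
#' Values are stored as float64, so a write/read round trip is bit-exact.
#'
#' @param image a [volume_image()].
#' @param path destination (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot_volume(image)
  nd <- grid_ndim(image$grid)
  img <- RNifti::asNifti(image$values, datatype = "double")
  pixdim <- c(-1, rep(1, 7))
  pixdim[seq_len(nd) + 1L] <- image$grid$voxel_size
  img <- RNifti::updateNifti(img, list(pixdim = pixdim,
                                       descrip = image$units))
  aff <- diag(4)
  diag(aff)[seq_len(nd)] <- image$grid$voxel_size
  aff[seq_len(nd), 4] <- image$grid$origin + image$grid$voxel_size / 2
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
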