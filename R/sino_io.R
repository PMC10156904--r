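# Sinogram on-disk format: flat little-endian float64 counts (angle-major:
# radial index fastest, then angle, then slice) next to a JSON sidecar
# carrying the geometry, background, subset partition, calibration and seed.

#' Write projection data (flat binary counts + JSON sidecar)
#'
#' @param data a [projection_data()].
#' @param path path of the binary counts file; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_projection_data <- function(data, path) {
  if (!inherits(data, "projection_data")) {
    stop("`data` must be projection_data", call. = FALSE)
  }
  # angle-major layout: permute so radial is fastest
  perm <- if (length(dim(data$counts)) == 3L) c(2, 1, 3) else c(2, 1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(data$counts, perm)), con,
           size = 8L, endian = "little")
  bg <- data$background
  flat_bg <- length(unique(as.numeric(bg))) == 1L
  sidecar <- list(
    format = "trikem-sinogram-v1",
    layout = "angle-major (radial fastest), float64 little-endian",
    shape = dim(data$counts),
    geometry = list(n_angles = data$geometry$n_angles,
                    n_radial = data$geometry$n_radial,
                    bin_width_mm = data$geometry$bin_width_mm,
                    modality = data$geometry$modality),
    background = if (flat_bg) as.numeric(bg[1]) else as.numeric(aperm(bg, perm)),
    subsets = data$subsets,
    calibration = data$calibration,
    seed = data$seed
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read projection data written by [write_projection_data()]
#'
#' @param path path of the binary counts file (sidecar expected at
#'   `paste0(path, ".json")`).
#' @return A [projection_data()].
#' @export
read_projection_data <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    stop("missing counts file or JSON sidecar for ", path, call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  geom <- parallel_geometry(sc$geometry$n_angles, sc$geometry$n_radial,
                            sc$geometry$bin_width_mm, sc$geometry$modality)
  shape <- as.integer(sc$shape)
  n <- prod(shape)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_counts <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  perm <- if (length(shape) == 3L) c(2, 1, 3) else c(2, 1)
  counts <- aperm(array(raw_counts, shape[perm]), order(perm))
  background <- sc$background
  if (length(background) > 1L) {
    background <- aperm(array(as.numeric(background), shape[perm]),
                        order(perm))
  }
  subsets <- sc$subsets
  if (is.matrix(subsets)) {
    # jsonlite collapses equal-length subset vectors into a matrix
    subsets <- lapply(seq_len(nrow(subsets)),
                      function(i) as.integer(subsets[i, ]))
  } else {
    subsets <- lapply(subsets, as.integer)
  }
  projection_data(geom, counts, background = background, subsets = subsets,
                  calibration = sc$calibration,
                  seed = if (is.null(sc$seed)) NULL else sc$seed)
}
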