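#' Regular image grid
#'
#' Describes a 2D or 3D axis-aligned voxel lattice. Voxel indices are 0-based;
#' the centre of voxel `(i, j, k)` sits at `origin + (i + 1/2, j + 1/2,
#' k + 1/2) * voxel_size`, so `origin` is the physical position (mm) of the
#' lower corner of the volume. The default origin centres the volume on the
#' physical origin, which is also the rotation centre of the projector.
#'
#' @param shape integer vector (length 2 or 3), voxels per axis; all `>= 1`.
#' @param voxel_size numeric, mm per axis (recycled to `length(shape)`);
#'   all `> 0`.
#' @param origin numeric, mm position of the volume corner; defaults to
#'   `-shape * voxel_size / 2` (centred volume).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(shape, voxel_size, origin = NULL) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L)) {
    stop("`shape` must have length 2 or 3", call. = FALSE)
  }
  if (any(is.na(shape)) || any(shape < 1L)) {
    stop("all `shape` entries must be >= 1", call. = FALSE)
  }
  voxel_size <- rep_len(as.numeric(voxel_size), length(shape))
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("all `voxel_size` entries must be > 0", call. = FALSE)
  }
  if (is.null(origin)) {
    origin <- -shape * voxel_size / 2
  }
  origin <- rep_len(as.numeric(origin), length(shape))
  structure(
    list(shape = shape, voxel_size = voxel_size, origin = origin),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(
    "<image_grid> ", paste(x$shape, collapse = " x "),
    " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
    " mm\n",
    sep = ""
  )
  invisible(x)
}

grid_ndim <- function(grid) length(grid$shape)

grid_nvox <- function(grid) prod(grid$shape)

voxel_volume <- function(grid) prod(grid$voxel_size)

#' @export
format.image_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), " @ ",
         paste(signif(x$voxel_size, 4), collapse = "x"), " mm")
}

grids_equal <- function(a, b, tol = 1e-9) {
  length(a$shape) == length(b$shape) &&
    all(a$shape == b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) <= tol * pmax(1, abs(a$voxel_size))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin)))
}

#' Voxel-centre coordinates along one axis
#'
#' @param grid an [image_grid()].
#' @param axis axis index (1-based).
#' @return numeric vector of mm positions of voxel centres.
#' @export
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$voxel_size[axis]
}

axis_edges <- function(grid, axis) {
  grid$origin[axis] + (0:grid$shape[axis]) * grid$voxel_size[axis]
}

#' Voxel-centre coordinate arrays
#'
#' Returns a list of arrays (one per axis, each of `grid$shape`) with the mm
#' coordinate of every voxel centre. Used by the phantom voxelizer and the
#' VOI masks, which share the same voxel-centre inclusion rule.
#'
#' @param grid an [image_grid()].
#' @return list of numeric arrays.
#' @export
voxel_center_coords <- function(grid) {
  nd <- grid_ndim(grid)
  centers <- lapply(seq_len(nd), axis_centers, grid = grid)
  template <- array(0, dim = grid$shape)
  lapply(seq_len(nd), function(a) {
    array(centers[[a]][slice.index(template, a)], dim = grid$shape)
  })
}

#' Voxel image container
#'
#' A dense voxel array bound to an [image_grid()] plus a units tag. Activity
#' and attenuation images must be non-negative and finite everywhere.
#'
#' @param values numeric array matching `grid$shape`.
#' @param grid an [image_grid()].
#' @param units one of `"arbitrary"`, `"activity-concentration"`,
#'   `"attenuation"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, grid,
                         units = c("arbitrary", "activity-concentration",
                                   "attenuation")) {
  units <- match.arg(units)
  values <- as.array(values)
  if (length(dim(values)) == 1L) dim(values) <- c(length(values), 1L)
  if (!identical(as.integer(dim(values)), grid$shape)) {
    stop("`values` dimensions do not match `grid$shape`", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("`values` must be finite everywhere", call. = FALSE)
  }
  if (units %in% c("activity-concentration", "attenuation") &&
      any(values < 0)) {
    stop("`", units, "` images must be non-negative", call. = FALSE)
  }
  structure(
    list(values = values, grid = grid, units = units),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", format(x$grid), ", units: ", x$units,
      ", range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

# Replace values keeping grid/units; skips re-validation of unit sign
# constraints for internal intermediates (callers clamp where needed).
with_values <- function(image, values, units = image$units) {
  values <- as.array(values)
  dim(values) <- image$grid$shape
  structure(
    list(values = values, grid = image$grid, units = units),
    class = "volume_image"
  )
}

as_volume_values <- function(x) {
  if (inherits(x, "volume_image")) x$values else as.array(x)
}

stopifnot_volume <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "volume_image")) {
    stop("`", arg, "` must be a volume_image", call. = FALSE)
  }
  invisible(x)
}
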