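#' Define an isotropic voxel grid
#'
#' The coordinate space on which masks, fraction templates and expression
#' maps live. Voxels are cubes of `voxel_size` micrometres; the centre of
#' voxel `(i, j, k)` (1-based indices) sits at
#' `origin + (index - 0.5) * voxel_size` on each axis. The axis convention is
#' x = left-right (sagittal normal), y = posterior-anterior (coronal normal),
#' z = ventral-dorsal (horizontal normal).
#'
#' @param shape Integer vector of length 3: number of voxels along x, y, z.
#' @param voxel_size Edge length of a voxel in micrometres (isotropic).
#' @param origin Physical coordinate (micrometres) of the corner of the first
#'   voxel. Defaults to centring the grid on the physical origin.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(32, 32, 32), voxel_size = 100)
#' @export
voxel_grid <- function(shape, voxel_size, origin = -shape * voxel_size / 2) {
  shape <- as.integer(round(shape))
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be three integers >= 1", call. = FALSE)
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("`voxel_size` must be a single positive number (micrometres)", call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite coordinates (micrometres)", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_size = as.numeric(voxel_size), origin = origin),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels of %g um (extent %.1f x %.1f x %.1f mm)\n",
    x$shape[1], x$shape[2], x$shape[3], x$voxel_size,
    x$shape[1] * x$voxel_size / 1000,
    x$shape[2] * x$voxel_size / 1000,
    x$shape[3] * x$voxel_size / 1000
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) x$shape

#' Voxel-centre coordinates along one axis
#' @param grid A `voxel_grid`.
#' @param axis Axis index 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of centre coordinates in micrometres.
#' @export
axis_centers <- function(grid, axis) {
  stopifnot(inherits(grid, "voxel_grid"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$voxel_size
}

#' Voxel-centre coordinates for linear voxel indices
#'
#' @param grid A `voxel_grid`.
#' @param index Integer vector of 1-based linear voxel indices (column-major,
#'   x fastest), e.g. as returned by `which()` on a mask array.
#' @return A numeric matrix with columns `x`, `y`, `z` in micrometres.
#' @export
voxel_centers <- function(grid, index) {
  stopifnot(inherits(grid, "voxel_grid"))
  index <- as.integer(index)
  n <- grid$shape
  i0 <- index - 1L
  ix <- i0 %% n[1]
  iy <- (i0 %/% n[1]) %% n[2]
  iz <- i0 %/% (n[1] * n[2])
  cbind(
    x = grid$origin[1] + (ix + 0.5) * grid$voxel_size,
    y = grid$origin[2] + (iy + 0.5) * grid$voxel_size,
    z = grid$origin[3] + (iz + 0.5) * grid$voxel_size
  )
}

# projection of every voxel centre onto a direction, as a full 3D array
grid_projection <- function(grid, normal) {
  px <- axis_centers(grid, 1) * normal[1]
  py <- axis_centers(grid, 2) * normal[2]
  pz <- axis_centers(grid, 3) * normal[3]
  outer(outer(px, py, "+"), pz, "+")
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    abs(a$voxel_size - b$voxel_size) <= tol * max(1, a$voxel_size) &&
    all(abs(a$origin - b$origin) <= tol * max(1, a$voxel_size))
}

check_same_grid <- function(a, b, what = "objects") {
  if (!same_grid(a, b)) stop(sprintf("%s are defined on different grids", what), call. = FALSE)
  invisible(TRUE)
}

#' Create a tissue mask on a voxel grid
#'
#' @param grid A `voxel_grid`.
#' @param inside Logical array with `dim(grid)` dimensions: `TRUE` for tissue
#'   voxels. Must contain at least one `TRUE`.
#' @return An object of class `brain_mask`.
#' @seealso [synthetic_brain_mask()] for a parametric brain-shaped mask.
#' @export
brain_mask <- function(grid, inside) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.logical(inside) || !identical(dim(inside), as.integer(grid$shape))) {
    stop("`inside` must be a logical array with the grid's dimensions", call. = FALSE)
  }
  if (anyNA(inside)) stop("`inside` must not contain NA", call. = FALSE)
  if (!any(inside)) stop("mask must contain at least one inside voxel", call. = FALSE)
  structure(list(grid = grid, inside = inside), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf(
    "<brain_mask> %s voxels inside (%.1f mm^3) on a %d x %d x %d grid\n",
    format(sum(x$inside), big.mark = ","), mask_volume(x) / 1e9,
    x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]
  ))
  invisible(x)
}

#' Mask volume in cubic micrometres
#' @param mask A `brain_mask`.
#' @return Volume in um^3 (inside-voxel count times voxel volume).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "brain_mask"))
  sum(mask$inside) * mask$grid$voxel_size^3
}

# physical bounding box of the mask: 3x2 matrix (rows x,y,z; cols min,max),
# using full voxel extents (centre +/- half voxel)
mask_bbox <- function(mask) {
  idx <- which(mask$inside)
  ctr <- voxel_centers(mask$grid, idx)
  h <- mask$grid$voxel_size / 2
  rbind(
    x = range(ctr[, 1]) + c(-h, h),
    y = range(ctr[, 2]) + c(-h, h),
    z = range(ctr[, 3]) + c(-h, h)
  )
}
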