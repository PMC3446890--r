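#' Describe one slab-sectioning series
#'
#' A sectioning series is a complete set of parallel slabs ("fractions") of
#' equal width cut perpendicular to `normal`. Slab `k` (1-based) occupies the
#' half-open interval `[offset + (k-1)*width, offset + k*width)` of the
#' projection of physical position onto the normal.
#'
#' @param series_id Short label, e.g. `"S"`, `"Co"`.
#' @param normal Direction of sectioning progression; normalised to unit
#'   length (an all-zero vector is an error).
#' @param width Slab thickness in micrometres.
#' @param offset Position (micrometres, along the normal) of the first slab
#'   boundary.
#' @param n_fractions Number of slabs in the series.
#' @return An object of class `sectioning_series`.
#' @export
sectioning_series <- function(series_id, normal, width, offset, n_fractions) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L || any(!is.finite(normal))) {
    stop("`normal` must be a finite 3-vector", call. = FALSE)
  }
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) stop("`normal` must be non-zero", call. = FALSE)
  normal <- normal / nrm
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop("`width` must be a single positive slab thickness in micrometres", call. = FALSE)
  }
  n_fractions <- as.integer(n_fractions)
  if (length(n_fractions) != 1L || is.na(n_fractions) || n_fractions < 1L) {
    stop("`n_fractions` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(
      series_id = as.character(series_id), normal = normal,
      width = as.numeric(width), offset = as.numeric(offset),
      n_fractions = n_fractions
    ),
    class = "sectioning_series"
  )
}

#' @export
print.sectioning_series <- function(x, ...) {
  cat(sprintf(
    "<sectioning_series> %s: %d fractions of %g um along (%.3f, %.3f, %.3f), offset %g um\n",
    x$series_id, x$n_fractions, x$width, x$normal[1], x$normal[2], x$normal[3], x$offset
  ))
  invisible(x)
}

#' Fraction labels of a series (e.g. "S1".."S9")
#' @param series A `sectioning_series`.
#' @return Character vector of length `n_fractions`.
#' @export
fraction_labels <- function(series) {
  stopifnot(inherits(series, "sectioning_series"))
  paste0(series$series_id, seq_len(series$n_fractions))
}

#' Which slab of a series contains a physical point
#'
#' Maps physical positions to 1-based fraction indices via the half-open
#' interval rule: a point whose projection onto the series normal falls in
#' `[offset + (k-1)*width, offset + k*width)` belongs to fraction `k`;
#' points outside `[offset, offset + n_fractions*width)` return `NA`.
#'
#' @param point Numeric 3-vector (micrometres) or an n-by-3 matrix of points.
#' @param series A `sectioning_series`. Its normal must be unit length (a
#'   non-unit normal stored by other means is an error).
#' @return Integer vector of fraction indices (1-based), `NA` for points
#'   outside the series span.
#' @examples
#' s <- sectioning_series("C", c(0, 1, 0), width = 1000, offset = 0, n_fractions = 13)
#' slab_index(c(0, 1500, 0), s)  # interior of the second slab -> 2
#' @export
slab_index <- function(point, series) {
  stopifnot(inherits(series, "sectioning_series"))
  if (abs(sqrt(sum(series$normal^2)) - 1) > 1e-9) {
    stop("series normal is not unit length", call. = FALSE)
  }
  if (is.null(dim(point))) {
    point <- matrix(as.numeric(point), ncol = 3L)
  }
  proj <- as.numeric(point %*% series$normal)
  k <- floor((proj - series$offset) / series$width)
  k <- as.integer(k) + 1L
  k[k < 1L | k > series$n_fractions] <- NA_integer_
  k
}

#' Build the fraction template of a series on a masked grid
#'
#' Assigns every in-mask voxel (by its centre location) to the fraction of
#' `series` that contains it, producing the per-voxel fraction label volume
#' and per-fraction voxel counts. Voxels outside the mask, and in-mask voxels
#' whose centres fall outside the series span, are labelled `NA`.
#'
#' @param grid A `voxel_grid`.
#' @param mask A `brain_mask` on the same grid.
#' @param series A `sectioning_series`.
#' @return An object of class `fraction_template` with fields `series`,
#'   `grid`, `fraction` (integer array, `NA` outside) and `fraction_volumes`
#'   (in-mask voxel count per fraction; may contain zeros for slabs the mask
#'   does not reach).
#' @export
build_fraction_template <- function(grid, mask, series) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "brain_mask"),
            inherits(series, "sectioning_series"))
  check_same_grid(grid, mask$grid, "grid and mask")
  proj <- grid_projection(grid, series$normal)
  k <- floor((proj - series$offset) / series$width)
  frac <- as.integer(k) + 1L
  frac[frac < 1L | frac > series$n_fractions] <- NA_integer_
  frac[!mask$inside] <- NA_integer_
  dim(frac) <- grid$shape
  vols <- tabulate(frac, nbins = series$n_fractions)
  if (sum(vols) == 0L) {
    stop(sprintf("empty template: series %s covers zero in-mask voxels", series$series_id),
         call. = FALSE)
  }
  structure(
    list(series = series, grid = grid, fraction = frac, fraction_volumes = vols),
    class = "fraction_template"
  )
}

#' @export
print.fraction_template <- function(x, ...) {
  cat(sprintf(
    "<fraction_template> %s: %d fractions, %s in-mask voxels assigned (%d empty fractions)\n",
    x$series$series_id, x$series$n_fractions,
    format(sum(x$fraction_volumes), big.mark = ","), sum(x$fraction_volumes == 0L)
  ))
  invisible(x)
}

#' Per-fraction voxel counts as a tibble
#' @param x A `fraction_template`.
#' @param ... Unused.
#' @return A tibble with columns `series_id`, `fraction`, `index`, `n_voxels`.
#' @export
tidy.fraction_template <- function(x, ...) {
  tibble::tibble(
    series_id = x$series$series_id,
    fraction = fraction_labels(x$series),
    index = seq_len(x$series$n_fractions),
    n_voxels = x$fraction_volumes
  )
}

#' Joint coverage volume of a set of fraction templates
#'
#' The set of voxels assigned a fraction in every series — the volume on
#' which reconstructed maps are defined (the "common brain volume" of a
#' multi-series design, E80 in the six-series reference design).
#'
#' @param templates Non-empty list of `fraction_template`s on a common grid.
#' @return An object of class `coverage_mask` with fields `grid` and
#'   `covered` (logical array).
#' @export
coverage <- function(templates) {
  if (!is.list(templates) || length(templates) == 0L ||
      !all(vapply(templates, inherits, logical(1), "fraction_template"))) {
    stop("`templates` must be a non-empty list of fraction templates", call. = FALSE)
  }
  grid <- templates[[1]]$grid
  covered <- !is.na(templates[[1]]$fraction)
  for (tp in templates[-1]) {
    check_same_grid(grid, tp$grid, "templates")
    covered <- covered & !is.na(tp$fraction)
  }
  structure(list(grid = grid, covered = covered), class = "coverage_mask")
}

#' @export
print.coverage_mask <- function(x, ...) {
  cat(sprintf("<coverage_mask> %s covered voxels (%.1f mm^3)\n",
              format(sum(x$covered), big.mark = ","),
              sum(x$covered) * x$grid$voxel_size^3 / 1e9))
  invisible(x)
}

# rotate a unit axis vector by `angle_deg` about another coordinate axis
rotate_about <- function(v, axis, angle_deg) {
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  R <- switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
    y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3),
    z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  )
  as.numeric(R %*% v)
}

#' The six-series, 61-fraction reference sectioning design
#'
#' Builds the reference whole-brain design: three orthogonal series S/C/H
#' (sagittal, coronal, horizontal normals along x, y, z) of 9/13/6 fractions,
#' and three slightly oblique counterparts So/Co/Ho of 10/16/7 fractions, all
#' 1,000 um wide — 61 fractions in total. Each oblique normal is the
#' corresponding orthogonal normal rotated by `oblique_angle_deg` about a
#' fixed perpendicular axis (S about z, C about x, H about y). Offsets centre
#' each series' slab span on the mask bounding box.
#'
#' @param grid A `voxel_grid`.
#' @param mask A `brain_mask`; its bounding box must fit within the 9 x 13 x
#'   6 mm spans of the orthogonal series.
#' @param oblique_angle_deg Tilt of the oblique series in degrees
#'   (default 10).
#' @return Named list of six `sectioning_series` (S, C, H, So, Co, Ho).
#' @export
default_design <- function(grid, mask, oblique_angle_deg = 10) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "brain_mask"))
  check_same_grid(grid, mask$grid, "grid and mask")
  spec <- list(
    S  = list(normal = c(1, 0, 0), n = 9L),
    C  = list(normal = c(0, 1, 0), n = 13L),
    H  = list(normal = c(0, 0, 1), n = 6L),
    So = list(normal = rotate_about(c(1, 0, 0), "z", oblique_angle_deg), n = 10L),
    Co = list(normal = rotate_about(c(0, 1, 0), "x", oblique_angle_deg), n = 16L),
    Ho = list(normal = rotate_about(c(0, 0, 1), "y", oblique_angle_deg), n = 7L)
  )
  width <- 1000
  ctr <- voxel_centers(grid, which(mask$inside))
  half <- grid$voxel_size / 2
  out <- vector("list", length(spec))
  names(out) <- names(spec)
  for (id in names(spec)) {
    s <- spec[[id]]
    # project the actual mask onto the normal (half-voxel slack at each end)
    proj <- range(ctr %*% s$normal) + c(-half, half)
    extent <- max(proj) - min(proj)
    span <- s$n * width
    if (extent > span) {
      stop(sprintf(
        "mask extent %.0f um along series %s exceeds its %d x %g um fraction span",
        extent, id, s$n, width
      ), call. = FALSE)
    }
    offset <- (max(proj) + min(proj)) / 2 - span / 2
    out[[id]] <- sectioning_series(id, s$normal, width, offset, s$n)
  }
  out
}

#' Build fraction templates for every series of a design
#'
#' @param grid A `voxel_grid`.
#' @param mask A `brain_mask`.
#' @param design List of `sectioning_series` (e.g. from [default_design()]).
#' @return Named list of `fraction_template`s.
#' @export
build_templates <- function(grid, mask, design) {
  stopifnot(is.list(design))
  lapply(design, function(s) build_fraction_template(grid, mask, s))
}
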