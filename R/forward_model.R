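#' Create a 3D expression density field
#'
#' @param grid A `voxel_grid`.
#' @param value Numeric array of non-negative densities with the grid's
#'   dimensions (a scalar is recycled to a uniform field). `NA` marks voxels
#'   with no defined value (e.g. outside a map's coverage).
#' @return An object of class `density_field`.
#' @export
density_field <- function(grid, value) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(value) == 1L) value <- array(as.numeric(value), dim = grid$shape)
  if (!identical(dim(value), as.integer(grid$shape))) {
    stop("`value` must match the grid's dimensions", call. = FALSE)
  }
  storage.mode(value) <- "double"
  if (any(value < 0, na.rm = TRUE) || any(is.infinite(value))) {
    stop("density values must be finite and non-negative", call. = FALSE)
  }
  structure(list(grid = grid, value = value), class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  v <- x$value[!is.na(x$value)]
  cat(sprintf("<density_field> %d x %d x %d, range [%g, %g]\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# measure one indicator/weighted voxel set through a template: per-fraction
# totals of `w` at linear voxel indices `idx`, divided by fraction volumes.
# Shared by section_field() and the phantom fast path.
section_indices <- function(idx, w, template, statistic = "mean") {
  f <- template$fraction[idx]
  keep <- !is.na(f)
  sums <- numeric(template$series$n_fractions)
  if (any(keep)) {
    acc <- rowsum(w[keep], group = f[keep])
    sums[as.integer(rownames(acc))] <- acc[, 1]
  }
  if (statistic == "sum") return(sums)
  vols <- template$fraction_volumes
  out <- numeric(length(sums))
  nz <- vols > 0L
  out[nz] <- sums[nz] / vols[nz]
  out
}

#' Virtually section a density field into per-fraction measurements
#'
#' The in-silico counterpart of cutting a series of tissue slabs and
#' measuring each fraction's expression density: fraction `k` measures the
#' volume-averaged density (mean of the field over the in-mask voxels
#' assigned to fraction `k`), or the total amount with `statistic = "sum"`.
#'
#' A fraction containing zero in-mask voxels holds no tissue; by default it
#' is reported as 0 (such a value never back-projects into any voxel), while
#' `on_empty = "error"` enforces the strict contract that every fraction must
#' hold tissue.
#'
#' @param field A `density_field`.
#' @param template A `fraction_template` on the same grid.
#' @param mask A `brain_mask`; defaults to the template's own in-mask
#'   assignment.
#' @param statistic `"mean"` (volume-averaged concentration, default) or
#'   `"sum"` (total amount).
#' @param on_empty `"zero"` (default) or `"error"` for fractions with no
#'   in-mask voxels.
#' @return A tibble with columns `series_id`, `fraction`, `index`, `value`
#'   (one row per fraction, in slab order).
#' @export
section_field <- function(field, template, mask = NULL,
                          statistic = c("mean", "sum"),
                          on_empty = c("zero", "error")) {
  stopifnot(inherits(field, "density_field"), inherits(template, "fraction_template"))
  statistic <- match.arg(statistic)
  on_empty <- match.arg(on_empty)
  check_same_grid(field$grid, template$grid, "field and template")
  frac <- template$fraction
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "brain_mask"))
    check_same_grid(field$grid, mask$grid, "field and mask")
    frac <- frac
    frac[!mask$inside] <- NA_integer_
  }
  vols <- tabulate(frac, nbins = template$series$n_fractions)
  if (on_empty == "error" && any(vols == 0L)) {
    stop(sprintf(
      "fraction(s) %s of series %s contain zero in-mask voxels",
      paste(fraction_labels(template$series)[vols == 0L], collapse = ", "),
      template$series$series_id
    ), call. = FALSE)
  }
  keep <- !is.na(frac)
  acc <- rowsum(as.numeric(field$value[keep]), group = frac[keep])
  sums <- numeric(template$series$n_fractions)
  sums[as.integer(rownames(acc))] <- acc[, 1]
  value <- if (statistic == "sum") sums else ifelse(vols > 0L, sums / pmax(vols, 1L), 0)
  tibble::tibble(
    series_id = template$series$series_id,
    fraction = fraction_labels(template$series),
    index = seq_len(template$series$n_fractions),
    value = as.numeric(value)
  )
}

#' Section a field through every series of a design
#'
#' @inheritParams section_field
#' @param templates List of `fraction_template`s.
#' @return A tibble stacking [section_field()] output for all series (61 rows
#'   in the reference design).
#' @export
section_design <- function(field, templates, mask = NULL,
                           statistic = c("mean", "sum"),
                           on_empty = c("zero", "error")) {
  statistic <- match.arg(statistic)
  on_empty <- match.arg(on_empty)
  dplyr::bind_rows(lapply(templates, function(tp) {
    section_field(field, tp, mask, statistic = statistic, on_empty = on_empty)
  }))
}

#' Apply multiplicative log-normal measurement noise to fraction data
#'
#' Models microarray measurement variability as an independent log-normal
#' factor per measurement (log-mean 0, log-sd `sdlog`), which preserves
#' non-negativity and gives intensity-proportional errors.
#'
#' @param data A fraction-data tibble with a `value` column (e.g. from
#'   [section_field()] or [section_design()]).
#' @param sdlog Standard deviation of the natural-log noise factor (>= 0;
#'   0 returns the input unchanged).
#' @param seed Integer seed; the same seed reproduces the same noise.
#' @return The tibble with `value` perturbed.
#' @export
add_measurement_noise <- function(data, sdlog, seed) {
  stopifnot(is.data.frame(data), "value" %in% names(data))
  if (!is.numeric(sdlog) || length(sdlog) != 1L || is.na(sdlog) || sdlog < 0) {
    stop("`sdlog` must be a single non-negative number", call. = FALSE)
  }
  if (sdlog == 0) return(data)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  data$value <- data$value * rlnorm(nrow(data), meanlog = 0, sdlog = sdlog)
  data
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
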