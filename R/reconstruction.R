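#' Pseudo-back-projection of fraction data into the volume
#'
#' Assigns each fraction's measured density to every voxel of that fraction —
#' the tomographic back-projection step. Voxels not assigned to any fraction
#' of the series (outside the mask or the series span) are `NA`.
#'
#' @param data Fraction data for one series: a tibble with columns `index`
#'   and `value` (as from [section_field()]), or a bare numeric vector of
#'   length `n_fractions` in slab order.
#' @param template The series' `fraction_template`.
#' @return A `density_field` (piecewise constant along the series normal).
#' @export
back_project <- function(data, template) {
  stopifnot(inherits(template, "fraction_template"))
  nf <- template$series$n_fractions
  if (is.data.frame(data)) {
    stopifnot(all(c("index", "value") %in% names(data)))
    if (nrow(data) != nf) {
      stop(sprintf("fraction data has %d rows but series %s has %d fractions",
                   nrow(data), template$series$series_id, nf), call. = FALSE)
    }
    v <- numeric(nf)
    v[data$index] <- data$value
  } else {
    v <- as.numeric(data)
    if (length(v) != nf) {
      stop(sprintf("fraction data has length %d but series %s has %d fractions",
                   length(v), template$series$series_id, nf), call. = FALSE)
    }
  }
  if (any(v < 0, na.rm = TRUE)) stop("fraction values must be non-negative", call. = FALSE)
  vol <- v[template$fraction]   # NA template entries propagate to NA voxels
  dim(vol) <- template$grid$shape
  density_field(template$grid, vol)
}

#' Reconstruct a 3D expression map from multi-series fraction data
#'
#' The core tomographic reconstruction: back-projects each series' fraction
#' values into the volume and averages the back-projections voxel-wise
#' (unweighted arithmetic mean over series). The map is defined only on the
#' joint coverage volume — voxels assigned a fraction in every series.
#'
#' @param all_series_data Fraction data for the series: either a single
#'   tibble with columns `series_id`, `index`, `value` (as from
#'   [section_design()]) or a list of per-series tibbles/vectors ordered like
#'   `templates`.
#' @param templates List of `fraction_template`s (named by series id when
#'   `all_series_data` is a combined tibble).
#' @param probe_id Optional probe identifier carried on the map.
#' @return An object of class `expression_map` with fields `grid`,
#'   `probe_id`, `value` (array, `NA` outside coverage), `coverage`
#'   (a `coverage_mask`) and `cutoff` (unset until [cutoff_filter()]).
#' @export
reconstruct <- function(all_series_data, templates, probe_id = NA_character_) {
  if (!is.list(templates) || length(templates) == 0L) {
    stop("`templates` must be a non-empty list", call. = FALSE)
  }
  if (is.data.frame(all_series_data)) {
    stopifnot(all(c("series_id", "index", "value") %in% names(all_series_data)))
    ids <- vapply(templates, function(tp) tp$series$series_id, character(1))
    all_series_data <- lapply(ids, function(id) {
      d <- all_series_data[all_series_data$series_id == id, , drop = FALSE]
      if (nrow(d) == 0L) stop(sprintf("no fraction data for series %s", id), call. = FALSE)
      d[order(d$index), , drop = FALSE]
    })
  }
  if (length(all_series_data) != length(templates)) {
    stop("need one fraction-data set per template", call. = FALSE)
  }
  cov <- coverage(templates)
  if (!any(cov$covered)) stop("no common volume: joint coverage is empty", call. = FALSE)
  grid <- cov$grid
  acc <- array(0, dim = grid$shape)
  for (i in seq_along(templates)) {
    bp <- back_project(all_series_data[[i]], templates[[i]])
    acc <- acc + bp$value   # NA outside a series' coverage propagates
  }
  value <- acc / length(templates)
  value[!cov$covered] <- NA_real_
  structure(
    list(grid = grid, probe_id = probe_id, value = value, coverage = cov,
         cutoff = NULL),
    class = "expression_map"
  )
}

#' @export
print.expression_map <- function(x, ...) {
  v <- x$value[x$coverage$covered]
  cat(sprintf("<expression_map>%s %s covered voxels, range [%g, %g]%s\n",
              if (is.na(x$probe_id)) "" else paste0(" ", x$probe_id),
              format(sum(x$coverage$covered), big.mark = ","),
              min(v), max(v),
              if (is.null(x$cutoff)) "" else
                sprintf(", cutoff threshold %g", x$cutoff$threshold)))
  invisible(x)
}

#' Threshold a map with the high-density cutoff filter
#'
#' The "80% cutoff filter": retains the voxels of a reconstructed map whose
#' value is at least `keep_fraction` of the map's maximum over the coverage
#' volume (default method `"max"`). The `"quantile"` method instead
#' thresholds at the `keep_fraction` quantile of the positive covered values;
#' it exists for sensitivity analysis of the cutoff definition — the
#' max-referenced threshold is the calibrated default.
#'
#' @param map An `expression_map` with a positive maximum.
#' @param keep_fraction Threshold level in (0, 1); default 0.8.
#' @param method `"max"` (threshold = keep_fraction x map maximum, default)
#'   or `"quantile"` (threshold = keep_fraction quantile of positive values).
#' @return An object of class `suprathreshold_region` with fields `grid`,
#'   `member` (logical array), `threshold`, `keep_fraction`, `method`.
#' @export
cutoff_filter <- function(map, keep_fraction = 0.8, method = c("max", "quantile")) {
  stopifnot(inherits(map, "expression_map"))
  method <- match.arg(method)
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      keep_fraction <= 0 || keep_fraction >= 1) {
    stop("`keep_fraction` must be a single number in (0, 1)", call. = FALSE)
  }
  v <- map$value[map$coverage$covered]
  m <- max(v)
  if (!is.finite(m) || m <= 0) stop("no signal: map has no positive value", call. = FALSE)
  threshold <- if (method == "max") {
    keep_fraction * m
  } else {
    as.numeric(quantile(v[v > 0], probs = keep_fraction, names = FALSE))
  }
  member <- !is.na(map$value) & map$value >= threshold
  structure(
    list(grid = map$grid, member = member, threshold = threshold,
         keep_fraction = keep_fraction, method = method),
    class = "suprathreshold_region"
  )
}

#' @export
print.suprathreshold_region <- function(x, ...) {
  cat(sprintf("<suprathreshold_region> %s voxels at threshold %g (%g x map %s)\n",
              format(sum(x$member), big.mark = ","), x$threshold,
              x$keep_fraction, x$method))
  invisible(x)
}

#' Attach a cutoff threshold to a map
#'
#' Convenience: runs [cutoff_filter()] and records the resulting threshold on
#' the map (required by suprathreshold area quantification).
#'
#' @inheritParams cutoff_filter
#' @return The map with its `cutoff` field set.
#' @export
apply_cutoff <- function(map, keep_fraction = 0.8, method = c("max", "quantile")) {
  region <- cutoff_filter(map, keep_fraction, method)
  map$cutoff <- list(threshold = region$threshold,
                     keep_fraction = region$keep_fraction, method = region$method)
  map
}

#' Convert a map to 8-bit intensity grades
#'
#' Rescales to `round(255 * value / max)` with round-half-away-from-zero
#' (127.5 becomes 128). For export and visual comparison only — quantification
#' always uses the raw averaged densities.
#'
#' @param map An `expression_map` with a positive maximum.
#' @return Integer array (`NA` outside coverage) with values in 0..255.
#' @export
to_8bit <- function(map) {
  stopifnot(inherits(map, "expression_map"))
  v <- map$value[map$coverage$covered]
  m <- max(v)
  if (!is.finite(m) || m <= 0) stop("no signal: map has no positive value", call. = FALSE)
  out <- array(NA_integer_, dim = map$grid$shape)
  out[map$coverage$covered] <- as.integer(floor(255 * v / m + 0.5))
  out
}
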