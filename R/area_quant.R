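#' Define a spherical sampling area
#'
#' Labels an area of interest as a voxelized sphere at a given centroid
#' (500 um diameter by default, the sampling-area convention for inter-
#' dataset comparison). With `mirror = TRUE` the x-mirrored twin about the
#' mid-sagittal plane is attached, and downstream densities are averaged
#' bilaterally.
#'
#' @param grid A `voxel_grid`.
#' @param centroid Numeric 3-vector, area centre in micrometres.
#' @param diameter Sphere diameter in micrometres (default 500).
#' @param area_id Label for the area.
#' @param mirror Attach the bilateral twin mirrored about `mirror_x`.
#' @param mirror_x x-coordinate (um) of the mid-sagittal mirror plane
#'   (default 0, the synthetic brain's symmetry plane).
#' @param coverage Optional `coverage_mask` or `brain_mask`; the centroid
#'   must then lie inside it.
#' @return An object of class `area_label` with fields `area_id`, `kind`,
#'   `grid`, `voxels` (linear indices) and optionally `voxels_mirror`.
#' @export
sphere_area <- function(grid, centroid, diameter = 500, area_id = "area",
                        mirror = FALSE, mirror_x = 0, coverage = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  centroid <- as.numeric(centroid)
  stopifnot(length(centroid) == 3L)
  if (!is.null(coverage)) {
    inside <- if (inherits(coverage, "coverage_mask")) coverage$covered else coverage$inside
    ci <- round((centroid - grid$origin) / grid$voxel_size + 0.5)
    if (any(ci < 1) || any(ci > grid$shape) ||
        !inside[ci[1], ci[2], ci[3]]) {
      stop(sprintf("centroid of %s lies outside the coverage volume", area_id),
           call. = FALSE)
    }
  }
  vox <- sphere_voxels(grid, centroid, diameter)
  if (!length(vox)) stop(sprintf("area %s contains no voxels", area_id), call. = FALSE)
  out <- structure(
    list(area_id = area_id, kind = "sphere", grid = grid, voxels = vox,
         centroid = centroid, diameter = diameter),
    class = "area_label"
  )
  if (mirror) {
    mc <- centroid
    mc[1] <- 2 * mirror_x - mc[1]
    out$voxels_mirror <- sphere_voxels(grid, mc, diameter)
  }
  out
}

#' Define an area from an arbitrary voxel mask
#'
#' @param grid A `voxel_grid`.
#' @param member Logical array on the grid, or integer vector of linear
#'   voxel indices.
#' @param area_id Label for the area.
#' @return An `area_label` of kind `"mask"`.
#' @export
mask_area <- function(grid, member, area_id = "area") {
  stopifnot(inherits(grid, "voxel_grid"))
  vox <- if (is.logical(member)) {
    stopifnot(identical(dim(member), as.integer(grid$shape)))
    which(member)
  } else {
    as.integer(member)
  }
  if (!length(vox)) stop(sprintf("area %s is empty", area_id), call. = FALSE)
  structure(
    list(area_id = area_id, kind = "mask", grid = grid, voxels = vox),
    class = "area_label"
  )
}

#' @export
print.area_label <- function(x, ...) {
  cat(sprintf("<area_label> %s (%s): %s voxels%s\n", x$area_id, x$kind,
              format(length(x$voxels), big.mark = ","),
              if (is.null(x$voxels_mirror)) "" else
                sprintf(" + %s mirrored", format(length(x$voxels_mirror), big.mark = ","))))
  invisible(x)
}

# density of one voxel set under the stated quantification rule
.area_density_one <- function(map, vox, mode, threshold) {
  v <- map$value[vox]
  if (mode == "raw") return(mean(v, na.rm = TRUE))
  # suprathreshold: voxels below threshold (or outside coverage) add 0 to
  # the numerator but still count in the area volume
  v[is.na(v) | v < threshold] <- 0
  sum(v) / length(vox)
}

#' Mean expression density of a map in an area
#'
#' Suprathreshold mode implements the quantification rule of the mapping
#' pipeline: the total of map values at or above the cutoff threshold within
#' the area, divided by the area's volume (its full voxel count — sub-
#' threshold voxels contribute zero to the numerator but still count in the
#' denominator). Raw mode is the plain mean of map values in the area (used
#' for inter-dataset comparison, without per-gene normalisation). Bilateral
#' areas are averaged over the two sides.
#'
#' @param map An `expression_map`; for suprathreshold mode its cutoff must
#'   have been set with [apply_cutoff()].
#' @param area An `area_label` (or list of them).
#' @param mode `"suprathreshold"` (default) or `"raw"`.
#' @return A tibble with columns `area_id`, `probe_id`, `mode`, `density`,
#'   `bilateral`.
#' @export
area_density <- function(map, area, mode = c("suprathreshold", "raw")) {
  stopifnot(inherits(map, "expression_map"))
  mode <- match.arg(mode)
  if (inherits(area, "area_label")) area <- list(area)
  stopifnot(all(vapply(area, inherits, logical(1), "area_label")))
  threshold <- NULL
  if (mode == "suprathreshold") {
    if (is.null(map$cutoff)) {
      stop("suprathreshold mode needs a cutoff threshold: call apply_cutoff() first",
           call. = FALSE)
    }
    threshold <- map$cutoff$threshold
  }
  rows <- lapply(area, function(a) {
    check_same_grid(map$grid, a$grid, "map and area")
    d <- .area_density_one(map, a$voxels, mode, threshold)
    bilateral <- !is.null(a$voxels_mirror)
    if (bilateral) {
      d <- (d + .area_density_one(map, a$voxels_mirror, mode, threshold)) / 2
    }
    tibble::tibble(area_id = a$area_id, probe_id = map$probe_id,
                   mode = mode, density = d, bilateral = bilateral)
  })
  dplyr::bind_rows(rows)
}

#' Define an area from a marker gene's expression map
#'
#' The marker-gene-defined region: the suprathreshold region of the marker's
#' reconstructed map under the cutoff filter. Disconnected suprathreshold
#' components are all retained (no connectivity pruning).
#'
#' @param map The marker gene's `expression_map`.
#' @param keep_fraction Cutoff level (default 0.8).
#' @param method Cutoff method, see [cutoff_filter()].
#' @param area_id Label; defaults to the map's probe id.
#' @return An `area_label` of kind `"marker"`.
#' @export
marker_area <- function(map, keep_fraction = 0.8, method = c("max", "quantile"),
                        area_id = NULL) {
  region <- cutoff_filter(map, keep_fraction, method)
  vox <- which(region$member)
  if (!length(vox)) stop("marker map has an empty suprathreshold region", call. = FALSE)
  structure(
    list(area_id = area_id %||% paste0(map$probe_id, "(+)"), kind = "marker",
         grid = map$grid, voxels = vox, threshold = region$threshold),
    class = "area_label"
  )
}

#' Combine areas by expression logic
#'
#' Builds the voxel set `intersection(positive) minus union(negative)` — the
#' combined-marker construction, e.g. areas expressing one gene but not
#' another (Htt-positive / Bdnf-negative in the motivating disease
#' analysis).
#'
#' @param positive Non-empty list of `area_label`s to intersect.
#' @param negative Optional list of `area_label`s to subtract.
#' @param area_id Label for the combined area.
#' @return An `area_label` of kind `"combined"`; an empty result is an
#'   error.
#' @export
combine_masks <- function(positive, negative = list(), area_id = NULL) {
  if (inherits(positive, "area_label")) positive <- list(positive)
  if (inherits(negative, "area_label")) negative <- list(negative)
  if (!length(positive)) stop("need at least one positive area", call. = FALSE)
  stopifnot(all(vapply(c(positive, negative), inherits, logical(1), "area_label")))
  grid <- positive[[1]]$grid
  vox <- positive[[1]]$voxels
  for (a in positive[-1]) {
    check_same_grid(grid, a$grid, "areas")
    vox <- intersect(vox, a$voxels)
  }
  for (a in negative) {
    check_same_grid(grid, a$grid, "areas")
    vox <- setdiff(vox, a$voxels)
  }
  if (!length(vox)) stop("combined area is empty", call. = FALSE)
  if (is.null(area_id)) {
    area_id <- paste0(
      paste(vapply(positive, `[[`, character(1), "area_id"), collapse = "&"),
      if (length(negative)) {
        paste0("-", paste(vapply(negative, `[[`, character(1), "area_id"), collapse = "-"))
      } else ""
    )
  }
  structure(
    list(area_id = area_id, kind = "combined", grid = grid, voxels = sort(vox)),
    class = "area_label"
  )
}

#' Overlap of an area with the regions of a label volume
#'
#' For every region of an integer atlas, the percentage of the region's
#' volume covered by the area, plus the area's share of the whole labelled
#' volume.
#'
#' @param area An `area_label`.
#' @param atlas Integer array on the same grid (0 or `NA` = background) or a
#'   named list `list(labels = array, names = character)`.
#' @return A tibble with columns `region`, `region_voxels`,
#'   `overlap_voxels`, `percent_of_region`; attribute `percent_of_whole`
#'   (also included as a final row with `region = "(whole)"`).
#' @export
region_overlap <- function(area, atlas) {
  stopifnot(inherits(area, "area_label"))
  region_names <- NULL
  if (is.list(atlas) && !is.null(atlas$labels)) {
    region_names <- atlas$names
    atlas <- atlas$labels
  }
  if (!identical(dim(atlas), as.integer(area$grid$shape))) {
    stop("atlas dimensions do not match the area's grid", call. = FALSE)
  }
  lab <- as.integer(atlas)
  lab[is.na(lab)] <- 0L
  ids <- sort(unique(lab[lab > 0L]))
  region_voxels <- tabulate(lab, nbins = max(ids))[ids]
  in_area <- lab[area$voxels]
  overlap <- tabulate(in_area[in_area > 0L], nbins = max(ids))[ids]
  whole <- sum(lab > 0L)
  pct_whole <- 100 * sum(in_area > 0L) / whole
  pct_region <- 100 * overlap / region_voxels
  nm <- if (!is.null(region_names)) region_names[ids] else as.character(ids)
  out <- tibble::tibble(
    region = c(nm, "(whole)"),
    region_voxels = c(region_voxels, whole),
    overlap_voxels = c(overlap, sum(in_area > 0L)),
    percent_of_region = c(pct_region, pct_whole)
  )
  attr(out, "percent_of_whole") <- pct_whole
  out
}

#' Compare area densities between two expression datasets
#'
#' Matches two area-by-gene expression tables (e.g. a reconstructed dataset
#' against an independently measured reference), selecting per platform the
#' probe with the highest mean intensity for each gene, and reports the
#' Pearson correlation of log2 values over all shared (gene, area) pairs
#' plus a coefficient-of-variation curve: for each 0.02-quantile window of
#' the reference values, the CV (sd/mean of untransformed values, after
#' trimming 0.1% from both ends) of the matched test values.
#'
#' @param test,ref Data frames with columns `gene`, `probe_id`, `area_id`,
#'   `value` (`probe_id` optional — defaults to one probe per gene).
#' @param window Quantile window width for the CV curve (default 0.02).
#' @param trim Fraction trimmed from each end within a window (default
#'   0.001).
#' @return A list of class `dataset_comparison`: `r` (Pearson r on log2
#'   values), `n_pairs`, `matched` (tibble of matched pairs) and `cv`
#'   (tibble: `quantile_lo`, `quantile_hi`, `cv`, `n`).
#' @export
compare_datasets <- function(test, ref, window = 0.02, trim = 0.001) {
  pick_probe <- function(d) {
    d <- tibble::as_tibble(d)
    if (!"probe_id" %in% names(d)) d$probe_id <- d$gene
    stopifnot(all(c("gene", "area_id", "value") %in% names(d)))
    best <- d |>
      dplyr::summarise(m = mean(.data$value), .by = c("gene", "probe_id")) |>
      dplyr::slice_max(.data$m, n = 1, by = "gene", with_ties = FALSE)
    dplyr::semi_join(d, best, by = c("gene", "probe_id"))
  }
  a <- pick_probe(test); b <- pick_probe(ref)
  matched <- dplyr::inner_join(
    dplyr::select(a, "gene", "area_id", test = "value"),
    dplyr::select(b, "gene", "area_id", ref = "value"),
    by = c("gene", "area_id")
  )
  if (nrow(matched) < 2L) stop("fewer than 2 shared (gene, area) pairs", call. = FALSE)
  if (any(matched$test <= 0) || any(matched$ref <= 0)) {
    stop("values must be positive for the log2 comparison", call. = FALSE)
  }
  # a degenerate (constant) dataset has undefined r, reported as NA
  r <- suppressWarnings(cor(log2(matched$test), log2(matched$ref)))
  qs <- seq(0, 1, by = window)
  br <- quantile(matched$ref, probs = qs, names = FALSE)
  win <- findInterval(matched$ref, br, rightmost.closed = TRUE, all.inside = TRUE)
  cv <- lapply(seq_len(length(qs) - 1L), function(w) {
    x <- matched$test[win == w]
    n <- length(x)
    if (n >= 2L) {
      lim <- quantile(x, probs = c(trim, 1 - trim), names = FALSE)
      x <- x[x >= lim[1] & x <= lim[2]]
    }
    tibble::tibble(
      quantile_lo = qs[w], quantile_hi = qs[w + 1L],
      cv = if (length(x) >= 2L) sd(x) / mean(x) else NA_real_,
      n = n
    )
  })
  structure(
    list(r = r, n_pairs = nrow(matched), matched = matched,
         cv = dplyr::bind_rows(cv)),
    class = "dataset_comparison"
  )
}

#' @export
print.dataset_comparison <- function(x, ...) {
  cat(sprintf("<dataset_comparison> r = %.3f over %s (gene, area) pairs\n",
              x$r, format(x$n_pairs, big.mark = ",")))
  invisible(x)
}

#' @export
glance.dataset_comparison <- function(x, ...) {
  tibble::tibble(r = x$r, n_pairs = x$n_pairs,
                 median_cv = median(x$cv$cv, na.rm = TRUE))
}

#' @export
tidy.dataset_comparison <- function(x, ...) x$cv

#' CV-by-quantile curve of a dataset comparison
#' @param object A `dataset_comparison`.
#' @param ... Unused.
#' @return A ggplot of CV against the reference quantile window.
#' @export
autoplot.dataset_comparison <- function(object, ...) {
  ggplot2::ggplot(object$cv,
                  ggplot2::aes(x = (.data$quantile_lo + .data$quantile_hi) / 2,
                               y = .data$cv)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference expression quantile", y = "CV (sd/mean)") +
    ggplot2::theme_minimal()
}

#' Compare expression densities across areas against a reference area
#'
#' Reports each area's suprathreshold expression density as a percentage of
#' the reference area's density, with a two-sided Student's t-test of the
#' per-voxel map values in the area against those in the reference area.
#' The voxelwise t-test treats voxels as observations; neighbouring voxels
#' of a back-projected map are strongly dependent, so this is a descriptive
#' statistic, not an independence-respecting inference.
#'
#' @param map An `expression_map` with its cutoff set ([apply_cutoff()]).
#' @param areas List of `area_label`s.
#' @param reference_area The reference `area_label` (density = 100%).
#' @param mode Density mode passed to [area_density()].
#' @param alpha Significance level annotated in the output (default 0.01).
#' @return A tibble with columns `area_id`, `density`, `percent_of_reference`,
#'   `p_value`, `significant`.
#' @export
compare_area_densities <- function(map, areas, reference_area,
                                   mode = c("suprathreshold", "raw"),
                                   alpha = 0.01) {
  stopifnot(inherits(map, "expression_map"), inherits(reference_area, "area_label"))
  mode <- match.arg(mode)
  if (inherits(areas, "area_label")) areas <- list(areas)
  ref_d <- area_density(map, reference_area, mode)$density
  ref_v <- map$value[reference_area$voxels]
  ref_v <- ref_v[!is.na(ref_v)]
  rows <- lapply(areas, function(a) {
    d <- area_density(map, a, mode)$density
    v <- map$value[a$voxels]
    v <- v[!is.na(v)]
    p <- if (identical(sort(a$voxels), sort(reference_area$voxels))) {
      1
    } else if (length(v) >= 2L && length(ref_v) >= 2L &&
               (sd(v) > 0 || sd(ref_v) > 0)) {
      t.test(v, ref_v, alternative = "two.sided")$p.value
    } else {
      NA_real_
    }
    tibble::tibble(area_id = a$area_id, density = d,
                   percent_of_reference = 100 * d / ref_d, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}
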