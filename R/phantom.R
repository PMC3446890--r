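#' Sample random phantom test spheres inside a mask
#'
#' Sphere centres are drawn uniformly from the in-mask voxel centres, so
#' spheres near the tissue boundary may protrude beyond the mask — the
#' situation responsible for poorly reconstructed phantoms.
#'
#' @param mask A `brain_mask`.
#' @param n Number of spheres (>= 1).
#' @param diameter Sphere diameter in micrometres (default 1000).
#' @param seed Integer seed; the same seed reproduces the same spheres.
#' @return A tibble with columns `sphere`, `x`, `y`, `z` (centre, um),
#'   `diameter`.
#' @export
sample_spheres <- function(mask, n, diameter = 1000, seed = 1) {
  stopifnot(inherits(mask, "brain_mask"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be an integer >= 1", call. = FALSE)
  if (diameter <= 0) stop("`diameter` must be positive", call. = FALSE)
  idx <- which(mask$inside)
  if (!length(idx)) stop("mask has no inside voxels", call. = FALSE)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  ctr <- voxel_centers(mask$grid, sample(idx, n, replace = TRUE))
  tibble::tibble(
    sphere = seq_len(n),
    x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
    diameter = as.numeric(diameter)
  )
}

# Precomputed reconstruction context: covered voxel ids and, per series, the
# fraction index of every covered voxel plus fraction volumes. Lets a sphere
# be reconstructed with a handful of vectorised lookups.
phantom_context <- function(templates, mask) {
  cov <- coverage(templates)
  cov_idx <- which(cov$covered)
  if (!length(cov_idx)) stop("no common volume: joint coverage is empty", call. = FALSE)
  list(
    grid = cov$grid,
    coverage = cov,
    cov_idx = cov_idx,
    fidx = vapply(templates, function(tp) tp$fraction[cov_idx],
                  integer(length(cov_idx))),
    templates = templates,
    mask = mask
  )
}

# core of evaluate_sphere, on a prebuilt context
eval_sphere_ctx <- function(ctx, center, diameter, keep_fraction = 0.8,
                            method = "max") {
  svox <- sphere_voxels(ctx$grid, center, diameter)
  n_sphere <- length(svox)
  n_series <- length(ctx$templates)
  # noiseless forward model: unit density inside the sphere, sectioned
  # through every template (mean over in-mask voxels of each fraction)
  vals <- numeric(length(ctx$cov_idx))
  any_signal <- FALSE
  for (s in seq_len(n_series)) {
    d <- section_indices(svox, rep(1, n_sphere), ctx$templates[[s]])
    if (any(d > 0)) any_signal <- TRUE
    vals <- vals + d[ctx$fidx[, s]]
  }
  if (!any_signal || n_sphere == 0L) {
    # sphere entirely outside the covered tissue: the no-TP case
    return(tibble::tibble(tp_percent = 0, diameter_ratio = 0,
                          n_region_voxels = 0L, n_sphere_voxels = n_sphere))
  }
  vals <- vals / n_series
  m <- max(vals)
  threshold <- if (method == "max") {
    keep_fraction * m
  } else {
    as.numeric(quantile(vals[vals > 0], probs = keep_fraction, names = FALSE))
  }
  region <- ctx$cov_idx[vals >= threshold]
  vs <- ctx$grid$voxel_size
  tp <- if (n_sphere) 100 * length(intersect(region, svox)) / n_sphere else 0
  eqd <- (6 * length(region) * vs^3 / pi)^(1 / 3)
  tibble::tibble(
    tp_percent = tp,
    diameter_ratio = eqd / diameter,
    n_region_voxels = length(region),
    n_sphere_voxels = n_sphere
  )
}

#' Reconstruct and score one phantom test sphere
#'
#' Builds the unit-density sphere field, sections it through every template
#' (noiseless), reconstructs by back-projection and series averaging,
#' applies the cutoff filter, and scores the result: `tp_percent` is the
#' percentage of the sphere's voxelized volume overlapped by the
#' suprathreshold region, `diameter_ratio` the equivalent-sphere diameter of
#' that region divided by the sphere diameter. A sphere entirely outside the
#' covered tissue scores 0/0 (the no-TP case, not an error).
#'
#' @param sphere A one-row tibble from [sample_spheres()], or a numeric
#'   centre 3-vector.
#' @param templates List of `fraction_template`s.
#' @param mask A `brain_mask`.
#' @param keep_fraction Cutoff level (default 0.8).
#' @param diameter Sphere diameter in um (taken from `sphere` if present).
#' @param method Cutoff method, see [cutoff_filter()].
#' @return A one-row tibble: `tp_percent`, `diameter_ratio`,
#'   `n_region_voxels`, `n_sphere_voxels`.
#' @export
evaluate_sphere <- function(sphere, templates, mask, keep_fraction = 0.8,
                            diameter = 1000, method = c("max", "quantile")) {
  method <- match.arg(method)
  if (is.data.frame(sphere)) {
    stopifnot(nrow(sphere) == 1L)
    center <- c(sphere$x, sphere$y, sphere$z)
    if ("diameter" %in% names(sphere)) diameter <- sphere$diameter
  } else {
    center <- as.numeric(sphere)
  }
  ctx <- phantom_context(templates, mask)
  eval_sphere_ctx(ctx, center, diameter, keep_fraction, method)
}

#' Run the phantom-sphere accuracy experiment
#'
#' The computational validation of the tomographic mapping accuracy: `n`
#' uniform-density spheres are placed at random in the tissue mask, each is
#' virtually sectioned by every series of the design (noiseless),
#' reconstructed, thresholded with the cutoff filter, and scored by
#' true-positive overlap and diameter inflation. Summary statistics report
#' the percentage of spheres with at least 5% TP, with more than 95% TP
#' (the histogram mode bin in the reference experiment), with no TP at all,
#' and the mean diameter ratio with its standard error.
#'
#' @param design List of `sectioning_series` (e.g. [default_design()]) or a
#'   prebuilt list of `fraction_template`s.
#' @param mask A `brain_mask`.
#' @param n Number of spheres (default 1366).
#' @param diameter Sphere diameter in um (default 1000).
#' @param seed Seed for sphere placement (default 1).
#' @param keep_fraction Cutoff level (default 0.8).
#' @param method Cutoff method, see [cutoff_filter()].
#' @return An object of class `phantom_summary`: list with `records` (per-
#'   sphere tibble), `summary` (named list of the headline statistics),
#'   `histogram` (tibble of 5-percentage-point TP bins), and the run
#'   parameters.
#' @export
run_phantom_experiment <- function(design, mask, n = 1366, diameter = 1000,
                                   seed = 1, keep_fraction = 0.8,
                                   method = c("max", "quantile")) {
  method <- match.arg(method)
  stopifnot(inherits(mask, "brain_mask"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be an integer >= 1", call. = FALSE)
  if (all(vapply(design, inherits, logical(1), "sectioning_series"))) {
    templates <- build_templates(mask$grid, mask, design)
  } else if (all(vapply(design, inherits, logical(1), "fraction_template"))) {
    templates <- design
  } else {
    stop("`design` must be a list of sectioning series or fraction templates",
         call. = FALSE)
  }
  ctx <- phantom_context(templates, mask)
  spheres <- sample_spheres(mask, n, diameter, seed)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    recs[[i]] <- eval_sphere_ctx(
      ctx, c(spheres$x[i], spheres$y[i], spheres$z[i]),
      spheres$diameter[i], keep_fraction, method)
  }
  records <- dplyr::bind_cols(spheres, dplyr::bind_rows(recs))

  tp <- records$tp_percent
  ratio <- records$diameter_ratio[records$n_region_voxels > 0]
  # 5-point bins [0,5), [5,10), ..., [95,100]
  breaks <- seq(0, 100, by = 5)
  bin_idx <- findInterval(tp, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin_idx, nbins = 20L)
  histogram <- tibble::tibble(
    bin = sprintf("[%d,%d%s", head(breaks, -1), breaks[-1],
                  c(rep(")", 19), "]")),
    lower = head(breaks, -1),
    upper = breaks[-1],
    count = counts
  )
  summary <- list(
    n_spheres = n,
    percent_tp_ge_5 = 100 * mean(tp >= 5),
    percent_tp_gt_95 = 100 * mean(tp > 95),
    percent_tp_zero = 100 * mean(tp == 0),
    mean_diameter_ratio = mean(ratio),
    sem_diameter_ratio = sd(ratio) / sqrt(length(ratio)),
    mode_bin = histogram$bin[which.max(histogram$count)]
  )
  structure(
    list(records = records, summary = summary, histogram = histogram,
         n = n, diameter = diameter, seed = as.integer(seed),
         keep_fraction = keep_fraction, method = method),
    class = "phantom_summary"
  )
}

#' @export
print.phantom_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<phantom_summary> %d spheres of %g um (cutoff %g %s)\n",
           "  TP >= 5%%: %.1f%%   TP > 95%%: %.1f%%   no TP: %.1f%%\n",
           "  mean diameter ratio: %.2f +/- %.2g (sem)\n"),
    x$n, x$diameter, x$keep_fraction, x$method,
    s$percent_tp_ge_5, s$percent_tp_gt_95, s$percent_tp_zero,
    s$mean_diameter_ratio, s$sem_diameter_ratio))
  invisible(x)
}

#' Per-sphere phantom records
#' @param x A `phantom_summary`.
#' @param ... Unused.
#' @return Tibble of per-sphere evaluation records.
#' @export
tidy.phantom_summary <- function(x, ...) x$records

#' One-row phantom summary statistics
#' @param x A `phantom_summary`.
#' @param ... Unused.
#' @return One-row tibble of the headline statistics.
#' @export
glance.phantom_summary <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' Histogram of phantom true-positive rates
#' @param object A `phantom_summary`.
#' @param ... Unused.
#' @return A ggplot: sphere counts per 5-percentage-point TP bin.
#' @export
autoplot.phantom_summary <- function(object, ...) {
  h <- object$histogram
  h$bin <- factor(h$bin, levels = h$bin)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "true-positive overlap (% of sphere volume)",
      y = "test spheres",
      title = sprintf("%d phantom spheres, %g um", object$n, object$diameter)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
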