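# Ellipsoid components of the synthetic brain (micrometres): a main
# cerebrum, a posterior-ventral cerebellar bulge and a ventral stem. The
# union fits the 9 x 13 x 6 mm spans of the reference design and is
# x-mirror symmetric by construction.
.brain_components <- function(scale = 1) {
  list(
    cerebrum   = list(center = c(0,   800,   300) * scale,
                      semi   = c(4300, 5450, 2500) * scale),
    cerebellum = list(center = c(0, -4600,  -200) * scale,
                      semi   = c(2550, 1900, 1750) * scale),
    stem       = list(center = c(0, -3300, -1600) * scale,
                      semi   = c(1500, 2500, 1100) * scale)
  )
}

#' Default voxel grid for the synthetic brain
#'
#' A grid centred on the synthetic brain's bounding box with a 600-um margin
#' on every side (room for phantom spheres protruding beyond the tissue).
#'
#' @param voxel_size Isotropic voxel edge in micrometres (default 100).
#' @param scale Scale factor applied to the brain (default 1).
#' @return A `voxel_grid`.
#' @export
default_grid <- function(voxel_size = 100, scale = 1) {
  comps <- .brain_components(scale)
  lo <- c(Inf, Inf, Inf); hi <- -lo
  for (cp in comps) {
    lo <- pmin(lo, cp$center - cp$semi)
    hi <- pmax(hi, cp$center + cp$semi)
  }
  margin <- 600
  shape <- ceiling((hi - lo + 2 * margin) / voxel_size)
  center <- (hi + lo) / 2
  voxel_grid(shape, voxel_size, origin = center - shape * voxel_size / 2)
}

#' Parametric brain-shaped tissue mask
#'
#' A deterministic, x-mirror-symmetric mask built as the union of three
#' axis-aligned ellipsoids (cerebrum, posterior cerebellar bulge, ventral
#' stem), sized to fit the 9 x 13 x 6 mm fraction spans of the reference
#' six-series design. Voxel membership is decided by voxel-centre location.
#'
#' @param grid A `voxel_grid`; defaults to [default_grid()] at `voxel_size`.
#' @param voxel_size Used only when `grid` is `NULL`.
#' @param scale Scale factor on all ellipsoid centres and semi-axes.
#' @return A `brain_mask`.
#' @export
synthetic_brain_mask <- function(grid = NULL, voxel_size = 100, scale = 1) {
  if (is.null(grid)) grid <- default_grid(voxel_size, scale)
  comps <- .brain_components(scale)
  x <- axis_centers(grid, 1); y <- axis_centers(grid, 2); z <- axis_centers(grid, 3)
  inside <- array(FALSE, dim = grid$shape)
  for (cp in comps) {
    dx2 <- ((x - cp$center[1]) / cp$semi[1])^2
    dy2 <- ((y - cp$center[2]) / cp$semi[2])^2
    dz2 <- ((z - cp$center[3]) / cp$semi[3])^2
    inside <- inside | (outer(outer(dx2, dy2, "+"), dz2, "+") <= 1)
  }
  brain_mask(grid, inside)
}

# voxel-centre sphere membership as linear indices, restricted to the grid
sphere_voxels <- function(grid, center, diameter) {
  r <- diameter / 2
  x <- axis_centers(grid, 1); y <- axis_centers(grid, 2); z <- axis_centers(grid, 3)
  ix <- which(abs(x - center[1]) <= r)
  iy <- which(abs(y - center[2]) <= r)
  iz <- which(abs(z - center[3]) <= r)
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  g <- expand.grid(ix = ix, iy = iy, iz = iz)
  d2 <- (x[g$ix] - center[1])^2 + (y[g$iy] - center[2])^2 + (z[g$iz] - center[3])^2
  g <- g[d2 <= r^2, , drop = FALSE]
  as.integer(g$ix + (g$iy - 1L) * grid$shape[1] +
               (g$iz - 1L) * grid$shape[1] * grid$shape[2])
}

#' Deterministic planted expression patterns
#'
#' Spatial density fields emulating classes of real expression patterns:
#' `uniform` (housekeeping-like), `sphere` (a focal structure such as a
#' nucleus), `gradient` (a smooth axis-wise trend) and `region_marker`
#' (an ellipsoidal sub-region expressing above background, the shape of an
#' area-marker gene).
#'
#' @param kind One of `"uniform"`, `"sphere"`, `"gradient"`,
#'   `"region_marker"`.
#' @param grid A `voxel_grid`.
#' @param params Named list of parameters. `uniform`: `value`. `sphere`:
#'   `center` (um), `diameter` (um), `inside`, `outside`. `gradient`: `axis`
#'   (1, 2 or 3), `low`, `high` (linear ramp across the grid extent).
#'   `region_marker`: `center`, `semi` (ellipsoid semi-axes, um), `inside`,
#'   `outside`.
#' @return A `density_field`.
#' @export
planted_pattern <- function(kind = c("uniform", "sphere", "gradient", "region_marker"),
                            grid, params = list()) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "voxel_grid"))
  p <- params
  value <- switch(kind,
    uniform = array(p$value %||% 1, dim = grid$shape),
    sphere = {
      stopifnot(!is.null(p$center), !is.null(p$diameter))
      v <- array(p$outside %||% 0, dim = grid$shape)
      v[sphere_voxels(grid, p$center, p$diameter)] <- p$inside %||% 1
      v
    },
    gradient = {
      ax <- as.integer(p$axis %||% 2L)
      ctr <- axis_centers(grid, ax)
      ramp <- (ctr - min(ctr)) / (max(ctr) - min(ctr))
      vals <- (p$low %||% 0) + ramp * ((p$high %||% 1) - (p$low %||% 0))
      n <- grid$shape
      if (ax == 1L) {
        array(rep(vals, times = n[2] * n[3]), n)
      } else if (ax == 2L) {
        array(rep(rep(vals, each = n[1]), times = n[3]), n)
      } else {
        array(rep(vals, each = n[1] * n[2]), n)
      }
    },
    region_marker = {
      stopifnot(!is.null(p$center), !is.null(p$semi))
      x <- axis_centers(grid, 1); y <- axis_centers(grid, 2); z <- axis_centers(grid, 3)
      dx2 <- ((x - p$center[1]) / p$semi[1])^2
      dy2 <- ((y - p$center[2]) / p$semi[2])^2
      dz2 <- ((z - p$center[3]) / p$semi[3])^2
      inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
      v <- array(p$outside %||% 0, dim = grid$shape)
      v[inside] <- p$inside %||% 1
      v
    }
  )
  density_field(grid, value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent substream seeds derived from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a full synthetic sectioning study
#'
#' Emulates the reference experiment end to end: a brain-shaped mask, the
#' six-series/61-fraction design, `n_probes` probes of which a stated
#' fraction carry planted spatial patterns (the rest are spatially uniform),
#' per-probe baseline intensities drawn log-normally across probes, virtual
#' sectioning through the forward model, and multiplicative log-normal
#' measurement noise. Ground-truth pattern descriptors are retained so
#' recovery can be scored.
#'
#' Planted patterns cycle through broad structures a non-uniformly expressed
#' gene might mark: an ellipsoidal sub-region, a focal 3.5-mm structure and a
#' smooth axis gradient. The pattern fixes the spatial shape of a probe's
#' profile; `effect_size` sets its measured amplitude — the standard
#' deviation of the noiseless log signal across fractions — so it is
#' directly comparable with the measurement-noise log-sd `sdlog`
#' (`effect_size = 4 * sdlog` plants signal four times the noise).
#'
#' @param n_probes Number of probes (default 2000).
#' @param fraction_nonuniform Fraction of probes with planted non-uniform
#'   patterns, in `[0, 1]` (default 0.1).
#' @param effect_size Natural-log contrast of planted patterns (default 0.4,
#'   i.e. 4x the default noise log-sd).
#' @param sdlog Measurement-noise log-sd (default 0.1).
#' @param seed Master seed; all randomness is derived from it via named
#'   substreams.
#' @param voxel_size Voxel size of the synthetic volume in micrometres
#'   (default 200: pattern scales here are millimetric, so fraction-level
#'   measurements are insensitive to refinement below this).
#' @param oblique_angle_deg Tilt of the oblique series (default 10).
#' @return An object of class `synthetic_study`: list with `mask`, `design`,
#'   `truth` (tibble: `probe_id`, `kind`, `baseline`, `params`), `data`
#'   (a [fraction_data()] object with 61 columns) and `seed`.
#' @export
synthetic_study <- function(n_probes = 2000, fraction_nonuniform = 0.1,
                            effect_size = 0.4, sdlog = 0.1, seed = 1,
                            voxel_size = 200, oblique_angle_deg = 10) {
  if (!is.numeric(fraction_nonuniform) || fraction_nonuniform < 0 || fraction_nonuniform > 1) {
    stop("`fraction_nonuniform` must be in [0, 1]", call. = FALSE)
  }
  stopifnot(n_probes >= 1)
  seeds <- derive_seeds(seed, 3L)  # 1: patterns, 2: baselines, 3: noise
  mask <- synthetic_brain_mask(voxel_size = voxel_size)
  grid <- mask$grid
  design <- default_design(grid, mask, oblique_angle_deg)
  templates <- build_templates(grid, mask, design)

  n_nonuni <- round(n_probes * fraction_nonuniform)
  probe_ids <- sprintf("probe_%05d", seq_len(n_probes))
  kinds <- rep("uniform", n_probes)
  bb <- mask_bbox(mask)

  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seeds[1])
  params <- vector("list", n_probes)
  if (n_nonuni > 0) {
    pick <- sort(sample.int(n_probes, n_nonuni))
    cycle <- c("region_marker", "sphere", "gradient")
    in_idx <- which(mask$inside)
    for (j in seq_along(pick)) {
      i <- pick[j]
      kinds[i] <- cycle[(j - 1L) %% 3L + 1L]
      params[[i]] <- switch(kinds[i],
        region_marker = {
          ctr <- voxel_centers(grid, sample(in_idx, 1L))[1, ]
          list(center = as.numeric(ctr),
               semi = runif(3, 1800, 3500))
        },
        sphere = {
          ctr <- voxel_centers(grid, sample(in_idx, 1L))[1, ]
          list(center = as.numeric(ctr), diameter = 3500)
        },
        gradient = list(axis = sample(1:3, 1L))
      )
    }
  }

  set.seed(seeds[2])
  baseline <- rlnorm(n_probes, meanlog = log(500), sdlog = 1)

  # Noiseless per-fraction profile of each pattern kind. The pattern fixes
  # the spatial shape; its amplitude is then set at the measurement level:
  # the log profile across (non-empty) fractions is standardised to
  # sd = effect_size, so effect_size is the per-fraction log-signal sd and
  # is directly comparable with the noise log-sd `sdlog`. Uniform probes
  # measure exactly 1 in every fraction.
  labels <- unlist(lapply(design, fraction_labels), use.names = FALSE)
  # fractions with no tissue measure 0 for every probe
  empty <- unlist(lapply(templates, function(tp) tp$fraction_volumes == 0L),
                  use.names = FALSE)
  profile_for <- function(kind, p) {
    if (kind == "uniform") return(ifelse(empty, 0, 1))
    fld <- switch(kind,
      sphere = planted_pattern("sphere", grid,
        c(p, list(inside = exp(1), outside = 1))),
      region_marker = planted_pattern("region_marker", grid,
        c(p, list(inside = exp(1), outside = 1))),
      gradient = planted_pattern("gradient", grid,
        c(p, list(low = 1, high = exp(1))))
    )
    prof <- section_design(fld, templates, mask)$value
    nz <- prof > 0   # empty fractions hold no tissue and stay at 0
    lp <- log(prof[nz])
    s <- sd(lp)
    if (s > 0) {
      prof[nz] <- exp((lp - mean(lp)) / s * effect_size)
    }
    prof
  }
  intensity <- matrix(0, nrow = n_probes, ncol = length(labels),
                      dimnames = list(probe_ids, labels))
  for (i in seq_len(n_probes)) {
    intensity[i, ] <- baseline[i] * profile_for(kinds[i], params[[i]])
  }

  set.seed(seeds[3])
  if (sdlog > 0) {
    intensity <- intensity * matrix(
      rlnorm(length(intensity), 0, sdlog), nrow = n_probes)
  }

  truth <- tibble::tibble(
    probe_id = probe_ids, kind = kinds, baseline = baseline,
    params = params
  )
  structure(
    list(mask = mask, design = design, truth = truth,
         data = fraction_data(intensity), seed = as.integer(seed)),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d probes x %d fractions (%d non-uniform), seed %d\n",
    nrow(x$truth), length(x$data$fractions),
    sum(x$truth$kind != "uniform"), x$seed))
  invisible(x)
}
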