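# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive per-voxel loops, written without reusing any package
# internals, so they can adjudicate the vectorised implementations.

tiny_grid <- function(n = 16, vs = 100) {
  voxel_grid(rep(n, 3), vs)
}

full_mask <- function(grid) {
  brain_mask(grid, array(TRUE, dim = grid$shape))
}

ball_mask <- function(grid, radius_frac = 0.45) {
  ext <- grid$shape * grid$voxel_size
  ctr <- grid$origin + ext / 2
  r <- min(ext) * radius_frac
  x <- axis_centers(grid, 1); y <- axis_centers(grid, 2); z <- axis_centers(grid, 3)
  inside <- array(FALSE, grid$shape)
  for (k in seq_len(grid$shape[3]))
    inside[, , k] <- outer((x - ctr[1])^2, (y - ctr[2])^2, "+") + (z - ctr[3])^2 <= r^2
  brain_mask(grid, inside)
}

# slab index of a single point: direct transcription of the interval rule
oracle_slab_index <- function(point, series) {
  proj <- sum(point * series$normal)
  k <- floor((proj - series$offset) / series$width) + 1
  if (k >= 1 && k <= series$n_fractions) as.integer(k) else NA_integer_
}

# per-voxel loop over a template's grid: fraction label of every voxel
oracle_template_labels <- function(grid, mask, series) {
  out <- array(NA_integer_, grid$shape)
  for (i in seq_len(grid$shape[1]))
    for (j in seq_len(grid$shape[2]))
      for (k in seq_len(grid$shape[3])) {
        if (!mask$inside[i, j, k]) next
        p <- grid$origin + (c(i, j, k) - 0.5) * grid$voxel_size
        out[i, j, k] <- oracle_slab_index(p, series)
      }
  out
}

# naive sectioning: accumulate field values per fraction with a loop
oracle_section <- function(field, labels, n_fractions) {
  sums <- numeric(n_fractions); cnt <- integer(n_fractions)
  for (v in seq_along(labels)) {
    f <- labels[v]
    if (!is.na(f)) {
      sums[f] <- sums[f] + field[v]
      cnt[f] <- cnt[f] + 1L
    }
  }
  ifelse(cnt > 0, sums / pmax(cnt, 1), 0)
}

# naive reconstruction: per voxel, average each series' fraction value
oracle_reconstruct <- function(values_by_series, labels_by_series) {
  n <- length(labels_by_series[[1]])
  out <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    acc <- 0; ok <- TRUE
    for (s in seq_along(labels_by_series)) {
      f <- labels_by_series[[s]][v]
      if (is.na(f)) { ok <- FALSE; break }
      acc <- acc + values_by_series[[s]][f]
    }
    if (ok) out[v] <- acc / length(labels_by_series)
  }
  out
}

# a small three-orthogonal-series design for oracle comparisons
toy_design <- function(grid, n_fractions = c(4, 4, 4)) {
  ext <- grid$shape * grid$voxel_size
  list(
    S = sectioning_series("S", c(1, 0, 0), ext[1] / n_fractions[1], grid$origin[1], n_fractions[1]),
    C = sectioning_series("C", c(0, 1, 0), ext[2] / n_fractions[2], grid$origin[2], n_fractions[2]),
    H = sectioning_series("H", c(0, 0, 1), ext[3] / n_fractions[3], grid$origin[3], n_fractions[3])
  )
}

# cached small synthetic study shared across statistics tests
local({
  cache <- new.env(parent = emptyenv())
  study_fixture <<- function(...) {
    key <- paste(deparse(list(...)), collapse = "")
    if (is.null(cache[[key]])) cache[[key]] <- synthetic_study(...)
    cache[[key]]
  }
})
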