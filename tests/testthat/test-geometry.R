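test_that("slab_index implements half-open slab intervals", {
  s <- sectioning_series("C", c(0, 1, 0), width = 1000, offset = -2000, n_fractions = 13)
  # boundary of the first slab belongs to it
  expect_identical(slab_index(c(0, -2000, 0), s), 1L)
  # interior of the second slab
  expect_identical(slab_index(c(5, -2000 + 1500, -3), s), 2L)
  # right edge of the last slab is exclusive
  expect_identical(slab_index(c(0, -2000 + 13 * 1000, 0), s), NA_integer_)
  expect_identical(slab_index(c(0, -2001, 0), s), NA_integer_)
  # vectorised over a matrix of points, matching the scalar oracle
  pts <- cbind(runif(50, -5, 5), runif(50, -4000, 13000), runif(50, -5, 5))
  expect_identical(
    slab_index(pts, s),
    vapply(seq_len(nrow(pts)), function(i) oracle_slab_index(pts[i, ], s), integer(1))
  )
})

test_that("slab_index rejects a corrupted non-unit normal", {
  s <- sectioning_series("S", c(1, 0, 0), 1000, 0, 5)
  s$normal <- c(2, 0, 0)
  expect_error(slab_index(c(0, 0, 0), s), "unit")
})

test_that("sectioning_series validates and normalises its inputs", {
  s <- sectioning_series("S", c(2, 0, 0), 1000, 0, 5)
  expect_equal(sqrt(sum(s$normal^2)), 1, tolerance = 1e-12)
  expect_error(sectioning_series("S", c(0, 0, 0), 1000, 0, 5), "non-zero")
  expect_error(sectioning_series("S", c(1, 0, 0), -1, 0, 5), "positive")
  expect_error(sectioning_series("S", c(1, 0, 0), 1000, 0, 0), ">= 1")
})

test_that("axis-aligned templates partition the mask uniformly", {
  g <- tiny_grid(20, 100)  # 2 mm extent
  m <- full_mask(g)
  s <- sectioning_series("H", c(0, 0, 1), width = 1000, offset = g$origin[3],
                         n_fractions = 2)
  tpl <- build_fraction_template(g, m, s)
  # each 1000-um slab holds exactly nx*ny*10 voxels
  expect_equal(tpl$fraction_volumes, rep(20 * 20 * 10, 2))
  # single full-extent fraction captures everything
  s1 <- sectioning_series("H", c(0, 0, 1), width = 2000, offset = g$origin[3],
                          n_fractions = 1)
  expect_equal(build_fraction_template(g, m, s1)$fraction_volumes, 20^3)
})

test_that("oblique template construction matches the per-voxel oracle", {
  g <- tiny_grid(12, 150)
  m <- ball_mask(g)
  tilted <- sectioning_series("So", c(cos(10 * pi / 180), sin(10 * pi / 180), 0),
                              width = 450, offset = g$origin[1] - 100, n_fractions = 5)
  tpl <- build_fraction_template(g, m, tilted)
  ref <- oracle_template_labels(g, m, tilted)
  expect_identical(tpl$fraction, ref)
  expect_equal(tpl$fraction_volumes, tabulate(ref, 5))
  # fraction indices are monotone non-decreasing along the normal
  proj_order <- order(grid_projection(g, tilted$normal))
  f <- tpl$fraction[proj_order]
  expect_true(all(diff(f[!is.na(f)]) >= 0))
})

test_that("a series missing the mask entirely is an empty-template error", {
  g <- tiny_grid(8, 100)
  m <- full_mask(g)
  far <- sectioning_series("S", c(1, 0, 0), 100, g$origin[1] + 5e5, 3)
  expect_error(build_fraction_template(g, m, far), "empty template")
})

test_that("shifting the offset by one width shifts fraction indices by one", {
  g <- tiny_grid(16, 100)
  m <- ball_mask(g)
  n <- c(0.3, 0.9, 0.3); n <- n / sqrt(sum(n^2))
  s0 <- sectioning_series("X", n, 400, -900, 8)
  s1 <- sectioning_series("X", n, 400, -900 + 400, 8)
  f0 <- build_fraction_template(g, m, s0)$fraction
  f1 <- build_fraction_template(g, m, s1)$fraction
  both <- !is.na(f0) & !is.na(f1)
  expect_true(any(both))
  expect_true(all(f0[both] - f1[both] == 1L))
})

test_that("coverage is the intersection of per-series coverage", {
  g <- tiny_grid(16, 100)
  m <- ball_mask(g)
  design <- toy_design(g)
  tpls <- build_templates(g, m, design)
  cov <- coverage(tpls)
  # brute-force set intersection oracle
  ref <- array(TRUE, g$shape)
  for (tp in tpls) ref <- ref & !is.na(oracle_template_labels(g, m, tp$series))
  expect_identical(cov$covered, ref)
  # one all-covering template reproduces the mask
  one <- build_fraction_template(g, m, sectioning_series(
    "S", c(1, 0, 0), g$shape[1] * g$voxel_size, g$origin[1], 1))
  expect_identical(coverage(list(one))$covered, m$inside)
  expect_error(coverage(list()), "non-empty")
})

test_that("templates with disjoint coverage give empty joint coverage", {
  g <- tiny_grid(10, 100)
  m <- full_mask(g)
  left <- sectioning_series("L", c(1, 0, 0), 500, g$origin[1], 1)
  right <- sectioning_series("R", c(1, 0, 0), 500, g$origin[1] + 500, 1)
  cov <- coverage(build_templates(g, m, list(left, right)))
  expect_false(any(cov$covered))
  expect_error(
    reconstruct(list(rep(1, 1), rep(1, 1)),
                build_templates(g, m, list(left, right))),
    "no common volume")
})

test_that("the reference design has six series and 61 fractions", {
  mask <- synthetic_brain_mask(voxel_size = 300)
  design <- default_design(mask$grid, mask, oblique_angle_deg = 10)
  expect_named(design, c("S", "C", "H", "So", "Co", "Ho"))
  expect_equal(vapply(design, `[[`, integer(1), "n_fractions"),
               c(S = 9L, C = 13L, H = 6L, So = 10L, Co = 16L, Ho = 7L))
  expect_equal(sum(vapply(design, `[[`, integer(1), "n_fractions")), 61L)
  expect_true(all(vapply(design, `[[`, numeric(1), "width") == 1000))
  # zero tilt collapses the oblique normals onto the orthogonal ones
  d0 <- default_design(mask$grid, mask, oblique_angle_deg = 0)
  expect_equal(d0$So$normal, d0$S$normal, tolerance = 1e-12)
  expect_equal(d0$Co$normal, d0$C$normal, tolerance = 1e-12)
  expect_equal(d0$Ho$normal, d0$H$normal, tolerance = 1e-12)
})

test_that("design slabs tile each series' span without gaps", {
  mask <- synthetic_brain_mask(voxel_size = 300)
  design <- default_design(mask$grid, mask)
  for (s in design) {
    # walking along the normal in half-width steps hits consecutive slabs
    t <- seq(s$offset + 1e-6, s$offset + s$n_fractions * s$width - 1e-6,
             by = s$width / 2)
    idx <- slab_index(outer(t, s$normal), s)
    expect_false(anyNA(idx))
    expect_true(all(diff(idx) %in% c(0L, 1L)))
    expect_identical(range(idx), c(1L, s$n_fractions))
  }
})

test_that("a mask too large for the fraction span is rejected", {
  g <- voxel_grid(c(100, 10, 10), 100)  # 10 mm along x > 9 mm span
  m <- full_mask(g)
  expect_error(default_design(g, m), "exceeds")
})
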