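# one-fraction-per-axis map whose values we can state exactly
flat_map <- function(g, m, values_by_slab = NULL) {
  tpl <- build_fraction_template(g, m, sectioning_series(
    "H", c(0, 0, 1), g$voxel_size, g$origin[3], g$shape[3]))
  vals <- values_by_slab %||% rep(1, g$shape[3])
  reconstruct(list(vals), list(tpl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sphere areas voxelize by centre inclusion and mirror bilaterally", {
  g <- tiny_grid(12, 100)
  # a one-voxel-diameter sphere captures exactly its centre voxel
  one <- sphere_area(g, g$origin + c(3.5, 3.5, 3.5) * 100, diameter = 100)
  expect_length(one$voxels, 1L)
  # a 500-um sphere at 100-um voxels: count equals brute-force enumeration
  ctr <- g$origin + c(6, 6, 6) * 100
  a <- sphere_area(g, ctr, diameter = 500)
  cnt <- 0L
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    p <- g$origin + (c(i, j, k) - 0.5) * 100
    if (sum((p - ctr)^2) <= 250^2) cnt <- cnt + 1L
  }
  expect_length(a$voxels, cnt)
  expect_true(abs(cnt - 4 / 3 * pi * 2.5^3) < 20)
  # mirrored twins have equal volume on a symmetric grid
  ctr2 <- c(g$origin[1] + 3.5 * 100, ctr[2], ctr[3])
  mirror_plane <- g$origin[1] + 6 * 100
  b <- sphere_area(g, ctr2, diameter = 500, mirror = TRUE, mirror_x = mirror_plane)
  expect_length(b$voxels_mirror, length(b$voxels))
  expect_false(setequal(b$voxels_mirror, b$voxels))
  # centroid outside the coverage volume is rejected
  m <- ball_mask(g, 0.2)
  expect_error(sphere_area(g, g$origin + 50, coverage = m), "outside")
})

test_that("area density follows the suprathreshold quantification rule", {
  g <- tiny_grid(6, 100)
  m <- full_mask(g)
  # slab values 10, 12, 14, 0, 0, 0; threshold will be 0.8 * 14 = 11.2
  map <- apply_cutoff(flat_map(g, m, c(10, 12, 14, 0, 0, 0)))
  expect_equal(map$cutoff$threshold, 0.8 * 14)
  # an 8-voxel area picking voxels from slabs with known values
  lin <- function(i, j, k) i + (j - 1) * 6 + (k - 1) * 36
  area <- mask_area(g, c(lin(1, 1, 2), lin(2, 1, 3), lin(3, 1, 3), lin(4, 1, 1),
                         lin(1, 2, 1), lin(2, 2, 4), lin(3, 2, 5), lin(4, 2, 6)),
                    area_id = "toy")
  # suprathreshold members: slab2 (12), two slab3 voxels (14, 14); slab1 (10)
  # is below 11.2; slabs 4-6 are zero
  expect_equal(area_density(map, area)$density, (12 + 14 + 14) / 8)
  expect_equal(area_density(map, area, mode = "raw")$density,
               (12 + 14 + 14 + 10 + 10) / 8)
  # an area entirely below threshold scores zero
  low <- mask_area(g, c(lin(1, 3, 1), lin(2, 3, 1)), area_id = "low")
  expect_equal(area_density(map, low)$density, 0)
  # uniform map, raw mode: the constant
  uni <- flat_map(g, m, rep(3, 6))
  expect_equal(area_density(uni, area, mode = "raw")$density, 3)
  # suprathreshold mode without a recorded cutoff is an error
  expect_error(area_density(uni, area), "apply_cutoff")
})

test_that("marker areas equal the cutoff region, keeping all components", {
  g <- tiny_grid(10, 100)
  m <- full_mask(g)
  # two disjoint hot slabs: both survive (no connectivity pruning)
  map <- flat_map(g, m, c(0, 9, 0, 0, 10, 0, 0, 0, 0, 0))
  mk <- marker_area(map, area_id = "marker")
  region <- cutoff_filter(map, 0.8)
  expect_setequal(mk$voxels, which(region$member))
  ks <- unique(ceiling(mk$voxels / (10 * 10)))
  expect_setequal(ks, c(2L, 5L))
  # a marker with one hot fraction triple selects that slab intersection
  design <- toy_design(g, c(2, 2, 2))
  tpls <- build_templates(g, m, design)
  hot <- reconstruct(list(c(1, 0), c(1, 0), c(1, 0)), tpls)
  mh <- marker_area(hot)
  expect_setequal(mh$voxels, which(!is.na(hot$value) & hot$value == 1))
})

test_that("mask combination is exact set algebra", {
  g <- tiny_grid(8, 100)
  set.seed(5)
  A <- mask_area(g, sort(sample(512, 120)), "A")
  B <- mask_area(g, sort(sample(512, 150)), "B")
  C <- mask_area(g, sort(sample(512, 90)), "C")
  expect_setequal(combine_masks(list(A))$voxels, A$voxels)
  comb <- combine_masks(list(A, B), list(C))
  expect_setequal(comb$voxels, setdiff(intersect(A$voxels, B$voxels), C$voxels))
  expect_error(combine_masks(list(A), list(A)), "empty")
})

test_that("region overlap percentages match a counting oracle", {
  g <- tiny_grid(9, 100)
  n <- prod(g$shape)
  atlas <- array(0L, g$shape)
  atlas[1:200] <- 1L; atlas[201:500] <- 2L; atlas[501:650] <- 3L
  set.seed(9)
  vox <- sort(sample(n, 300))
  ov <- region_overlap(mask_area(g, vox, "m"), atlas)
  for (k in 1:3) {
    expect_equal(ov$percent_of_region[k],
                 100 * sum(atlas[vox] == k) / sum(atlas == k))
  }
  expect_equal(attr(ov, "percent_of_whole"),
               100 * sum(atlas[vox] > 0) / sum(atlas > 0))
  # a mask equal to one region scores 100% there and 0 elsewhere
  ov2 <- region_overlap(mask_area(g, which(atlas == 2L), "r2"), atlas)
  expect_equal(ov2$percent_of_region[1:3], c(0, 100, 0))
  # the whole labelled volume scores 100% everywhere
  ov3 <- region_overlap(mask_area(g, which(atlas > 0L), "all"), atlas)
  expect_equal(ov3$percent_of_region, rep(100, 4))
  # volume-weighted region percentages recompose the whole-mask percentage
  w <- ov$region_voxels[1:3]
  expect_equal(sum(ov$percent_of_region[1:3] * w) / sum(w),
               attr(ov, "percent_of_whole"))
})

test_that("dataset comparison recovers a planted log-linear correlation", {
  set.seed(13)
  n <- 10000
  genes <- sprintf("g%05d", seq_len(n))
  lref <- rnorm(n, 6, 2)
  ltest <- 0.9 * lref + rnorm(n, 0, 1.1)
  planted_r <- cor(ltest, lref)
  cmp <- compare_datasets(
    tibble::tibble(gene = genes, area_id = "a", value = 2^ltest),
    tibble::tibble(gene = genes, area_id = "a", value = 2^lref)
  )
  expect_equal(cmp$r, planted_r, tolerance = 0.02)
  expect_equal(cmp$n_pairs, n)
  expect_equal(nrow(cmp$cv), 50L)
  # identical datasets correlate exactly 1; constant windows have CV 0
  same <- compare_datasets(
    tibble::tibble(gene = genes[1:100], area_id = "a", value = 2^lref[1:100]),
    tibble::tibble(gene = genes[1:100], area_id = "a", value = 2^lref[1:100])
  )
  expect_equal(same$r, 1)
  const <- compare_datasets(
    tibble::tibble(gene = genes[1:200], area_id = "a", value = 5),
    tibble::tibble(gene = genes[1:200], area_id = "a", value = 2^lref[1:200])
  )
  expect_true(all(const$cv$cv[!is.na(const$cv$cv)] == 0))
  expect_error(compare_datasets(
    tibble::tibble(gene = "g1", area_id = "a", value = 1),
    tibble::tibble(gene = "g2", area_id = "a", value = 1)
  ), "fewer than 2")
})

test_that("per-gene probe selection keeps the highest-mean probe", {
  test <- tibble::tibble(
    gene = c("g1", "g1", "g1", "g2", "g2"),
    probe_id = c("p1a", "p1a", "p1b", "p2a", "p2b"),
    area_id = c("a", "b", "a", "a", "a"),
    value = c(10, 20, 100, 3, 4)
  )
  ref <- tibble::tibble(gene = c("g1", "g1", "g2"), area_id = c("a", "b", "a"),
                        value = c(8, 16, 5))
  cmp <- compare_datasets(test, ref)
  # p1b has the higher mean for g1 but covers only area a; p2b wins for g2
  expect_setequal(cmp$matched$test, c(100, 4))
})

test_that("area-density comparison scales to the reference and tests shifts", {
  g <- tiny_grid(10, 100)
  m <- full_mask(g)
  map <- apply_cutoff(flat_map(g, m, c(4, 8, 2, 0, 0, 10, 10, 10, 10, 10)),
                      keep_fraction = 0.1)
  lin <- function(k) which(rep(seq_len(10), each = 100) == k)
  ref <- mask_area(g, lin(1), "ref")          # density 4
  dbl <- mask_area(g, lin(2), "double")       # density 8
  out <- compare_area_densities(map, list(ref, dbl), ref)
  expect_equal(out$percent_of_reference, c(100, 200))
  expect_equal(out$p_value[1], 1)
  # a planted shifted-mean area is significant at alpha 0.01
  set.seed(3)
  noisy_vals <- c(rnorm(500, 5, 0.3), rnorm(500, 6, 0.3))
  nm <- flat_map(g, m, rep(1, 10))
  nm$value[] <- NA_real_
  nm$value[1:1000] <- pmax(noisy_vals, 0)
  nm$coverage$covered[] <- FALSE
  nm$coverage$covered[1:1000] <- TRUE
  nm <- apply_cutoff(nm, 0.5)
  a1 <- mask_area(g, 1:500, "base")
  a2 <- mask_area(g, 501:1000, "shifted")
  res <- compare_area_densities(nm, list(a2), a1)
  expect_lt(res$p_value, 0.01)
  expect_true(res$significant)
})

test_that("raw area density is linear and order-preserving under scaling", {
  g <- tiny_grid(8, 100)
  m <- full_mask(g)
  v1 <- runif(8); v2 <- runif(8)
  area <- mask_area(g, sample(prod(g$shape), 40), "a")
  m1 <- flat_map(g, m, v1); m2 <- flat_map(g, m, v2)
  m12 <- flat_map(g, m, 2 * v1 + 3 * v2)
  expect_equal(area_density(m12, area, mode = "raw")$density,
               2 * area_density(m1, area, mode = "raw")$density +
                 3 * area_density(m2, area, mode = "raw")$density,
               tolerance = 1e-12)
})
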