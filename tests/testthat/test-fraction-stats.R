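make_fd <- function(m, present = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  fraction_data(m, present)
}

test_that("per-chip normalisation scales every fraction to a unit target", {
  set.seed(1)
  m <- matrix(rlnorm(200 * 6, log(100), 1), 200, 6,
              dimnames = list(sprintf("p%03d", 1:200),
                              c("S1", "S2", "C1", "C2", "H1", "H2")))
  norm <- normalize_per_chip(make_fd(m))
  expect_equal(unname(apply(norm$intensity, 2, quantile, 0.75)), rep(1, 6))
  # a column already at target is unchanged
  m2 <- m
  m2[, 1] <- m[, 1] / quantile(m[, 1], 0.75)
  norm2 <- normalize_per_chip(make_fd(m2))
  expect_equal(norm2$intensity[, 1], m2[, 1])
  # scale invariance: multiplying a chip by 10 changes nothing afterwards
  m3 <- m
  m3[, 4] <- 10 * m[, 4]
  expect_equal(normalize_per_chip(make_fd(m3))$intensity,
               norm$intensity)
  # median target variant
  normed <- normalize_per_chip(make_fd(m), target = "median")
  expect_equal(unname(apply(normed$intensity, 2, median)), rep(1, 6))
  # zero column is an error naming the fraction
  m4 <- m; m4[, 2] <- 0
  expect_error(normalize_per_chip(make_fd(m4)), "S2")
})

test_that("total-probe filtering keeps probes with any present flag", {
  m <- matrix(1, 4, 3, dimnames = list(paste0("p", 1:4), c("S1", "S2", "S3")))
  pres <- rbind(c(TRUE, FALSE, FALSE),   # present once: kept
                c(FALSE, FALSE, FALSE),  # never present: dropped
                c(TRUE, TRUE, TRUE),
                c(FALSE, TRUE, FALSE))
  out <- filter_total_probes(make_fd(m, pres))
  expect_identical(out$probes, c("p1", "p3", "p4"))
  # an empty result is allowed
  empty <- filter_total_probes(make_fd(m[1:2, ], pres[c(2, 2), ]))
  expect_length(empty$probes, 0L)
})

test_that("fraction correlations match hand-computed Pearson values", {
  # 5 probes x 4 fractions toy matrix
  m <- matrix(c(1, 2, 3, 4, 5,
                2, 4, 6, 8, 10,
                5, 4, 3, 2, 1,
                1, 3, 2, 5, 4), 5, 4,
              dimnames = list(paste0("p", 1:5), c("S1", "S2", "C1", "C2")))
  fc <- fraction_correlations(make_fd(m))
  lx <- log2(m + 1)
  ref <- cor(lx)
  expect_equal(fc$r, ref)
  up <- ref[upper.tri(ref)]
  expect_equal(fc$summary$mean_r, mean(up))
  expect_equal(fc$summary$sem_r, sd(up) / sqrt(6))
  expect_equal(fc$summary$min_r, min(up))
  expect_equal(fc$summary$n_pairs, 6L)
  # duplicate columns correlate exactly 1; anti-proportional log profiles -1
  dup <- cbind(S1 = m[, 1], S2 = m[, 1])
  expect_equal(fraction_correlations(make_fd(dup))$r["S1", "S2"], 1)
  anti <- cbind(S1 = 2^(1:5), S2 = 2^(5:1)) - 1
  expect_equal(fraction_correlations(make_fd(anti))$r["S1", "S2"], -1)
  # constant fraction is an error naming it
  const <- cbind(S1 = rep(2, 5), S2 = 1:5)
  expect_error(fraction_correlations(make_fd(const)), "S1")
  # affine transforms of a profile leave r unchanged (on the log scale the
  # transform must be applied to the log values)
  expect_s3_class(tidy(fc), "tbl_df")
  expect_equal(nrow(tidy(fc)), 6L)
})

test_that("replicate pairing follows descending r with anatomical tie-breaks", {
  # block structure: each Sx strongly matches Sox
  set.seed(8)
  base <- matrix(rlnorm(400 * 3, log(50), 1), 400, 3)
  noise <- function() matrix(rlnorm(400 * 3, 0, 0.05), 400, 3)
  m <- cbind(base * noise(), base * noise())
  colnames(m) <- c("S1", "S2", "S3", "So1", "So2", "So3")
  rownames(m) <- sprintf("p%03d", 1:400)
  pr <- pair_replicates(make_fd(m))
  expect_equal(nrow(pr$pairs), 3L)
  expect_identical(pr$pairs$fraction_b[match(c("S1", "S2", "S3"), pr$pairs$fraction_a)],
                   c("So1", "So2", "So3"))
  expect_length(pr$unpaired, 0L)
  # all-equal correlations: anatomical order decides (S1-So1, S2-So2, ...)
  eq <- cbind(S1 = 1:6, S2 = 1:6, So1 = 1:6, So2 = 1:6) + 0
  rownames(eq) <- paste0("p", 1:6)
  pre <- pair_replicates(make_fd(eq))
  expect_identical(pre$pairs$fraction_a, c("S1", "S2"))
  expect_identical(pre$pairs$fraction_b, c("So1", "So2"))
  # overlapping groups are rejected
  expect_error(pair_replicates(make_fd(eq), group_a = c("S1", "S2"),
                               group_b = c("S2", "So1")), "overlap")
})

test_that("planted cross-group correspondence is recovered under noise", {
  st <- study_fixture(n_probes = 400, fraction_nonuniform = 0.25,
                      effect_size = 0.5, sdlog = 0.05, seed = 21,
                      voxel_size = 300)
  fd <- normalize_per_chip(drop_empty_fractions(st$data))
  pr <- pair_replicates(fd)
  # anatomically matching fractions measure overlapping slabs: the S series
  # must pair with So in order (the oblique series has one extra fraction)
  sa <- pr$pairs[grepl("^S[0-9]", pr$pairs$fraction_a), ]
  ia <- as.integer(sub("^S", "", sa$fraction_a))
  ib <- as.integer(sub("^So", "", sa$fraction_b))
  expect_true(mean(abs(ia - ib) <= 1) >= 0.8)
})

test_that("compute_iv classifies probes and halves them on the I split", {
  st <- study_fixture(n_probes = 400, fraction_nonuniform = 0.25,
                      effect_size = 0.5, sdlog = 0.05, seed = 21,
                      voxel_size = 300)
  fd <- normalize_per_chip(drop_empty_fractions(st$data))
  iv <- compute_iv(fd)
  gc <- attr(iv, "group_counts")
  # the median split halves the probe set
  expect_equal(gc[["IV"]] + gc[["Iv"]], gc[["iV"]] + gc[["iv"]])
  expect_equal(sum(gc), 400L)
  # groups are consistent with the stated letter rules
  expect_identical(iv$group,
                   paste0(ifelse(iv$I > median(iv$I), "I", "i"),
                          ifelse(iv$V < 0.05, "V", "v")))
  # BH adjustment is monotone in p
  ord <- order(iv$p)
  expect_true(all(diff(iv$V[ord]) >= -1e-15))
  expect_true(all(iv$V >= iv$p - 1e-15))
})

test_that("a constant probe is V-negative with p = 1", {
  m <- matrix(rlnorm(50 * 8, log(10), 0.3), 50, 8,
              dimnames = list(sprintf("p%02d", 1:50),
                              c("S1", "S2", "C1", "C2", "So1", "So2", "Co1", "Co2")))
  m[7, ] <- 4   # exactly constant everywhere
  iv <- compute_iv(make_fd(m))
  expect_equal(iv$p[7], 1)
  expect_match(iv$group[7], "v$")
})

test_that("planted non-uniform probes are the significant ones, matching aov", {
  # 50 probes, 10 planted at large effect: exactly those reach FDR < 0.05
  st <- study_fixture(n_probes = 50, fraction_nonuniform = 0.2,
                      effect_size = 0.8, sdlog = 0.1, seed = 31,
                      voxel_size = 300)
  fd <- normalize_per_chip(drop_empty_fractions(st$data))
  pr <- pair_replicates(fd)
  iv <- compute_iv(fd, pr)
  planted <- st$truth$probe_id[st$truth$kind != "uniform"]
  expect_length(planted, 10L)
  expect_setequal(iv$probe_id[iv$V < 0.05], planted)

  # cross-check the vectorised F-test against stats::aov per probe
  lx <- log2(fd$intensity + 1)
  for (p in c(planted[1:3], setdiff(iv$probe_id, planted)[1:3])) {
    y <- c(lx[p, pr$pairs$fraction_a], lx[p, pr$pairs$fraction_b])
    lvl <- factor(rep(seq_len(nrow(pr$pairs)), times = 2))
    ref <- summary(stats::aov(y ~ lvl))[[1]][["Pr(>F)"]][1]
    expect_equal(iv$p[iv$probe_id == p], ref, tolerance = 1e-10)
  }
})

test_that("empty fractions can be dropped before correlation analyses", {
  st <- study_fixture(n_probes = 50, fraction_nonuniform = 0.2,
                      effect_size = 0.8, sdlog = 0.1, seed = 31,
                      voxel_size = 300)
  expect_error(fraction_correlations(st$data), "Co1")
  fd <- drop_empty_fractions(st$data)
  expect_lt(length(fd$fractions), length(st$data$fractions))
  expect_s3_class(fraction_correlations(fd)$summary, "tbl_df")
})
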