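test_that("parenchyma floor is the 99th percentile, linear interpolation", {
  expect_equal(suppressWarnings(parenchyma_min_threshold(rep(50, 200))), 50)

  # sort-based oracle for the declared convention: rank 1 + p(n-1)
  expect_equal(parenchyma_min_threshold(1:100), 99.01)
  expect_warning(parenchyma_min_threshold(1:99), "fewer than 100")

  set.seed(7)
  s <- rnorm(10000, 55, 10)
  srt <- sort(s)
  h <- 1 + 0.99 * (length(s) - 1)
  oracle <- srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] - srt[floor(h)])
  expect_equal(parenchyma_min_threshold(s), oracle, tolerance = 1e-12)
  expect_lt(abs(parenchyma_min_threshold(s) - oracle), 0.5)

  expect_error(parenchyma_min_threshold(numeric(0)), "empty")
})

test_that("bilevel operators match an independent exhaustive oracle", {
  for (seed in 1:25) {
    v <- random_histogram(seed)
    expect_equal(bilevel_threshold_variance(v), oracle_variance(v),
                 info = paste("variance, seed", seed))
    expect_equal(bilevel_threshold_cross_entropy(v), oracle_cross_entropy(v),
                 info = paste("cross-entropy, seed", seed))
  }
})

test_that("bilevel operators: two-level histograms and tie-breaking", {
  v <- c(rep(100, 50), rep(200, 50))
  # every cut in [100, 200) separates the two levels equally well; the
  # smallest optimal candidate is returned
  expect_equal(bilevel_threshold_variance(v), 100)
  expect_equal(bilevel_threshold_cross_entropy(c(100, 200)), 100)

  # bimodal mixture: both criteria land between the modes and agree with the
  # exhaustive oracle; they sit within 15 HU of each other
  set.seed(1)
  v2 <- c(rnorm(500, 120, 10), rnorm(500, 260, 10))
  tv <- bilevel_threshold_variance(v2)
  tc <- bilevel_threshold_cross_entropy(v2)
  expect_equal(tv, oracle_variance(v2))
  expect_equal(tc, oracle_cross_entropy(v2))
  expect_gt(tv, 120); expect_lt(tv, 260)
  expect_lt(abs(tv - tc), 15)

  expect_error(bilevel_threshold_variance(c(5, 5, 5)), "degenerate")
  expect_error(bilevel_threshold_cross_entropy(rep(7, 10)), "degenerate")
})

test_that("per-tumor thresholding runs on Lipiodol-positive voxels", {
  d <- c(20, 20, 20)
  set.seed(3)
  hu <- array(55, d)
  tumor <- array(FALSE, d); tumor[5:16, 5:16, 5:16] <- TRUE
  dep <- which(tumor)[1:800]
  hu[dep[1:400]] <- rnorm(400, 120, 5)
  hu[dep[401:800]] <- rnorm(400, 260, 5)
  ct <- image_volume(hu)
  r <- per_tumor_threshold(ct, binary_mask(tumor), t_min = 87)
  expect_false(r$skipped)
  expect_gt(r$t_mean, 120); expect_lt(r$t_mean, 260)
  expect_equal(r$t_mean, (r$t_ce + r$t_var) / 2)

  # tumor entirely below the floor: flagged skip, not an exception
  ct_cold <- image_volume(array(50, d))
  r2 <- per_tumor_threshold(ct_cold, binary_mask(tumor), t_min = 87)
  expect_true(r2$skipped)
  expect_true(is.na(r2$t_mean))
})

test_that("cohort thresholds: modes, permutation invariance, monotonicity", {
  # per-technique percentiles 159/239 (cross-entropy) and 151/243 (variance)
  # average to the published 155 / 241 HU
  pt <- data.frame(t_ce = c(159, 159, 239, 239), t_var = c(151, 151, 243, 243))
  ct <- cohort_thresholds(pt, "percentile_then_average")
  expect_identical(ct$t_low_mid, 155)
  expect_identical(ct$t_mid_high, 241)

  # when t_ce == t_var per tumor the two modes coincide
  pt2 <- data.frame(t_ce = c(120, 160, 200, 280), t_var = c(120, 160, 200, 280))
  a <- cohort_thresholds(pt2, "percentile_then_average")
  b <- cohort_thresholds(pt2, "average_then_percentile")
  expect_equal(a$t_low_mid, b$t_low_mid)
  expect_equal(a$t_mid_high, b$t_mid_high)

  # permutation invariance
  set.seed(9)
  pt3 <- data.frame(t_ce = runif(12, 120, 280), t_var = runif(12, 120, 280))
  perm <- sample(12)
  expect_equal(cohort_thresholds(pt3), cohort_thresholds(pt3[perm, ]))

  # monotonicity: adding a tumor above the current 67th percentile never
  # decreases t_mid_high
  for (extra in c(300, 350, 500)) {
    pt4 <- rbind(pt3, data.frame(t_ce = extra, t_var = extra))
    expect_gte(cohort_thresholds(pt4)$t_mid_high,
               cohort_thresholds(pt3)$t_mid_high)
  }

  expect_error(cohort_thresholds(pt3[1:2, ]), "at least 3")
})

test_that("density classification boundaries and partition", {
  thr <- default_thresholds()
  d <- c(4, 1, 1)
  ct <- image_volume(array(c(87, 88, 155, 241), d))
  tumor <- binary_mask(array(TRUE, d))
  map <- classify_density(ct, tumor, thr)
  # 87 HU is not Lipiodol (strict-above floor); 88 is low; 155 still low;
  # 241 still mid
  expect_identical(as.integer(map$labels), c(0L, 1L, 1L, 2L))

  ct2 <- image_volume(array(c(86, 150, 200, 300), d))
  expect_identical(as.integer(classify_density(ct2, tumor, thr)$labels),
                   c(0L, 1L, 2L, 3L))

  # shift invariance: +10 HU on voxels and thresholds leaves labels unchanged
  thr10 <- threshold_set(97, 165, 251)
  ct3 <- image_volume(ct2$voxels + 10)
  expect_identical(classify_density(ct3, tumor, thr10)$labels,
                   classify_density(ct2, tumor, thr)$labels)

  # partition: every tumor voxel gets exactly one label, none outside
  set.seed(5)
  hu <- array(runif(1000, 0, 400), c(10, 10, 10))
  tm <- sphere_mask(c(10, 10, 10), c(5, 5, 5), 4)
  m2 <- classify_density(image_volume(hu), tm, thr)
  expect_true(all(m2$labels[!tm$voxels] == 0))
  counts <- tabulate(m2$labels[tm$voxels] + 1L, 4L)
  expect_equal(sum(counts), sum(tm$voxels))
  # label monotone in HU within the map
  labs <- m2$labels[tm$voxels]
  vals <- hu[tm$voxels]
  ord <- order(vals)
  expect_true(all(diff(labs[ord]) >= 0 | diff(vals[ord]) == 0))
})

test_that("coverage counts fractions and enforces the 50-voxel rule", {
  map <- label_map_with_counts(100, n_low = 40, n_mid = 0, n_high = 10)
  cov <- coverage(map, binary_mask(array(TRUE, c(100, 1, 1))), "r")
  expect_equal(cov$frac_any, 0.5)
  expect_equal(cov$frac_low, 0.4)
  expect_equal(cov$frac_high, 0.1)
  expect_equal(cov$frac_low + cov$frac_mid + cov$frac_high, cov$frac_any,
               tolerance = 1e-9)

  # all-none region
  map0 <- label_map_with_counts(80, 0, 0, 0)
  expect_equal(coverage(map0, binary_mask(array(TRUE, c(80, 1, 1))))$frac_any, 0)

  # sub-50-voxel region: flagged skip
  reg49 <- array(FALSE, c(100, 1, 1)); reg49[1:49] <- TRUE
  expect_true(coverage(map, binary_mask(reg49))$skipped)

  # region outside the tumor is an error
  mapS <- classify_density(image_volume(array(100, c(6, 6, 6))),
                           sphere_mask(c(6, 6, 6), c(3, 3, 3), 2),
                           default_thresholds())
  expect_error(coverage(mapS, binary_mask(array(TRUE, c(6, 6, 6)))),
               "outside the tumor")
})

test_that("coverage is additive over a disjoint partition", {
  map <- label_map_with_counts(300, n_low = 60, n_mid = 90, n_high = 30)
  all_reg <- array(FALSE, c(300, 1, 1))
  a <- all_reg; a[1:120] <- TRUE
  b <- all_reg; b[121:300] <- TRUE
  whole <- array(TRUE, c(300, 1, 1))
  ca <- coverage(map, binary_mask(a))
  cb <- coverage(map, binary_mask(b))
  cw <- coverage(map, binary_mask(whole))
  expect_equal((ca$frac_any * ca$n_voxels + cb$frac_any * cb$n_voxels) /
                 (ca$n_voxels + cb$n_voxels), cw$frac_any, tolerance = 1e-12)
})
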