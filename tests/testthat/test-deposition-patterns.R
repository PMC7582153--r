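test_that("homogeneity and sparsity use inclusive boundaries", {
  # all high
  m <- label_map_with_counts(200, 0, 0, 200)
  h <- is_homogeneous(m)
  expect_true(h$homogeneous); expect_equal(h$frac_mid_or_high, 1)

  # exactly 85.0% mid is homogeneous; 84.9%-ish is not
  expect_true(is_homogeneous(label_map_with_counts(1000, 0, 850, 0))$homogeneous)
  expect_false(is_homogeneous(label_map_with_counts(1000, 151, 849, 0))$homogeneous)

  # sparse: no Lipiodol at all
  expect_true(is_sparse(label_map_with_counts(100, 0, 0, 0))$sparse)
  # exactly (20%, 10%) is sparse
  expect_true(is_sparse(label_map_with_counts(1000, 0, 200, 100))$sparse)
  # one bound violated fails the AND
  expect_false(is_sparse(label_map_with_counts(1000, 0, 50, 110))$sparse)
  expect_false(is_sparse(label_map_with_counts(1000, 0, 201, 0))$sparse)
})

test_that("rim analysis on an analytic shell phantom", {
  d <- c(56, 56, 56)
  ctr <- c(28, 28, 28)
  tumor <- sphere_mask(d, ctr, 20)
  co <- coord_arrays(d)
  rho <- sqrt((co$X - ctr[1])^2 + (co$Y - ctr[2])^2 + (co$Z - ctr[3])^2)
  hu <- array(40, d)
  hu[tumor$voxels] <- 100
  shell <- tumor$voxels & rho > 17          # outer 3 mm at 180 HU
  hu[shell] <- 180
  ra <- rim_analysis(image_volume(hu), tumor, t_min = 87)
  expect_true(ra$defined)
  # core is eroded by 0.15 * r_eq (= ~3 mm), so the core is the 100 HU bulk
  expect_equal(ra$base_intensity, 100, tolerance = 1)
  # voxel-sum oracle over the rim mask
  oracle <- mean(pmax(0, hu[ra$rim_mask$voxels] - ra$base_intensity))
  expect_equal(ra$rim_score, oracle, tolerance = 1e-9)
  expect_gte(ra$rim_score, 17)
  expect_true(ra$rim)
  # core/rim partition the tumor
  expect_identical(ra$core_mask$voxels | ra$rim_mask$voxels, tumor$voxels)
  expect_false(any(ra$core_mask$voxels & ra$rim_mask$voxels))
})

test_that("uniform tumors have zero rim score; tiny tumors are flagged", {
  d <- c(32, 32, 32)
  tumor <- sphere_mask(d, c(16, 16, 16), 8)
  hu <- array(40, d); hu[tumor$voxels] <- 100
  ra <- rim_analysis(image_volume(hu), tumor, t_min = 87)
  expect_equal(ra$base_intensity, 100)
  expect_equal(ra$rim_score, 0)
  expect_false(ra$rim)

  # r = 2 mm sphere: erosion by 0.3 mm (sub-voxel) keeps the core non-empty
  small <- sphere_mask(d, c(16, 16, 16), 2)
  ra2 <- rim_analysis(image_volume(hu), small, t_min = 87)
  expect_false(is.null(ra2$core_mask))
  expect_equal(sum(ra2$core_mask$voxels), sum(small$voxels))
  expect_false(ra2$rim)

  # single-voxel tumor: rim undefined, rim FALSE
  one <- array(FALSE, d); one[16, 16, 16] <- TRUE
  ra3 <- rim_analysis(image_volume(hu), binary_mask(one), t_min = 87)
  expect_false(ra3$defined)
  expect_false(ra3$rim)
})

test_that("rim analysis is invariant to a joint global HU shift", {
  case <- generate_phantom(phantom_config(seed = 21, pattern = "rim_sparse"))
  a <- rim_analysis(case$ct, case$tumor_mask, t_min = 87)
  shifted <- image_volume(case$ct$voxels + 50, spacing = case$ct$spacing)
  b <- rim_analysis(shifted, case$tumor_mask, t_min = 137)
  expect_equal(b$rim_score, a$rim_score, tolerance = 1e-9)
  expect_equal(b$base_intensity, a$base_intensity + 50, tolerance = 1e-9)
  expect_identical(b$rim, a$rim)
})

test_that("peripheral coverage over the 3.5 mm band", {
  d <- c(40, 40, 40)
  tumor <- sphere_mask(d, c(20, 20, 20), 8)
  hu_cold <- array(40, d)
  pc <- peripheral_coverage(image_volume(hu_cold), tumor, t_min = 87)
  expect_equal(pc$peripheral_pct, 0)
  expect_false(pc$clipped)
  # band thickness: all periphery voxels within 3.5 mm of the surface
  dist <- lipioquant:::dist_to_mask(tumor)
  expect_true(all(dist[pc$periphery_mask$voxels] <= 3.5))
  expect_false(any(pc$periphery_mask$voxels & tumor$voxels))

  hu_hot <- array(200, d)
  expect_equal(peripheral_coverage(image_volume(hu_hot), tumor, 87)$peripheral_pct,
               100)

  # half the shell above the floor by construction (hemisphere)
  co <- coord_arrays(d)
  hu_half <- array(40, d)
  hu_half[co$X > 20] <- 200
  ph <- peripheral_coverage(image_volume(hu_half), tumor, 87)
  expect_equal(ph$peripheral_pct, 50, tolerance = 2)

  # clipped flag when the band hits the volume border
  edge_tumor <- sphere_mask(d, c(3, 20, 20), 3)
  pe <- peripheral_coverage(image_volume(hu_cold), edge_tumor, 87)
  expect_true(pe$clipped)
})

test_that("pattern taxonomy composes the features", {
  thr <- default_thresholds()
  mk_lesion <- function(growth) lesion_record("L", "HCC", growth, "selective", 3)

  case <- generate_phantom(phantom_config(seed = 31, pattern = "homogeneous"))
  map <- classify_density(case$ct, case$tumor_mask, thr)
  pat <- classify_pattern(map, case$ct, case$tumor_mask, thr$t_min,
                          mk_lesion("well_delineated"))
  expect_identical(pat$category, "homogeneous")
  expect_gte(pat$frac_mid_or_high, 0.85)

  # infiltrative lesions report no rim and use the two-way taxonomy
  case2 <- generate_phantom(phantom_config(seed = 32, pattern = "sparse",
                                           shape = "infiltrative"))
  map2 <- classify_density(case2$ct, case2$tumor_mask, thr)
  pat2 <- classify_pattern(map2, case2$ct, case2$tumor_mask, thr$t_min,
                           mk_lesion("infiltrative"))
  expect_identical(pat2$category, "infiltrative sparse")
  expect_true(is.na(pat2$rim))

  # engineered rim-sparse archetype
  case3 <- generate_phantom(phantom_config(seed = 33, pattern = "rim_sparse"))
  map3 <- classify_density(case3$ct, case3$tumor_mask, thr)
  pat3 <- classify_pattern(map3, case3$ct, case3$tumor_mask, thr$t_min,
                           mk_lesion("well_delineated"))
  expect_identical(pat3$category, "rim sparse")
  expect_gte(pat3$rim_score, 17)
  expect_identical(pattern_archetype(pat3), "rim_sparse")
})
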