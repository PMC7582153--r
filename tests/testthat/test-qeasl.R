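test_that("VOI statistics use the population SD and flag odd volumes", {
  d <- c(20, 20, 20)
  voi <- array(FALSE, d); voi[1:10, 1:10, 1:10] <- TRUE
  mri <- image_volume(array(100, d), modality = "MRI")
  vs <- voi_stats(mri, binary_mask(voi))
  expect_equal(vs$mean, 100); expect_equal(vs$sd, 0)
  expect_false(vs$volume_warning)

  # two-point population SD: {90, 110} -> mean 100, sd 10
  d2 <- c(2, 1, 1)
  vs2 <- suppressWarnings(
    voi_stats(image_volume(array(c(90, 110), d2), modality = "MRI"),
              binary_mask(array(TRUE, d2))))
  expect_equal(vs2$mean, 100); expect_equal(vs2$sd, 10)

  # 1331-voxel cube at 0.9 mm isotropic: 970.3 mm^3, inside the +/-20% band
  d3 <- c(11, 11, 11)
  vs3 <- voi_stats(image_volume(array(50, d3), spacing = rep(0.9, 3),
                                modality = "MRI"),
                   binary_mask(array(TRUE, d3), spacing = rep(0.9, 3)))
  expect_equal(vs3$physical_volume_mm3, 1331 * 0.9^3, tolerance = 1e-9)
  expect_false(vs3$volume_warning)

  # VOI overlapping the tumor is rejected
  tumor <- binary_mask(voi)
  expect_error(voi_stats(mri, binary_mask(voi), tumor), "overlaps")
})

test_that("viability threshold is mean + 2 SD, inclusive", {
  d <- c(3, 1, 1)
  mri <- image_volume(array(c(120, 119.9, 80), d), modality = "MRI")
  tumor <- binary_mask(array(TRUE, d))
  voi <- structure(list(mean = 100, sd = 10, n_voxels = 1000,
                        physical_volume_mm3 = 1000, volume_warning = FALSE),
                   class = "voi_stats")
  vm <- viable_mask(mri, tumor, voi)
  expect_identical(as.vector(vm$viable$voxels), c(TRUE, FALSE, FALSE))
  # partition invariant
  expect_identical(vm$viable$voxels | vm$necrotic$voxels, tumor$voxels)
  expect_false(any(vm$viable$voxels & vm$necrotic$voxels))

  # degenerate VOI (sd = 0): everything at or above the mean is viable
  voi0 <- voi; voi0$sd <- 0
  vm0 <- viable_mask(mri, tumor, voi0)
  expect_identical(as.vector(vm0$viable$voxels), c(TRUE, TRUE, FALSE))
})

test_that("viable fraction recovers the construction and is threshold-monotone", {
  case <- generate_phantom(phantom_config(seed = 41, baseline_viable_frac = 0.3))
  vs <- voi_stats(case$mri_baseline, case$voi_mask)
  vm <- viable_mask(case$mri_baseline, case$tumor_mask, vs)
  frac <- sum(vm$viable$voxels) / sum(case$tumor_mask$voxels)
  expect_equal(frac, 0.3, tolerance = 0.01)

  # raising the VOI mean never adds viable voxels
  vs_hi <- vs; vs_hi$mean <- vs$mean + 30
  vm_hi <- viable_mask(case$mri_baseline, case$tumor_mask, vs_hi)
  expect_true(all(vm$viable$voxels | !vm_hi$viable$voxels))
  expect_lte(sum(vm_hi$viable$voxels), sum(vm$viable$voxels))
})

test_that("ETV change arithmetic and the 65% response boundary", {
  expect_equal(percent_change_etv(10, 3.5), -65)
  expect_equal(percent_change_etv(10, 10), 0)
  expect_equal(percent_change_etv(2, 3), 50)
  expect_warning(na <- percent_change_etv(0, 1), "excluded")
  expect_true(is.na(na))

  expect_identical(classify_response(-65), "responder")
  expect_identical(classify_response(-64.9), "non_responder")
  expect_identical(classify_response(10.5), "non_responder")
  expect_true(is.na(classify_response(NA_real_)))
})

test_that("regional reduction counts conversions and respects flags", {
  d <- c(200, 1, 1)
  tumor <- binary_mask(array(TRUE, d))
  mk_viab <- function(viable_idx) {
    v <- array(FALSE, d); v[viable_idx] <- TRUE
    structure(list(viable = binary_mask(v),
                   necrotic = binary_mask(array(!v, d)),
                   threshold_used = 0, tumor_mask = tumor),
              class = "viability_mask")
  }
  base <- mk_viab(1:100)
  foll <- mk_viab(41:100)  # first 40 converted
  region <- binary_mask(array(TRUE, d))
  ro <- regional_reduction(base, foll, region)
  expect_equal(ro$n_baseline_viable, 100)
  expect_equal(ro$n_converted, 40)
  expect_equal(ro$pct_reduction, 40)

  # no conversion
  expect_equal(regional_reduction(base, base, region)$pct_reduction, 0)

  # sub-50-voxel region is a flagged skip
  small <- array(FALSE, d); small[1:30] <- TRUE
  expect_true(regional_reduction(base, foll, binary_mask(small))$skipped)

  # region without baseline-viable voxels: undefined percentage, flagged
  dead <- array(FALSE, d); dead[101:200] <- TRUE
  ro2 <- regional_reduction(base, foll, binary_mask(dead))
  expect_true(ro2$skipped)
  expect_true(is.na(ro2$pct_reduction))
})

test_that("regional reductions aggregate exactly over a disjoint partition", {
  d <- c(300, 1, 1)
  tumor <- binary_mask(array(TRUE, d))
  set.seed(8)
  v0 <- array(runif(300) < 0.7, d)
  conv <- v0 & array(runif(300) < 0.4, d)
  mk <- function(v) structure(list(viable = binary_mask(array(v, d)),
                                   necrotic = binary_mask(array(!v, d)),
                                   threshold_used = 0, tumor_mask = tumor),
                              class = "viability_mask")
  base <- mk(v0); foll <- mk(v0 & !conv)
  parts <- list(1:100, 101:200, 201:300)
  tot <- 0
  for (p in parts) {
    r <- array(FALSE, d); r[p] <- TRUE
    o <- regional_reduction(base, foll, binary_mask(r))
    tot <- tot + o$n_converted
  }
  whole <- regional_reduction(base, foll, binary_mask(array(TRUE, d)))
  expect_equal(tot, whole$n_converted)
})
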