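test_that("generation is deterministic given the seed", {
  a <- generate_phantom(phantom_config(seed = 99, pattern = "rim_nonsparse"))
  b <- generate_phantom(phantom_config(seed = 99, pattern = "rim_nonsparse"))
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$mri_followup$voxels, b$mri_followup$voxels)
  expect_identical(a$truth$density, b$truth$density)

  c <- generate_phantom(phantom_config(seed = 100, pattern = "rim_nonsparse"))
  expect_false(identical(a$ct$voxels, c$ct$voxels))
})

test_that("noise-free homogeneous phantom closes the generator/classifier loop", {
  case <- generate_phantom(phantom_config(seed = 1, pattern = "homogeneous",
                                          noise_scale = 0))
  map <- classify_density(case$ct, case$tumor_mask, default_thresholds())
  # classified labels equal the generating truth exactly at zero noise
  expect_identical(map$labels[case$tumor_mask$voxels],
                   case$truth$density[case$tumor_mask$voxels])
  h <- is_homogeneous(map)
  expect_true(h$homogeneous)
  expect_gte(h$frac_mid_or_high, 0.85)
})

test_that("config validation rejects contradictions", {
  expect_error(phantom_config(seed = 1, pattern = "homogeneous",
                              density_weights = c(0.5, 0.3, 0.2),
                              fill_frac = 0.5),
               "contradiction")
  expect_error(phantom_config(seed = 1, density_weights = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(phantom_config(seed = 1, diameter_mm = 8), "10 mm")
  expect_silent(phantom_config(seed = 1, diameter_mm = 8, allow_small = TRUE))
  expect_error(phantom_config(seed = 1,
                              conversion_probs = c(none = 0, low = 0.5,
                                                   mid = 1, high = 1.2)),
               "probabilities")
})

test_that("cohort generation is reproducible and mixes archetypes", {
  expect_error(generate_cohort(0), "at least 1")
  coh <- generate_cohort(7, master_seed = 5)
  expect_length(coh$cases, 7)
  expect_identical(sort(unique(coh$truth$pattern)),
                   sort(c("homogeneous", "sparse", "rim_sparse",
                          "rim_nonsparse", "nonrim_sparse",
                          "nonrim_nonsparse", "peripheral_halo")))
  coh2 <- generate_cohort(7, master_seed = 5)
  expect_identical(coh$cases[[3]]$ct$voxels, coh2$cases[[3]]$ct$voxels)
})

test_that("bimodal cohort thresholds land between the deposit modes", {
  # half the tumors deposit around 130 HU, half around 260 HU
  n <- 6
  cases <- lapply(seq_len(n), function(i) {
    hm <- c(background = 55, low = if (i <= n / 2) 130 else 260,
            mid = 195, high = 300)
    generate_phantom(phantom_config(seed = 200 + i, pattern = "custom",
                                    fill_frac = 0.5,
                                    density_weights = c(1, 0, 0),
                                    hu_means = hm))
  })
  pt <- do.call(rbind, lapply(cases, function(c) {
    r <- per_tumor_threshold(c$ct, c$tumor_mask, t_min = 87)
    data.frame(t_ce = r$t_ce, t_var = r$t_var)
  }))
  ct <- cohort_thresholds(pt)
  expect_gt(ct$t_low_mid, 87)
  expect_lt(ct$t_mid_high, 300)
})

test_that("phantom cases round-trip through the NIfTI case directory", {
  case <- generate_phantom(phantom_config(seed = 77, pattern = "sparse",
                                          shape = "infiltrative"))
  dir <- withr::local_tempdir()
  write_phantom_case(case, dir)
  back <- as_lesion_case(dir)
  expect_equal(back$ct$voxels, case$ct$voxels, tolerance = 1e-6)
  expect_identical(back$tumor_mask_ct$voxels, case$tumor_mask$voxels)
  expect_identical(back$lesion$growth_type, "infiltrative")
})
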