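#' Synthetic lesion phantom configuration
#'
#' Describes one generated case: an HU-calibrated liver-background CT with a
#' lesion whose Lipiodol deposits are arranged in one of the deposition-
#' pattern archetypes, plus baseline/follow-up arterial-phase MRI with an
#' enhancing (viable) compartment whose follow-up devascularization
#' probability increases with the local Lipiodol density class.
#'
#' Deposit placement per archetype (fractions are deterministic voxel counts,
#' carved out of a smoothed noise field so deposits are spatially coherent):
#' `homogeneous` fills ~95% of the tumor with mid/high density;
#' `sparse` (infiltrative growth) scatters low-density deposits over ~15%;
#' `rim_sparse` fills 40% of the outer 15%-of-equivalent-radius shell with
#' mid density over a nearly empty core; `rim_nonsparse` adds a 35% mid-fill
#' core under a dense mid/high rim; `nonrim_sparse` scatters low density
#' uniformly; `nonrim_nonsparse` fills the core (70%) more than the rim
#' (20%) with mid density, the configuration that keeps the rim score below
#' the cut-off; `peripheral_halo` pairs a sparse interior with mid-density
#' Lipiodol in ~70% of the 3.5 mm band outside the tumor surface;
#' `custom` fills `fill_frac` of the whole tumor with `density_weights`.
#'
#' @param seed integer RNG seed; every stochastic draw is governed by it.
#' @param dim grid shape (voxels).
#' @param spacing voxel size (mm).
#' @param shape lesion shape.
#' @param diameter_mm lesion diameter (>= 10 mm, the study's inclusion rule,
#'   unless `allow_small`).
#' @param pattern deposition archetype, see above.
#' @param density_weights length-3 (low, mid, high) mixture weights for
#'   deposit voxels; `NULL` uses the archetype default.
#' @param fill_frac,fill_core,fill_rim,halo_frac deposit fill fractions;
#'   `NULL` uses archetype defaults.
#' @param hu_means,hu_sds named (background, low, mid, high) HU means and
#'   spreads.
#' @param noise_scale multiplier on all sds; 0 gives noise-free volumes whose
#'   voxels sit exactly at the class means.
#' @param mri_background,mri_viable,mri_necrotic MRI signal model: background
#'   mean/sd and the viable/necrotic compartment signal levels.
#' @param baseline_viable_frac fraction of tumor voxels enhancing at
#'   baseline.
#' @param conversion_probs named (none, low, mid, high) probabilities that a
#'   baseline-viable voxel is non-enhancing at follow-up, conditional on its
#'   Lipiodol density class.
#' @param lesion_id identifier for the generated lesion record.
#' @param allow_small permit sub-centimeter lesions (for exclusion-rule
#'   tests).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(seed, dim = c(64, 64, 64), spacing = c(1, 1, 1),
                           shape = c("sphere", "ellipsoid", "lobulated",
                                     "infiltrative"),
                           diameter_mm = 30,
                           pattern = c("homogeneous", "sparse", "rim_sparse",
                                       "rim_nonsparse", "nonrim_sparse",
                                       "nonrim_nonsparse", "peripheral_halo",
                                       "custom"),
                           density_weights = NULL, fill_frac = NULL,
                           fill_core = NULL, fill_rim = NULL,
                           halo_frac = NULL,
                           hu_means = c(background = 55, low = 120,
                                        mid = 195, high = 300),
                           hu_sds = c(background = 8, low = 15,
                                      mid = 20, high = 30),
                           noise_scale = 1,
                           mri_background = c(mean = 100, sd = 10),
                           mri_viable = 200, mri_necrotic = 80,
                           baseline_viable_frac = 0.7,
                           conversion_probs = c(none = 0.2, low = 0.4,
                                                mid = 0.6, high = 0.8),
                           lesion_id = sprintf("phantom-%d", seed),
                           allow_small = FALSE) {
  pattern <- match.arg(pattern)
  shape <- match.arg(shape)
  if (pattern == "sparse" && missing(shape)) shape <- "infiltrative"

  defaults <- switch(pattern,
    homogeneous      = list(fill_frac = 0.95, w = c(0.02, 0.58, 0.40)),
    sparse           = list(fill_frac = 0.15, w = c(1, 0, 0)),
    rim_sparse       = list(fill_core = 0.05, fill_rim = 0.40, w = c(0, 1, 0)),
    rim_nonsparse    = list(fill_core = 0.35, fill_rim = 0.90, w = c(0, 0.7, 0.3)),
    nonrim_sparse    = list(fill_frac = 0.15, w = c(1, 0, 0)),
    nonrim_nonsparse = list(fill_core = 0.70, fill_rim = 0.20, w = c(0, 1, 0)),
    peripheral_halo  = list(fill_frac = 0.10, halo_frac = 0.70, w = c(1, 0, 0),
                            halo_w = c(0, 1, 0)),
    custom           = list(fill_frac = 0.5, w = c(1 / 3, 1 / 3, 1 / 3)))
  if (is.null(density_weights)) density_weights <- defaults$w
  if (is.null(fill_frac)) fill_frac <- defaults$fill_frac
  if (is.null(fill_core)) fill_core <- defaults$fill_core
  if (is.null(fill_rim)) fill_rim <- defaults$fill_rim
  if (is.null(halo_frac)) halo_frac <- defaults$halo_frac

  if (abs(sum(density_weights) - 1) > 1e-9)
    stop("density mixture weights must sum to 1")
  if (any(conversion_probs < 0 | conversion_probs > 1))
    stop("conversion probabilities must lie in [0, 1]")
  if (!allow_small && diameter_mm < 10)
    stop("lesion diameter below 10 mm (study inclusion rule); ",
         "set allow_small = TRUE to generate anyway")
  if (pattern == "homogeneous") {
    mh <- sum(density_weights[2:3]) * fill_frac
    if (mh < 0.85)
      stop(sprintf(paste0("pattern/mixture contradiction: homogeneous ",
                          "archetype needs mid+high fill >= 0.85, got %.2f"), mh))
  }
  if (baseline_viable_frac < 0 || baseline_viable_frac > 1)
    stop("baseline_viable_frac must lie in [0, 1]")

  structure(list(seed = as.integer(seed), dim = dim, spacing = spacing,
                 shape = shape, diameter_mm = diameter_mm, pattern = pattern,
                 density_weights = density_weights, fill_frac = fill_frac,
                 fill_core = fill_core, fill_rim = fill_rim,
                 halo_frac = halo_frac, hu_means = hu_means, hu_sds = hu_sds,
                 noise_scale = noise_scale, mri_background = mri_background,
                 mri_viable = mri_viable, mri_necrotic = mri_necrotic,
                 baseline_viable_frac = baseline_viable_frac,
                 conversion_probs = conversion_probs, lesion_id = lesion_id),
            class = "phantom_config")
}

# Smoothed uniform-noise field for spatially coherent random selections.
coherent_field <- function(d, sigma = 1.5) {
  array(gauss_smooth_cpp(runif(prod(d)), d, rep(sigma, 3)), d)
}

# Deterministically select round(frac * |region|) voxels from `region`
# (logical array), preferring the largest values of a coherent noise field.
select_frac <- function(region, frac, field) {
  sel <- array(FALSE, dim(region))
  n <- round(frac * sum(region))
  if (n <= 0) return(sel)
  vals <- field[region]
  ord <- order(vals, decreasing = TRUE)[seq_len(n)]
  idx <- which(region)[ord]
  sel[idx] <- TRUE
  sel
}

# Lesion mask construction in voxel coordinates (physical distances).
lesion_shape_mask <- function(config) {
  d <- config$dim; sp <- config$spacing
  ctr <- (d + 1) / 2 * sp
  r <- config$diameter_mm / 2
  gx <- (seq_len(d[1]) - 0.5) * sp[1]
  gy <- (seq_len(d[2]) - 0.5) * sp[2]
  gz <- (seq_len(d[3]) - 0.5) * sp[3]
  X <- array(rep(gx, times = d[2] * d[3]), d) - ctr[1]
  Y <- array(rep(rep(gy, each = d[1]), times = d[3]), d) - ctr[2]
  Z <- array(rep(gz, each = d[1] * d[2]), d) - ctr[3]
  rho <- sqrt(X^2 + Y^2 + Z^2)
  mask <- switch(config$shape,
    sphere = rho <= r,
    ellipsoid = {
      # axis ratio 1.3 with the sphere's volume preserved
      a <- r * 1.3^(2 / 3); b <- r / 1.3^(1 / 3)
      (X / a)^2 + (Y / b)^2 + (Z / b)^2 <= 1
    },
    lobulated = {
      theta <- acos(pmin(1, pmax(-1, Z / pmax(rho, 1e-9))))
      phi <- atan2(Y, X)
      rho <= r * (1 + 0.15 * sin(3 * theta) * cos(2 * phi))
    },
    infiltrative = {
      f <- coherent_field(d, sigma = 3)
      f <- (f - mean(f)) / max(stats::sd(f), 1e-9)
      rho <= r * (1 + 0.35 * f)
    })
  mask
}

draw_hu <- function(n, mean, sd, noise_scale) {
  if (n == 0) return(numeric(0))
  mean + rnorm(n, 0, sd * noise_scale)
}

#' Generate one synthetic lesion case
#'
#' Deterministic given the config seed: returns CT, baseline and follow-up
#' MRI, tumor / VOI / parenchyma-sample masks, and the generating ground
#' truth (per-voxel density class, per-voxel viability at both time points,
#' pattern label, conversion probabilities).
#'
#' @param config a [phantom_config()].
#' @return An object of class `phantom_case`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  d <- config$dim; sp <- config$spacing
  n <- prod(d)
  hm <- config$hu_means; hs <- config$hu_sds * config$noise_scale

  tumor <- lesion_shape_mask(config)
  tumor_mask <- binary_mask(tumor, spacing = sp, require_nonempty = TRUE)

  # core/rim split at 15% of the equivalent-sphere radius, same physical
  # definition the rim classifier uses
  V <- sum(tumor) * prod(sp)
  r_eq <- (3 * V / (4 * pi))^(1 / 3)
  dist_in <- array(edt_cpp(!tumor, d, sp), d)
  core <- tumor & (dist_in > 0.15 * r_eq)
  rim <- tumor & !core
  dist_out <- array(edt_cpp(tumor, d, sp), d)
  peri_band <- !tumor & (dist_out <= 3.5)

  # deposit placement
  field <- coherent_field(d)
  deposit <- array(FALSE, d)
  halo <- array(FALSE, d)
  p <- config$pattern
  if (p %in% c("homogeneous", "sparse", "nonrim_sparse", "custom")) {
    deposit <- select_frac(tumor, config$fill_frac, field)
  } else if (p %in% c("rim_sparse", "rim_nonsparse", "nonrim_nonsparse")) {
    deposit <- select_frac(core, config$fill_core, field) |
      select_frac(rim, config$fill_rim, field)
  } else if (p == "peripheral_halo") {
    deposit <- select_frac(tumor, config$fill_frac, field)
    halo <- select_frac(peri_band, config$halo_frac, coherent_field(d))
  }

  # density class truth: 0 none, 1 low, 2 mid, 3 high
  density <- array(0L, d)
  nd <- sum(deposit)
  if (nd > 0)
    density[deposit] <- sample.int(3L, nd, replace = TRUE,
                                   prob = config$density_weights)
  if (any(halo)) density[halo] <- 2L  # halo deposits are mid density

  # CT voxels
  ct_vox <- array(draw_hu(n, hm["background"], config$hu_sds["background"],
                          config$noise_scale), d)
  for (k in 1:3) {
    sel <- density == k
    ct_vox[sel] <- draw_hu(sum(sel), hm[k + 1], config$hu_sds[k + 1],
                           config$noise_scale)
  }
  ct <- image_volume(ct_vox, spacing = sp, modality = "CT")

  # auxiliary masks in clean background corners
  voi <- array(FALSE, d)
  voi[3:12, 3:12, 3:12] <- TRUE
  voi <- voi & !tumor & !peri_band
  par_samp <- array(FALSE, d)
  par_samp[(d[1] - 13):(d[1] - 2), (d[2] - 13):(d[2] - 2), 3:14] <- TRUE
  par_samp <- par_samp & !tumor & !peri_band & !halo

  # MRI baseline: enhancing compartment by construction
  mb <- config$mri_background
  viable0 <- select_frac(tumor, config$baseline_viable_frac, coherent_field(d))
  mri_b <- array(mb["mean"] + rnorm(n, 0, mb["sd"] * config$noise_scale), d)
  mri_b[tumor] <- config$mri_necrotic +
    rnorm(sum(tumor), 0, mb["sd"] * config$noise_scale)
  mri_b[viable0] <- config$mri_viable +
    rnorm(sum(viable0), 0, mb["sd"] * config$noise_scale)

  # follow-up: baseline-viable voxels devascularize with a probability that
  # increases with the local Lipiodol density class
  pr <- config$conversion_probs[density[viable0] + 1L]
  converted <- array(FALSE, d)
  converted[viable0] <- runif(sum(viable0)) < pr
  viable1 <- viable0 & !converted
  mri_f <- array(mb["mean"] + rnorm(n, 0, mb["sd"] * config$noise_scale), d)
  mri_f[tumor] <- config$mri_necrotic +
    rnorm(sum(tumor), 0, mb["sd"] * config$noise_scale)
  mri_f[viable1] <- config$mri_viable +
    rnorm(sum(viable1), 0, mb["sd"] * config$noise_scale)

  growth <- if (config$shape == "infiltrative") "infiltrative" else "well_delineated"
  lesion <- lesion_record(config$lesion_id, entity = "HCC",
                          growth_type = growth, tace_approach = "selective",
                          diameter_cm = config$diameter_mm / 10)

  structure(list(
    ct = ct,
    mri_baseline = image_volume(mri_b, spacing = sp, modality = "MRI"),
    mri_followup = image_volume(mri_f, spacing = sp, modality = "MRI"),
    tumor_mask = tumor_mask,
    voi_mask = binary_mask(voi, spacing = sp),
    parenchyma_mask = binary_mask(par_samp, spacing = sp),
    lesion = lesion,
    truth = list(pattern = config$pattern, density = density,
                 viable_baseline = viable0, viable_followup = viable1,
                 conversion_probs = config$conversion_probs,
                 mri_threshold = unname(mb["mean"] +
                                          2 * mb["sd"] * config$noise_scale)),
    config = config),
    class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s: %s %s, %d tumor voxels, pattern %s\n",
              x$lesion$lesion_id, x$config$shape,
              paste(x$config$dim, collapse = "x"),
              sum(x$tumor_mask$voxels), x$truth$pattern))
  invisible(x)
}

#' Generate a reproducible phantom cohort
#'
#' Streams one sub-seed per case from a single master seed and cycles through
#' the requested archetype mix. Infiltrative-growth shapes are used for the
#' `sparse` archetype, spheres elsewhere; diameters cycle over a small range
#' so the cohort spans lesion sizes.
#'
#' @param n number of cases (>= 1).
#' @param scenario_mix character vector of archetypes to cycle through.
#' @param master_seed integer master seed.
#' @param ... further arguments forwarded to [phantom_config()].
#' @return List with `cases` (list of `phantom_case`) and `truth`
#'   (data.frame: lesion_id, pattern, shape, diameter_mm, seed).
#' @export
generate_cohort <- function(n, scenario_mix = c("homogeneous", "sparse",
                                                "rim_sparse", "rim_nonsparse",
                                                "nonrim_sparse",
                                                "nonrim_nonsparse",
                                                "peripheral_halo"),
                            master_seed = 1, ...) {
  if (n < 1) stop("cohort size must be at least 1")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  diameters <- rep(c(26, 30, 34), length.out = n)
  patterns <- rep(scenario_mix, length.out = n)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    shape <- if (patterns[i] == "sparse") "infiltrative" else "sphere"
    cfg <- phantom_config(seed = seeds[i], pattern = patterns[i],
                          shape = shape, diameter_mm = diameters[i],
                          lesion_id = sprintf("case-%03d", i), ...)
    cases[[i]] <- generate_phantom(cfg)
  }
  truth <- data.frame(
    lesion_id = vapply(cases, function(c) c$lesion$lesion_id, ""),
    pattern = patterns, shape = vapply(cases, function(c) c$config$shape, ""),
    diameter_mm = diameters, seed = seeds, stringsAsFactors = FALSE)
  list(cases = cases, truth = truth)
}

#' Write a phantom case to a NIfTI directory
#'
#' Materializes the CT, both MRIs and all masks as NIfTI files plus a truth
#' CSV, so the case can be consumed through the file-based interface.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$ct, file.path(dir, "ct.nii.gz"))
  write_volume(case$mri_baseline, file.path(dir, "mri_baseline.nii.gz"))
  write_volume(case$mri_followup, file.path(dir, "mri_followup.nii.gz"))
  write_volume(case$tumor_mask, file.path(dir, "tumor_mask.nii.gz"))
  write_volume(case$voi_mask, file.path(dir, "voi_mask.nii.gz"))
  write_volume(case$parenchyma_mask, file.path(dir, "parenchyma_mask.nii.gz"))
  truth <- data.frame(lesion_id = case$lesion$lesion_id,
                      pattern = case$truth$pattern,
                      growth_type = case$lesion$growth_type,
                      diameter_cm = case$lesion$diameter_cm)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
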