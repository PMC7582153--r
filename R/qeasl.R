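#' Background-parenchyma VOI statistics
#'
#' The qEASL enhancement threshold derives from a roughly 1 cm^3 volume of
#' interest placed in untreated background liver parenchyma on the arterial
#' phase: its mean signal plus two standard deviations defines "enhancing".
#' The standard deviation is the population SD (divisor n), pinned for
#' determinism. A VOI whose physical volume is outside 1000 mm^3 +/- 20%
#' gets a warning flag.
#'
#' @param mri an [image_volume] (arterial-phase MRI).
#' @param voi_mask a [binary_mask] on the MRI grid.
#' @param tumor_mask optional [binary_mask]; the VOI must not overlap it.
#' @return List of class `voi_stats`: `mean`, `sd`, `n_voxels`,
#'   `physical_volume_mm3`, `volume_warning`.
#' @export
voi_stats <- function(mri, voi_mask, tumor_mask = NULL) {
  check_geometry(voi_mask, mri, "VOI mask")
  if (!any(voi_mask$voxels)) stop("empty VOI mask")
  if (!is.null(tumor_mask) && any(voi_mask$voxels & tumor_mask$voxels))
    stop("VOI overlaps the tumor mask")
  v <- mri$voxels[voi_mask$voxels]
  n <- length(v)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))  # population SD
  vol <- n * prod(mri$spacing)
  warn <- abs(vol - 1000) > 200
  if (warn)
    warning(sprintf("VOI volume %.1f mm^3 deviates > 20%% from 1 cm^3", vol))
  structure(list(mean = m, sd = s, n_voxels = n, physical_volume_mm3 = vol,
                 volume_warning = warn),
            class = "voi_stats")
}

#' qEASL viable/necrotic partition of a tumor
#'
#' A tumor voxel is viable (enhancing) iff its signal is at least two
#' standard deviations above the VOI mean (inclusive boundary); the rest of
#' the tumor is necrotic. Viable and necrotic partition the tumor exactly.
#'
#' Enhancement is taken as the raw arterial-phase signal by default (the
#' parenchymal VOI mean is thresholded directly); passing a `precontrast`
#' volume switches to subtraction mode, in which the pre-contrast signal is
#' subtracted voxelwise before thresholding (the VOI statistics must then be
#' computed on the same subtracted image).
#'
#' @param mri an [image_volume] (arterial-phase MRI).
#' @param tumor_mask a [binary_mask] on the MRI grid.
#' @param voi a [voi_stats] result.
#' @param precontrast optional pre-contrast [image_volume] for subtraction
#'   mode.
#' @return List of class `viability_mask`: `viable`, `necrotic`
#'   ([binary_mask]s), `threshold_used`, `tumor_mask`.
#' @export
viable_mask <- function(mri, tumor_mask, voi, precontrast = NULL) {
  stopifnot(inherits(voi, "voi_stats"))
  check_geometry(tumor_mask, mri, "tumor mask")
  signal <- mri$voxels
  if (!is.null(precontrast)) {
    check_geometry(precontrast, mri, "pre-contrast volume")
    signal <- signal - precontrast$voxels
  }
  thr <- voi$mean + 2 * voi$sd
  viable <- tumor_mask$voxels & (signal >= thr)
  structure(list(
    viable = binary_mask(viable, spacing = mri$spacing, origin = mri$origin),
    necrotic = binary_mask(tumor_mask$voxels & !viable,
                           spacing = mri$spacing, origin = mri$origin),
    threshold_used = thr, tumor_mask = tumor_mask),
    class = "viability_mask")
}

#' @export
print.viability_mask <- function(x, ...) {
  cat(sprintf("<viability_mask> threshold %.2f: %d viable / %d necrotic voxels\n",
              x$threshold_used, sum(x$viable$voxels), sum(x$necrotic$voxels)))
  invisible(x)
}

#' Enhancing tumor volume (ETV)
#'
#' Physical volume of the viable compartment, in cm^3.
#'
#' @param viability a [viable_mask()] result.
#' @return ETV in cm^3.
#' @export
etv <- function(viability) {
  stopifnot(inherits(viability, "viability_mask"))
  if (sum(viability$viable$voxels) == 0) return(0)
  physical_volume(viability$viable) / 1000
}

#' Signed percent change in enhancing tumor volume
#'
#' `100 * (followup - baseline) / baseline`. Lesions without enhancing tissue
#' at baseline cannot be assessed and are excluded (returns `NA` with a
#' warning rather than an error, so cohort runs continue).
#'
#' @param baseline_etv,followup_etv ETV in cm^3.
#' @return Signed percentage, or `NA` if `baseline_etv` is 0.
#' @export
percent_change_etv <- function(baseline_etv, followup_etv) {
  stopifnot(baseline_etv >= 0, followup_etv >= 0)
  if (baseline_etv == 0) {
    warning("excluded: no enhancing tumor tissue on baseline MRI")
    return(NA_real_)
  }
  100 * (followup_etv - baseline_etv) / baseline_etv
}

#' qEASL response classification
#'
#' Responder iff enhancing tumor volume fell by at least 65%
#' (`pct_change <= -65`, inclusive).
#'
#' @param pct_change signed percent change from [percent_change_etv()].
#' @return `"responder"` or `"non_responder"` (`NA` in, `NA` out).
#' @export
classify_response <- function(pct_change) {
  if (is.na(pct_change)) return(NA_character_)
  if (pct_change <= -65) "responder" else "non_responder"
}

#' Region-wise devascularization between baseline and follow-up
#'
#' Counts voxels in a region that were viable (arterially hyperenhancing) at
#' baseline and non-enhancing at follow-up, as a percentage of the region's
#' baseline-viable voxels. Both viability masks must already live in CT space
#' (registered); regions under 50 voxels are skipped with a flag, as is a
#' region with no baseline-viable voxels (percentage undefined).
#'
#' @param baseline_viability,followup_viability [viable_mask()] results in CT
#'   space.
#' @param region a [binary_mask] in CT space.
#' @param region_id identifier carried into the result.
#' @return List of class `region_outcome`: `region_id`, `n_baseline_viable`,
#'   `n_converted`, `pct_reduction`, `skipped`.
#' @export
regional_reduction <- function(baseline_viability, followup_viability,
                               region, region_id = "region") {
  stopifnot(inherits(baseline_viability, "viability_mask"),
            inherits(followup_viability, "viability_mask"))
  if (!identical(dim(region$voxels), dim(baseline_viability$viable$voxels)) ||
      !identical(dim(region$voxels), dim(followup_viability$viable$voxels)))
    stop("region and viability masks must share the CT grid")
  n <- sum(region$voxels)
  skip <- function(reason)
    structure(list(region_id = region_id, n_region = n,
                   n_baseline_viable = NA_integer_, n_converted = NA_integer_,
                   pct_reduction = NA_real_, skipped = TRUE, reason = reason),
              class = "region_outcome")
  if (n < 50) return(skip(sprintf("region has %d voxels (< 50)", n)))
  base_v <- region$voxels & baseline_viability$viable$voxels
  n_base <- sum(base_v)
  if (n_base == 0) return(skip("no baseline-viable voxels in region"))
  n_conv <- sum(base_v & !followup_viability$viable$voxels)
  structure(list(region_id = region_id, n_region = n,
                 n_baseline_viable = n_base, n_converted = n_conv,
                 pct_reduction = 100 * n_conv / n_base, skipped = FALSE),
            class = "region_outcome")
}

#' @export
print.region_outcome <- function(x, ...) {
  if (x$skipped)
    cat(sprintf("<region_outcome> %s: skipped (%s)\n", x$region_id, x$reason))
  else
    cat(sprintf("<region_outcome> %s: %d/%d baseline-viable voxels converted (%.1f%%)\n",
                x$region_id, x$n_converted, x$n_baseline_viable,
                x$pct_reduction))
  invisible(x)
}
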