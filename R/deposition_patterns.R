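#' Pattern cut-off configuration
#'
#' Every pattern cut-off in one place, defaulting to the values the source
#' cohort was analyzed with: homogeneity at 85% mid-or-high coverage,
#' sparsity at 20% mid and 10% high, rim decision at a mean rim excess of
#' 17 HU over the base intensity, periphery band 3.5 mm, core erosion at 15%
#' of the equivalent-sphere radius. `sparse_mid_includes_high` switches the
#' sparsity rule's "medium" term to mid-or-high (the default reads Table 1's
#' "medium density" literally as the mid class alone).
#'
#' @param homogeneous_min minimum mid-or-high fraction for homogeneity.
#' @param sparse_max_mid,sparse_max_high sparsity bounds.
#' @param rim_cutoff_hu rim decision cut-off on the rim score (HU).
#' @param periphery_mm dilation distance for the periphery band (mm).
#' @param core_erode_frac erosion distance as a fraction of the
#'   equivalent-sphere radius.
#' @param sparse_mid_includes_high see above.
#' @return List of cut-offs.
#' @export
pattern_config <- function(homogeneous_min = 0.85, sparse_max_mid = 0.20,
                           sparse_max_high = 0.10, rim_cutoff_hu = 17,
                           periphery_mm = 3.5, core_erode_frac = 0.15,
                           sparse_mid_includes_high = FALSE) {
  list(homogeneous_min = homogeneous_min, sparse_max_mid = sparse_max_mid,
       sparse_max_high = sparse_max_high, rim_cutoff_hu = rim_cutoff_hu,
       periphery_mm = periphery_mm, core_erode_frac = core_erode_frac,
       sparse_mid_includes_high = sparse_mid_includes_high)
}

label_fractions <- function(map) {
  lab <- map$labels[map$tumor_mask$voxels]
  tab <- tabulate(lab + 1L, 4L)
  tab / length(lab)
}

#' Homogeneous deposition test
#'
#' Deposition is homogeneous iff at least 85% (inclusive) of the tumor volume
#' contains medium- or high-density Lipiodol.
#'
#' @param map a [classify_density()] result.
#' @param config a [pattern_config()].
#' @return List: `homogeneous` (logical), `frac_mid_or_high`.
#' @export
is_homogeneous <- function(map, config = pattern_config()) {
  fr <- label_fractions(map)
  f <- fr[3] + fr[4]
  list(homogeneous = f >= config$homogeneous_min, frac_mid_or_high = f)
}

#' Sparse deposition test
#'
#' Deposition is sparse iff at most 20% of the tumor volume has medium AND at
#' most 10% has high-density Lipiodol (both inclusive).
#'
#' @inheritParams is_homogeneous
#' @return List: `sparse` (logical), `frac_mid`, `frac_high`.
#' @export
is_sparse <- function(map, config = pattern_config()) {
  fr <- label_fractions(map)
  f_mid <- if (config$sparse_mid_includes_high) fr[3] + fr[4] else fr[3]
  list(sparse = f_mid <= config$sparse_max_mid & fr[4] <= config$sparse_max_high,
       frac_mid = fr[3], frac_high = fr[4])
}

# Distance (mm) from every voxel to the nearest voxel outside the mask.
dist_to_background <- function(mask) {
  array(edt_cpp(!mask$voxels, dim(mask$voxels), mask$spacing),
        dim(mask$voxels))
}

# Distance (mm) from every voxel to the nearest voxel inside the mask.
dist_to_mask <- function(mask) {
  array(edt_cpp(mask$voxels, dim(mask$voxels), mask$spacing),
        dim(mask$voxels))
}

#' Rim deposition analysis
#'
#' Splits the tumor into a core and a rim shell in physical units: from the
#' tumor's physical volume V, the equivalent-sphere radius
#' `r_eq = (3V / 4 pi)^(1/3)` is computed; the core is the tumor eroded by
#' 15% of that radius (Euclidean distance transform in mm, correct on
#' anisotropic grids), the rim is the remainder. The base intensity is the
#' maximum of the low-density floor `t_min` and the mean core HU; the rim
#' score is the mean over rim voxels of `max(0, HU - base)` (voxels below
#' base contribute 0). The tumor is rim-depositing iff the score reaches
#' 17 HU. Tumors whose erosion empties the core or the rim get a flagged
#' "rim undefined" result with `rim = FALSE`.
#'
#' @param ct an [image_volume] (CT, HU).
#' @param tumor_mask a [binary_mask] on the CT grid.
#' @param t_min HU floor for Lipiodol presence.
#' @param config a [pattern_config()].
#' @return List: `rim`, `rim_score`, `base_intensity`, `r_eq_mm`,
#'   `core_mask`, `rim_mask`, `defined`.
#' @export
rim_analysis <- function(ct, tumor_mask, t_min, config = pattern_config()) {
  check_geometry(tumor_mask, ct, "tumor mask")
  if (!any(tumor_mask$voxels)) stop("empty tumor mask")
  V <- sum(tumor_mask$voxels) * prod(tumor_mask$spacing)
  r_eq <- (3 * V / (4 * pi))^(1 / 3)
  d_er <- config$core_erode_frac * r_eq
  dist <- dist_to_background(tumor_mask)
  core <- tumor_mask$voxels & (dist > d_er)
  rim <- tumor_mask$voxels & !core
  if (!any(core) || !any(rim)) {
    # erosion emptied the core, or the erosion distance is below the voxel
    # size so no rim shell exists: rim deposition is undefined
    core_mask <- if (any(core))
      binary_mask(core, spacing = tumor_mask$spacing,
                  origin = tumor_mask$origin) else NULL
    return(list(rim = FALSE, rim_score = NA_real_, base_intensity = NA_real_,
                r_eq_mm = r_eq, core_mask = core_mask, rim_mask = NULL,
                defined = FALSE))
  }
  base <- max(t_min, mean(ct$voxels[core]))
  score <- mean(pmax(0, ct$voxels[rim] - base))
  list(rim = score >= config$rim_cutoff_hu, rim_score = score,
       base_intensity = base, r_eq_mm = r_eq,
       core_mask = binary_mask(core, spacing = tumor_mask$spacing,
                               origin = tumor_mask$origin),
       rim_mask = binary_mask(rim, spacing = tumor_mask$spacing,
                              origin = tumor_mask$origin),
       defined = TRUE)
}

#' Peripheral Lipiodol coverage
#'
#' Dilates the tumor mask by 3.5 mm (physical units), subtracts the tumor,
#' and reports the percentage of the resulting periphery band whose voxels
#' exceed the Lipiodol floor `t_min`. If the band is clipped by the volume
#' border the result is flagged (`clipped = TRUE`).
#'
#' @inheritParams rim_analysis
#' @return List: `peripheral_pct`, `n_periphery`, `periphery_mask`,
#'   `clipped`.
#' @export
peripheral_coverage <- function(ct, tumor_mask, t_min,
                                config = pattern_config()) {
  check_geometry(tumor_mask, ct, "tumor mask")
  if (!any(tumor_mask$voxels)) stop("empty tumor mask")
  dist <- dist_to_mask(tumor_mask)
  peri <- !tumor_mask$voxels & (dist <= config$periphery_mm)
  if (!any(peri)) stop("empty periphery: degenerate geometry")
  d <- dim(tumor_mask$voxels)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  clipped <- any(peri & border) || any(tumor_mask$voxels & border)
  pct <- 100 * sum(ct$voxels[peri] > t_min) / sum(peri)
  list(peripheral_pct = pct, n_periphery = sum(peri),
       periphery_mask = binary_mask(peri, spacing = tumor_mask$spacing,
                                    origin = tumor_mask$origin),
       clipped = clipped)
}

#' Classify a lesion's Lipiodol deposition pattern
#'
#' Composes the four pattern features into the deposition-pattern taxonomy:
#' the growth type (well-delineated vs infiltrative) is a manual annotation
#' taken from the lesion record, never inferred; homogeneity, sparsity and
#' (for well-delineated lesions only) rim presence are computed from the
#' density label map and CT. The category string follows the decision tree:
#' well-delineated lesions are homogeneous, or rim/non-rim crossed with
#' sparse/non-sparse; infiltrative lesions are sparse or non-sparse.
#' Peripheral coverage is reported alongside as a continuous percentage.
#'
#' @param map a [classify_density()] result.
#' @param ct an [image_volume] (CT, HU).
#' @param tumor_mask a [binary_mask] on the CT grid.
#' @param t_min HU floor for Lipiodol presence.
#' @param lesion a [lesion_record()] (supplies `growth_type`).
#' @param config a [pattern_config()].
#' @return List of class `pattern_report`.
#' @export
classify_pattern <- function(map, ct, tumor_mask, t_min, lesion,
                             config = pattern_config()) {
  stopifnot(inherits(lesion, "lesion_record"))
  hom <- is_homogeneous(map, config)
  spa <- is_sparse(map, config)
  peri <- peripheral_coverage(ct, tumor_mask, t_min, config)
  well <- lesion$growth_type == "well_delineated"
  rim <- if (well) rim_analysis(ct, tumor_mask, t_min, config)
         else list(rim = NA, rim_score = NA_real_, base_intensity = NA_real_,
                   core_mask = NULL, rim_mask = NULL, defined = FALSE)
  category <-
    if (!well) {
      if (spa$sparse) "infiltrative sparse" else "infiltrative non-sparse"
    } else if (hom$homogeneous) {
      "homogeneous"
    } else {
      paste(if (isTRUE(rim$rim)) "rim" else "non-rim",
            if (spa$sparse) "sparse" else "non-sparse")
    }
  structure(list(
    lesion_id = lesion$lesion_id, growth_type = lesion$growth_type,
    category = category,
    homogeneous = hom$homogeneous, frac_mid_or_high = hom$frac_mid_or_high,
    sparse = spa$sparse, frac_mid = spa$frac_mid, frac_high = spa$frac_high,
    rim = rim$rim, rim_score = rim$rim_score,
    base_intensity = rim$base_intensity, rim_defined = rim$defined,
    peripheral_pct = peri$peripheral_pct, periphery_clipped = peri$clipped,
    core_mask = rim$core_mask, rim_mask = rim$rim_mask,
    periphery_mask = peri$periphery_mask),
    class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(sprintf("<pattern_report> %s (%s): %s | mid+high %.1f%%, rim score %s, peripheral %.1f%%\n",
              x$lesion_id, x$growth_type, x$category,
              100 * x$frac_mid_or_high,
              if (is.na(x$rim_score)) "n/a" else sprintf("%.1f HU", x$rim_score),
              x$peripheral_pct))
  invisible(x)
}

#' Map a pattern report onto the phantom archetype labels
#'
#' Deterministic mapping from a [classify_pattern()] report to the seven
#' generator archetypes, used to score archetype recovery on phantoms:
#' infiltrative lesions map to `sparse`; well-delineated lesions map to
#' `homogeneous`, `peripheral_halo` (sparse, non-rim interior with at least
#' half of the 3.5 mm periphery band Lipiodol-positive), or the
#' rim/non-rim x sparse/non-sparse combinations.
#'
#' @param report a `pattern_report`.
#' @param peripheral_min_pct periphery coverage (percent) above which a
#'   sparse non-rim lesion counts as a peripheral-halo archetype.
#' @return One of `"homogeneous"`, `"sparse"`, `"rim_sparse"`,
#'   `"rim_nonsparse"`, `"nonrim_sparse"`, `"nonrim_nonsparse"`,
#'   `"peripheral_halo"` (or `"infiltrative_nonsparse"`).
#' @export
pattern_archetype <- function(report, peripheral_min_pct = 50) {
  stopifnot(inherits(report, "pattern_report"))
  if (report$growth_type == "infiltrative")
    return(if (report$sparse) "sparse" else "infiltrative_nonsparse")
  if (report$homogeneous) return("homogeneous")
  rim <- isTRUE(report$rim)
  if (!rim && report$sparse && report$peripheral_pct >= peripheral_min_pct)
    return("peripheral_halo")
  if (rim && report$sparse) return("rim_sparse")
  if (rim && !report$sparse) return("rim_nonsparse")
  if (report$sparse) return("nonrim_sparse")
  "nonrim_nonsparse"
}
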