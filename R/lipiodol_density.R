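#' @section Percentile convention:
#' All percentiles in this package (the 99th-percentile parenchyma floor and
#' the 33rd/67th cohort percentiles) use linear interpolation between order
#' statistics (R's `quantile()` type 7): for a sorted sample x of size n and
#' probability p, the value at rank 1 + p(n-1), interpolated.
#' @name percentile-convention
#' @keywords internal
NULL

pctile <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

#' Minimum Lipiodol threshold from Lipiodol-free parenchyma
#'
#' The floor separating "no Lipiodol" from low-density Lipiodol is the 99th
#' percentile of voxel intensities sampled from parenchyma regions in which no
#' Lipiodol deposition is observed. The study this package implements reports
#' 87 HU for its cohort.
#'
#' @param samples numeric vector of HU values from no-Lipiodol parenchyma.
#' @return Threshold in HU.
#' @export
parenchyma_min_threshold <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty parenchyma sample set")
  if (length(samples) < 100)
    warning("fewer than 100 parenchyma sample voxels (", length(samples), ")")
  pctile(samples, 0.99)
}

# Integer-HU candidate grid over [min, max) of the sample. HU is an
# integer-calibrated scale; an integer grid keeps the exhaustive search and
# any independent oracle on the same footing.
threshold_candidates <- function(v) {
  lo <- floor(min(v))
  hi <- ceiling(max(v))
  if (hi - 1 < lo) lo else seq.int(lo, hi - 1)
}

# Class statistics for every candidate cut t: "lower" is v <= t, "higher"
# v > t. Returns only candidates with both classes non-empty.
split_stats <- function(v) {
  cand <- threshold_candidates(v)
  vs <- sort(v)
  cs <- cumsum(vs)
  n <- length(vs)
  n1 <- findInterval(cand, vs)           # count of v <= t
  keep <- n1 > 0 & n1 < n
  cand <- cand[keep]; n1 <- n1[keep]
  if (length(cand) == 0) return(NULL)
  s1 <- cs[n1]
  list(cand = cand, n1 = n1, n2 = n - n1, s1 = s1, s2 = cs[n] - s1, n = n)
}

#' Bilevel threshold maximizing between-class variance
#'
#' Otsu's criterion: exhaustive search over integer-HU candidate cuts for the
#' threshold t maximizing `w1 * w2 * (mu1 - mu2)^2`, where class 1 is `v <= t`
#' and class 2 is `v > t`. Ties return the smallest optimal candidate.
#'
#' @param values numeric vector of HU values (at least 2 distinct).
#' @return Threshold in HU.
#' @export
bilevel_threshold_variance <- function(values) {
  v <- as.numeric(values)
  if (length(unique(v)) < 2) stop("degenerate histogram: all values identical")
  st <- split_stats(v)
  m1 <- st$s1 / st$n1
  m2 <- st$s2 / st$n2
  obj <- (st$n1 / st$n) * (st$n2 / st$n) * (m1 - m2)^2
  st$cand[which.max(obj)]  # which.max takes the first (smallest) maximizer
}

#' Bilevel threshold minimizing cross-entropy
#'
#' Li's minimum cross-entropy criterion: exhaustive search over integer-HU
#' candidates for the t minimizing
#' `-(S1 * log(mu1) + S2 * log(mu2))`, with S the class intensity sums and mu
#' the class means ("lower" `v <= t`, "higher" `v > t`). The criterion needs
#' positive intensities; non-positive samples are shifted to be positive and
#' the resulting threshold shifted back. Ties return the smallest candidate.
#'
#' @inheritParams bilevel_threshold_variance
#' @return Threshold in HU.
#' @export
bilevel_threshold_cross_entropy <- function(values) {
  v <- as.numeric(values)
  if (length(unique(v)) < 2) stop("degenerate histogram: all values identical")
  shift <- 0
  if (min(v) <= 0) {
    shift <- ceiling(1 - min(v))
    v <- v + shift
  }
  st <- split_stats(v)
  m1 <- st$s1 / st$n1
  m2 <- st$s2 / st$n2
  obj <- -(st$s1 * log(m1) + st$s2 * log(m2))
  st$cand[which.min(obj)] - shift
}

#' Per-tumor bilevel Lipiodol threshold
#'
#' Splits one tumor's Lipiodol deposition into lower- and higher-density
#' regions: both bilevel operators are applied and their average taken. By
#' default they run on the tumor's Lipiodol-positive voxels only (HU >
#' `t_min`); `scope = "full_tumor"` uses the whole tumor histogram instead.
#' Tumors with fewer than 50 Lipiodol-positive voxels are skipped with a flag
#' (not an error) and excluded from cohort threshold derivation.
#'
#' @param ct an [image_volume] (CT, HU).
#' @param tumor_mask a [binary_mask] on the CT grid.
#' @param t_min HU floor from [parenchyma_min_threshold()].
#' @param scope `"lipiodol_positive"` (default) or `"full_tumor"`.
#' @return List with `t_ce`, `t_var`, `t_mean`, `n_positive`, `skipped` and,
#'   when skipped, `reason`.
#' @export
per_tumor_threshold <- function(ct, tumor_mask, t_min,
                                scope = c("lipiodol_positive", "full_tumor")) {
  scope <- match.arg(scope)
  check_geometry(tumor_mask, ct, "tumor mask")
  vals <- ct$voxels[tumor_mask$voxels]
  pos <- vals[vals > t_min]
  use <- if (scope == "lipiodol_positive") pos else vals
  if (length(pos) < 50)
    return(list(skipped = TRUE,
                reason = sprintf("only %d Lipiodol-positive voxels (< 50)",
                                 length(pos)),
                n_positive = length(pos),
                t_ce = NA_real_, t_var = NA_real_, t_mean = NA_real_))
  t_ce <- bilevel_threshold_cross_entropy(use)
  t_var <- bilevel_threshold_variance(use)
  list(skipped = FALSE, n_positive = length(pos),
       t_ce = t_ce, t_var = t_var, t_mean = (t_ce + t_var) / 2)
}

#' Cohort-level density thresholds from per-tumor thresholds
#'
#' Pools the per-tumor bilevel thresholds into the two cohort cut-offs: the
#' 33rd percentile across tumors separates low from medium density and the
#' 67th percentile separates medium from high. Two orderings of the
#' percentile/average steps are supported:
#' * `"percentile_then_average"` (default): take the 33rd/67th percentile of
#'   each technique's threshold list separately, then average the two
#'   techniques. This is the computation whose intermediate values the source
#'   study prints (cross-entropy 159/239 HU and variance 151/243 HU averaging
#'   to 155/241 HU).
#' * `"average_then_percentile"`: percentiles of the per-tumor averaged
#'   thresholds.
#'
#' @param per_tumor data.frame (or list of lists) with columns `t_ce`,
#'   `t_var`; skipped tumors (NA) are dropped.
#' @param mode percentile/average ordering, see above.
#' @return List with `t_low_mid`, `t_mid_high` (HU) and the per-technique
#'   percentiles in `detail`.
#' @export
cohort_thresholds <- function(per_tumor,
                              mode = c("percentile_then_average",
                                       "average_then_percentile")) {
  mode <- match.arg(mode)
  if (!is.data.frame(per_tumor))
    per_tumor <- do.call(rbind, lapply(per_tumor, function(r)
      data.frame(t_ce = r$t_ce, t_var = r$t_var)))
  keep <- complete.cases(per_tumor[, c("t_ce", "t_var")])
  per_tumor <- per_tumor[keep, , drop = FALSE]
  if (nrow(per_tumor) < 3)
    stop("cohort threshold derivation needs at least 3 tumors, got ",
         nrow(per_tumor))
  if (mode == "percentile_then_average") {
    q33 <- c(ce = pctile(per_tumor$t_ce, 0.33), var = pctile(per_tumor$t_var, 0.33))
    q67 <- c(ce = pctile(per_tumor$t_ce, 0.67), var = pctile(per_tumor$t_var, 0.67))
    list(t_low_mid = mean(q33), t_mid_high = mean(q67),
         detail = list(q33 = q33, q67 = q67, mode = mode))
  } else {
    tm <- (per_tumor$t_ce + per_tumor$t_var) / 2
    list(t_low_mid = pctile(tm, 0.33), t_mid_high = pctile(tm, 0.67),
         detail = list(mode = mode))
  }
}

#' The three Lipiodol density cut-offs
#'
#' @param t_min HU floor (no Lipiodol vs low density).
#' @param t_low_mid HU cut between low and medium density.
#' @param t_mid_high HU cut between medium and high density.
#' @param provenance free-form record of how each was derived.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(t_min, t_low_mid, t_mid_high, provenance = "fixed") {
  stopifnot(is.numeric(t_min), is.numeric(t_low_mid), is.numeric(t_mid_high))
  if (!(t_min < t_low_mid && t_low_mid < t_mid_high))
    stop("thresholds must satisfy t_min < t_low_mid < t_mid_high")
  structure(list(t_min = t_min, t_low_mid = t_low_mid,
                 t_mid_high = t_mid_high, provenance = provenance),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> none/low %g HU | low/mid %g HU | mid/high %g HU\n",
              x$t_min, x$t_low_mid, x$t_mid_high))
  invisible(x)
}

#' Default cut-offs published for the source cohort
#'
#' 87 / 155 / 241 HU — usable directly on new data without re-deriving
#' cohort thresholds.
#' @return A [threshold_set].
#' @export
default_thresholds <- function() {
  threshold_set(87, 155, 241, provenance = "published cohort values")
}

#' Per-voxel Lipiodol density classification
#'
#' Labels every tumor voxel by density class. Boundary semantics are
#' strict-above throughout ("contains Lipiodol" means the voxel *exceeds* the
#' floor): none if HU <= t_min; low if t_min < HU <= t_low_mid; mid if
#' t_low_mid < HU <= t_mid_high; high if HU > t_mid_high. Voxels outside the
#' tumor are 0.
#'
#' @param ct an [image_volume] (CT, HU).
#' @param tumor_mask a [binary_mask] on the CT grid.
#' @param thresholds a [threshold_set].
#' @return An object of class `density_label_map` with an integer `labels`
#'   array (0 none, 1 low, 2 mid, 3 high), the mask and the thresholds used.
#' @export
classify_density <- function(ct, tumor_mask, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  check_geometry(tumor_mask, ct, "tumor mask")
  hu <- ct$voxels
  lab <- (hu > thresholds$t_min) + (hu > thresholds$t_low_mid) +
    (hu > thresholds$t_mid_high)
  lab[!tumor_mask$voxels] <- 0L
  structure(list(labels = array(as.integer(lab), dim(hu)),
                 tumor_mask = tumor_mask, threshold_set = thresholds,
                 spacing = tumor_mask$spacing, origin = tumor_mask$origin),
            class = "density_label_map")
}

#' @export
print.density_label_map <- function(x, ...) {
  n <- sum(x$tumor_mask$voxels)
  tab <- tabulate(x$labels[x$tumor_mask$voxels] + 1L, 4L)
  cat(sprintf("<density_label_map> %d tumor voxels: none %d, low %d, mid %d, high %d\n",
              n, tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Lipiodol coverage of a tumor region
#'
#' Fraction of region voxels containing Lipiodol of any density, plus the
#' per-class fractions. Regions smaller than 50 voxels are skipped with a
#' flag (segmentation/registration imprecision makes them unreliable); the
#' region must lie inside the tumor mask of the label map.
#'
#' @param map a [classify_density()] result.
#' @param region a [binary_mask], subset of the tumor mask.
#' @param region_id identifier carried into the result.
#' @return List of class `coverage_stats`: `region_id`, `n_voxels`,
#'   `frac_any`, `frac_low`, `frac_mid`, `frac_high`, `skipped`.
#' @export
coverage <- function(map, region, region_id = "region") {
  stopifnot(inherits(map, "density_label_map"))
  if (!identical(dim(region$voxels), dim(map$labels)))
    stop("region grid does not match label map")
  if (!any(region$voxels)) stop("empty region")
  if (any(region$voxels & !map$tumor_mask$voxels))
    stop("region extends outside the tumor mask")
  n <- sum(region$voxels)
  if (n < 50)
    return(structure(list(region_id = region_id, n_voxels = n,
                          frac_any = NA_real_, frac_low = NA_real_,
                          frac_mid = NA_real_, frac_high = NA_real_,
                          skipped = TRUE,
                          reason = sprintf("region has %d voxels (< 50)", n)),
                     class = "coverage_stats"))
  lab <- map$labels[region$voxels]
  tab <- tabulate(lab + 1L, 4L)
  structure(list(region_id = region_id, n_voxels = n,
                 frac_any = sum(tab[2:4]) / n,
                 frac_low = tab[2] / n, frac_mid = tab[3] / n,
                 frac_high = tab[4] / n, skipped = FALSE),
            class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  if (x$skipped)
    cat(sprintf("<coverage_stats> %s: skipped (%s)\n", x$region_id, x$reason))
  else
    cat(sprintf("<coverage_stats> %s: n=%d any %.1f%% (low %.1f%%, mid %.1f%%, high %.1f%%)\n",
                x$region_id, x$n_voxels, 100 * x$frac_any, 100 * x$frac_low,
                100 * x$frac_mid, 100 * x$frac_high))
  invisible(x)
}
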