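#' Pipeline configuration
#'
#' One structured object controlling every cut-off and mode of the per-lesion
#' and cohort workflows, with the published values as defaults. Supplying a
#' `thresholds` [threshold_set] (e.g. [default_thresholds()]) skips cohort
#' threshold derivation — the published 87/155/241 HU cut-offs applied to new
#' data.
#'
#' @param thresholds a [threshold_set], or `NULL` to derive cohort thresholds
#'   from the data (two-pass).
#' @param t_min_override fixed Lipiodol floor (HU); `NULL` derives it from
#'   the pooled no-Lipiodol parenchyma samples (99th percentile).
#' @param pattern pattern cut-offs, a [pattern_config()].
#' @param demons registration settings, a [demons_config()].
#' @param percentile_mode cohort percentile/average ordering, see
#'   [cohort_thresholds()].
#' @param threshold_scope per-tumor bilevel scope, see
#'   [per_tumor_threshold()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = NULL, t_min_override = NULL,
                            pattern = pattern_config(),
                            demons = demons_config(),
                            percentile_mode = "percentile_then_average",
                            threshold_scope = "lipiodol_positive") {
  structure(list(thresholds = thresholds, t_min_override = t_min_override,
                 pattern = pattern, demons = demons,
                 percentile_mode = percentile_mode,
                 threshold_scope = threshold_scope),
            class = "pipeline_config")
}

#' Adapt a phantom case to the lesion-case input contract
#'
#' A lesion case is a list with the CT, both MRIs, the per-time-point tumor
#' masks, the VOI and parenchyma-sample masks, and the lesion record. The
#' phantom generator produces all time points on one grid with a shared
#' tumor mask.
#'
#' @param case a `phantom_case` or a directory written by
#'   [write_phantom_case()].
#' @return A list satisfying the [run_lesion()] input contract.
#' @export
as_lesion_case <- function(case) {
  if (is.character(case)) {
    dir <- case
    truth <- utils::read.csv(file.path(dir, "truth.csv"))
    ct <- load_volume(file.path(dir, "ct.nii.gz"), "CT")
    list(ct = ct,
         mri_baseline = load_volume(file.path(dir, "mri_baseline.nii.gz"), "MRI"),
         mri_followup = load_volume(file.path(dir, "mri_followup.nii.gz"), "MRI"),
         tumor_mask_ct = load_mask(file.path(dir, "tumor_mask.nii.gz"), ct),
         tumor_mask_baseline = load_mask(file.path(dir, "tumor_mask.nii.gz")),
         tumor_mask_followup = load_mask(file.path(dir, "tumor_mask.nii.gz")),
         voi_mask = load_mask(file.path(dir, "voi_mask.nii.gz")),
         parenchyma_mask = load_mask(file.path(dir, "parenchyma_mask.nii.gz")),
         lesion = lesion_record(truth$lesion_id[1], "HCC",
                                truth$growth_type[1], "selective",
                                truth$diameter_cm[1]))
  } else {
    stopifnot(inherits(case, "phantom_case"))
    list(ct = case$ct, mri_baseline = case$mri_baseline,
         mri_followup = case$mri_followup,
         tumor_mask_ct = case$tumor_mask,
         tumor_mask_baseline = case$tumor_mask,
         tumor_mask_followup = case$tumor_mask,
         voi_mask = case$voi_mask, parenchyma_mask = case$parenchyma_mask,
         lesion = case$lesion)
  }
}

# row-bind data frames with unequal columns, padding with NA
rbind_fill <- function(dfs) {
  dfs <- Filter(Negate(is.null), dfs)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}

excluded_row <- function(lesion_id, reason) {
  data.frame(lesion_id = lesion_id, status = "excluded",
             exclude_reason = reason, stringsAsFactors = FALSE)
}

#' Analyze one lesion end to end
#'
#' Runs the full per-lesion workflow in order: input checks and exclusion
#' rules (diameter >= 1 cm, presence of all inputs, baseline enhancement),
#' MRI-to-CT mask registration for both MRI time points, qEASL viability in
#' native MRI space with label-safe resampling of the compartment masks into
#' CT space, density classification, coverage of the whole tumor and the
#' viable/necrotic subregions, pattern classification, ETV response, and
#' density-stratified regional devascularization. Any stage error marks the
#' lesion excluded with the stage name; a cohort run continues.
#'
#' @param case a lesion case, see [as_lesion_case()].
#' @param config a [pipeline_config()]. `config$thresholds` must be set
#'   (run_lesion does not derive cohort thresholds; see [run_cohort()]),
#'   otherwise the published defaults are used.
#' @return List of class `lesion_result`: `row` (one-row feature data.frame),
#'   `maps` (density map, pattern report, viability masks), `regional`
#'   (per-density-class region outcomes), `status`.
#' @export
run_lesion <- function(case, config = pipeline_config()) {
  if (inherits(case, "phantom_case")) case <- as_lesion_case(case)
  lesion <- case$lesion
  fail <- function(stage, msg)
    list(row = excluded_row(lesion$lesion_id, paste0(stage, ": ", msg)),
         status = "excluded", maps = NULL, regional = NULL)

  required <- c("ct", "mri_baseline", "mri_followup", "tumor_mask_ct",
                "tumor_mask_baseline", "tumor_mask_followup", "voi_mask")
  miss <- required[vapply(required, function(f) is.null(case[[f]]), TRUE)]
  if (length(miss) > 0)
    return(fail("inputs", paste("missing input:", paste(miss, collapse = ", "))))
  if (lesion$diameter_cm < 1)
    return(fail("inclusion", "diameter < 1 cm"))

  thr <- config$thresholds
  if (is.null(thr)) {
    t_min <- config$t_min_override
    if (is.null(t_min) && !is.null(case$parenchyma_mask))
      t_min <- parenchyma_min_threshold(
        case$ct$voxels[case$parenchyma_mask$voxels])
    thr <- default_thresholds()
    if (!is.null(t_min) && t_min < thr$t_low_mid)
      thr <- threshold_set(t_min, thr$t_low_mid, thr$t_mid_high,
                           provenance = "derived floor, published cut-offs")
  }

  res <- tryCatch({
    # registration: both MRI tumor masks onto the CT tumor mask
    reg_b <- register_masks(case$tumor_mask_ct, case$tumor_mask_baseline,
                            config$demons)
    reg_f <- register_masks(case$tumor_mask_ct, case$tumor_mask_followup,
                            config$demons)

    # qEASL in native MRI space
    voi_b <- voi_stats(case$mri_baseline, case$voi_mask)
    viab_b <- viable_mask(case$mri_baseline, case$tumor_mask_baseline, voi_b)
    voi_f <- voi_stats(case$mri_followup, case$voi_mask)
    viab_f <- viable_mask(case$mri_followup, case$tumor_mask_followup, voi_f)

    etv_b <- etv(viab_b)
    etv_f <- etv(viab_f)
    if (etv_b == 0) stop("no enhancing tumor tissue on baseline MRI")
    pct <- percent_change_etv(etv_b, etv_f)

    # compartment masks into CT space (categorical: nearest)
    to_ct <- function(reg, m) apply_transform(reg, m, "nearest")
    viab_b_ct <- list(viable = to_ct(reg_b, viab_b$viable),
                      necrotic = to_ct(reg_b, viab_b$necrotic))
    viab_f_ct <- list(viable = to_ct(reg_f, viab_f$viable),
                      necrotic = to_ct(reg_f, viab_f$necrotic))
    clamp <- function(vm) {  # registered compartments, clipped to CT tumor
      v <- vm$viable$voxels & case$tumor_mask_ct$voxels
      structure(list(
        viable = binary_mask(v, reference = NULL,
                             spacing = case$tumor_mask_ct$spacing,
                             origin = case$tumor_mask_ct$origin),
        necrotic = binary_mask(case$tumor_mask_ct$voxels & !v,
                               spacing = case$tumor_mask_ct$spacing,
                               origin = case$tumor_mask_ct$origin),
        threshold_used = NA_real_, tumor_mask = case$tumor_mask_ct),
        class = "viability_mask")
    }
    viab_b_ct <- clamp(viab_b_ct)
    viab_f_ct <- clamp(viab_f_ct)

    # density + patterns on CT
    dmap <- classify_density(case$ct, case$tumor_mask_ct, thr)
    cov_all <- coverage(dmap, case$tumor_mask_ct, "whole_tumor")
    cov_viab <- if (sum(viab_b_ct$viable$voxels) > 0)
      coverage(dmap, viab_b_ct$viable, "baseline_viable") else NULL
    cov_necr <- if (sum(viab_b_ct$necrotic$voxels) > 0)
      coverage(dmap, viab_b_ct$necrotic, "baseline_necrotic") else NULL
    pat <- classify_pattern(dmap, case$ct, case$tumor_mask_ct, thr$t_min,
                            lesion, config$pattern)

    # density-stratified devascularization in CT space
    regional <- lapply(0:3, function(k) {
      reg_mask <- binary_mask(dmap$labels == k & case$tumor_mask_ct$voxels,
                              spacing = case$tumor_mask_ct$spacing,
                              origin = case$tumor_mask_ct$origin)
      if (!any(reg_mask$voxels)) return(NULL)
      regional_reduction(viab_b_ct, viab_f_ct, reg_mask,
                         c("none", "low", "mid", "high")[k + 1])
    })
    regional <- Filter(Negate(is.null), regional)

    gv <- function(cv, f) if (is.null(cv) || cv$skipped) NA_real_ else cv[[f]]
    row <- data.frame(
      lesion_id = lesion$lesion_id, status = "analyzed", exclude_reason = "",
      entity = lesion$entity, growth_type = lesion$growth_type,
      tace_approach = lesion$tace_approach, diameter_cm = lesion$diameter_cm,
      t_min = thr$t_min, t_low_mid = thr$t_low_mid, t_mid_high = thr$t_mid_high,
      n_tumor_voxels = sum(case$tumor_mask_ct$voxels),
      frac_any = gv(cov_all, "frac_any"), frac_low = gv(cov_all, "frac_low"),
      frac_mid = gv(cov_all, "frac_mid"), frac_high = gv(cov_all, "frac_high"),
      frac_any_viable = gv(cov_viab, "frac_any"),
      frac_any_necrotic = gv(cov_necr, "frac_any"),
      category = pat$category, homogeneous = pat$homogeneous,
      sparse = pat$sparse, rim = isTRUE(pat$rim),
      rim_score = pat$rim_score, peripheral_pct = pat$peripheral_pct,
      baseline_etv_cm3 = etv_b, followup_etv_cm3 = etv_f,
      pct_change = pct, responder = classify_response(pct),
      dice_baseline = reg_b$dice_post, dice_followup = reg_f$dice_post,
      stringsAsFactors = FALSE)
    list(row = row, status = "analyzed",
         maps = list(density = dmap, pattern = pat,
                     viability_baseline_ct = viab_b_ct,
                     viability_followup_ct = viab_f_ct),
         regional = regional)
  }, error = function(e) fail("analysis", conditionMessage(e)))
  class(res) <- "lesion_result"
  res
}

#' Analyze a cohort of lesions with cohort-level threshold derivation
#'
#' Two-pass workflow: pass 1 derives the Lipiodol floor (99th percentile of
#' pooled no-Lipiodol parenchyma samples) and each tumor's bilevel thresholds,
#' then pools them into the cohort 33rd/67th-percentile cut-offs; pass 2
#' applies the resulting [threshold_set] to every lesion via [run_lesion()].
#' A cohort with fewer than 3 threshold-eligible tumors falls back to the
#' mean per-tumor threshold with a warning. If `config$thresholds` is set,
#' pass 1 is skipped (fixed published cut-offs).
#'
#' @param cases list of lesion cases (see [as_lesion_case()]; `phantom_case`
#'   objects are adapted automatically).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the feature CSV, regional CSV and a
#'   JSON run manifest.
#' @return List of class `cohort_result`: `features` (data.frame),
#'   `regional` (data.frame), `thresholds` ([threshold_set]), `results`
#'   (per-lesion `lesion_result`s), `manifest`.
#' @export
run_cohort <- function(cases, config = pipeline_config(), out_dir = NULL) {
  cases <- lapply(cases, function(c)
    if (inherits(c, "phantom_case")) as_lesion_case(c) else c)

  thr <- config$thresholds
  per_tumor <- NULL
  if (is.null(thr)) {
    t_min <- config$t_min_override
    if (is.null(t_min)) {
      samp <- unlist(lapply(cases, function(c)
        if (is.null(c$parenchyma_mask)) numeric(0)
        else c$ct$voxels[c$parenchyma_mask$voxels]))
      t_min <- parenchyma_min_threshold(samp)
    }
    per_tumor <- do.call(rbind, lapply(cases, function(c) {
      r <- per_tumor_threshold(c$ct, c$tumor_mask_ct, t_min,
                               config$threshold_scope)
      data.frame(lesion_id = c$lesion$lesion_id, t_ce = r$t_ce,
                 t_var = r$t_var, t_mean = r$t_mean, skipped = r$skipped)
    }))
    eligible <- per_tumor[!per_tumor$skipped, ]
    if (nrow(eligible) >= 3) {
      ct <- cohort_thresholds(eligible, config$percentile_mode)
      thr <- threshold_set(t_min, ct$t_low_mid, ct$t_mid_high,
                           provenance = "cohort-derived")
    } else if (nrow(eligible) >= 1) {
      warning("fewer than 3 threshold-eligible tumors; falling back to the ",
              "mean per-tumor threshold")
      tm <- mean(eligible$t_mean)
      thr <- threshold_set(t_min, tm, tm + 1e-6,
                           provenance = "single-tumor fallback")
    } else {
      stop("no tumor has enough Lipiodol-positive voxels for thresholds")
    }
  }

  cfg2 <- config
  cfg2$thresholds <- thr
  results <- lapply(cases, run_lesion, config = cfg2)

  features <- rbind_fill(lapply(results, function(r) r$row))
  regional <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (is.null(r$regional) || length(r$regional) == 0) return(NULL)
    do.call(rbind, lapply(r$regional, function(o)
      data.frame(lesion_id = r$row$lesion_id, region_id = o$region_id,
                 n_region = o$n_region,
                 n_baseline_viable = o$n_baseline_viable,
                 n_converted = o$n_converted,
                 pct_reduction = o$pct_reduction, skipped = o$skipped,
                 stringsAsFactors = FALSE)))
  }))

  manifest <- list(
    software = paste("lipioquant",
                     as.character(utils::packageVersion("lipioquant"))),
    thresholds = list(t_min = thr$t_min, t_low_mid = thr$t_low_mid,
                      t_mid_high = thr$t_mid_high,
                      provenance = thr$provenance),
    percentile_mode = config$percentile_mode,
    lesions = lapply(results, function(r)
      list(lesion_id = r$row$lesion_id, status = r$row$status,
           reason = r$row$exclude_reason)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    if (!is.null(regional))
      write.csv(regional, file.path(out_dir, "regional.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(features = features, regional = regional, thresholds = thr,
                 per_tumor = per_tumor, results = results,
                 manifest = manifest),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  n_ok <- sum(x$features$status == "analyzed")
  cat(sprintf("<cohort_result> %d lesions (%d analyzed, %d excluded); thresholds %g/%g/%g HU\n",
              nrow(x$features), n_ok, nrow(x$features) - n_ok,
              x$thresholds$t_min, x$thresholds$t_low_mid,
              x$thresholds$t_mid_high))
  invisible(x)
}
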