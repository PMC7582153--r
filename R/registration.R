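#' Demons registration settings
#'
#' Hyperparameters of the mask-driven diffeomorphic demons iteration. The
#' source study does not report registration hyperparameters; these defaults
#' are package choices, all overridable.
#'
#' @param iterations maximum demons iterations.
#' @param sigma_image Gaussian smoothing (voxels) applied to the binary masks
#'   before force computation; the smoothed masks play the role of the fixed
#'   and moving images.
#' @param sigma_fluid fluid-like regularization: smoothing (voxels) of each
#'   force increment.
#' @param sigma_diff diffusion-like regularization: smoothing (voxels) of the
#'   accumulated displacement field.
#' @param max_step cap (mm) on the per-iteration displacement increment;
#'   small steps keep the accumulated field invertible.
#' @param dice_tol stop early once Dice reaches `1 - dice_tol`.
#' @return A list of settings.
#' @export
demons_config <- function(iterations = 100, sigma_image = 1.5,
                          sigma_fluid = 1.0, sigma_diff = 1.0,
                          max_step = 1.0, dice_tol = 1e-3) {
  list(iterations = iterations, sigma_image = sigma_image,
       sigma_fluid = sigma_fluid, sigma_diff = sigma_diff,
       max_step = max_step, dice_tol = dice_tol)
}

mask_centroid_mm <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  mask$origin + (colMeans(idx) - 1) * mask$spacing
}

smooth_field <- function(disp, d, sigma) {
  if (sigma <= 0) return(disp)
  for (c in 1:3)
    disp[, c] <- gauss_smooth_cpp(disp[, c], d, rep(sigma, 3))
  disp
}

warp_to_fixed <- function(values, geom_m, fixed, disp, nearest, fill = 0) {
  warp_cpp(as.numeric(values), dim(geom_m$voxels), geom_m$spacing,
           geom_m$origin, dim(fixed$voxels), fixed$spacing, fixed$origin,
           disp, nearest, fill)
}

#' Register a moving tumor mask to a fixed tumor mask
#'
#' Mask-driven deformable registration in the direction MRI-to-CT: the fixed
#' mask is the 24 h CT tumor segmentation, the moving mask an MRI tumor
#' segmentation. Registration is derived from the binary masks, not the raw
#' images, so that image intensities (enhancing tumor, Lipiodol) cannot bias
#' downstream intensity analyses. A rigid centroid translation pre-aligns the
#' masks, then a demons iteration on Gaussian-smoothed mask images refines the
#' deformation; force increments are capped and the field smoothed each step
#' so the accumulated transform stays diffeomorphic (everywhere-positive
#' Jacobian determinant, checked).
#'
#' @param fixed_mask,moving_mask non-empty [binary_mask] objects; grids may
#'   differ (the moving mask is resampled onto the fixed grid through the
#'   deformation).
#' @param config settings from [demons_config()].
#' @return An object of class `deformation_field`: per-voxel displacement
#'   (mm, on the fixed grid, n x 3), the fixed geometry, pre/post Dice, and
#'   the minimum Jacobian determinant.
#' @export
register_masks <- function(fixed_mask, moving_mask, config = demons_config()) {
  stopifnot(inherits(fixed_mask, "binary_mask"),
            inherits(moving_mask, "binary_mask"))
  if (!any(fixed_mask$voxels)) stop("fixed mask is empty")
  if (!any(moving_mask$voxels)) stop("moving mask is empty")
  d <- dim(fixed_mask$voxels)
  n <- prod(d)

  # rigid pre-alignment: constant displacement taking fixed-grid points into
  # the moving mask's frame so that the centroids coincide
  shift <- mask_centroid_mm(moving_mask) - mask_centroid_mm(fixed_mask)
  disp <- matrix(rep(shift, each = n), ncol = 3)

  warp_mask <- function(dd) {
    v <- warp_to_fixed(moving_mask$voxels, moving_mask, fixed_mask, dd,
                       nearest = TRUE)
    binary_mask(array(v != 0, d), spacing = fixed_mask$spacing,
                origin = fixed_mask$origin)
  }
  dice_pre <- dice(warp_mask(disp), fixed_mask)

  # smoothed mask images drive the demons forces
  Fimg <- gauss_smooth_cpp(as.numeric(fixed_mask$voxels), d,
                           rep(config$sigma_image, 3))
  Mimg <- gauss_smooth_cpp(as.numeric(moving_mask$voxels),
                           dim(moving_mask$voxels),
                           rep(config$sigma_image, 3))
  gF <- field_gradient(array(Fimg, d), fixed_mask$spacing)
  g2 <- gF[, 1]^2 + gF[, 2]^2 + gF[, 3]^2

  best <- list(disp = disp, dice = dice_pre)
  dd <- disp
  iterations <- if (dice_pre >= 1 - config$dice_tol) 0L else config$iterations
  for (it in seq_len(iterations)) {
    Mw <- warp_to_fixed(Mimg, moving_mask, fixed_mask, dd, nearest = FALSE)
    diff <- Mw - Fimg
    denom <- g2 + diff^2
    scale <- ifelse(denom > 1e-9, diff / denom, 0)
    v <- -gF * scale
    vn <- sqrt(v[, 1]^2 + v[, 2]^2 + v[, 3]^2)
    cap <- ifelse(vn > config$max_step, config$max_step / vn, 1)
    v <- v * cap
    v <- smooth_field(v, d, config$sigma_fluid)
    dd <- smooth_field(dd + v, d, config$sigma_diff)
    if (it %% 10 == 0 || it == config$iterations) {
      dc <- dice(warp_mask(dd), fixed_mask)
      if (dc > best$dice) best <- list(disp = dd, dice = dc)
      if (dc >= 1 - config$dice_tol) break
    }
  }

  field <- structure(list(displacement = best$disp, dim = d,
                          spacing = fixed_mask$spacing,
                          origin = fixed_mask$origin,
                          moving_spacing = moving_mask$spacing,
                          moving_origin = moving_mask$origin,
                          dice_pre = dice_pre, dice_post = best$dice),
                     class = "deformation_field")
  field$min_jacobian <- min(jacobian_determinant(field))
  if (field$dice_post < dice_pre)
    stop(sprintf("registration diverged: Dice %.4f after vs %.4f before",
                 field$dice_post, dice_pre))
  if (field$min_jacobian <= 0)
    stop(sprintf("deformation folds (min Jacobian determinant %.4f <= 0)",
                 field$min_jacobian))
  field
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field> %s grid, Dice %.4f -> %.4f, min |J| %.3f\n",
              paste(x$dim, collapse = "x"), x$dice_pre, x$dice_post,
              x$min_jacobian))
  invisible(x)
}

# Central-difference gradient of a 3D array, physical units (per mm).
# One-sided at the borders. Returns an n x 3 matrix.
field_gradient <- function(arr, spacing) {
  d <- dim(arr)
  g <- matrix(0, prod(d), 3)
  for (ax in 1:3) {
    hi <- arr; lo <- arr
    idx_hi <- pmin(seq_len(d[ax]) + 1L, d[ax])
    idx_lo <- pmax(seq_len(d[ax]) - 1L, 1L)
    if (ax == 1) { hi <- arr[idx_hi, , , drop = FALSE]; lo <- arr[idx_lo, , , drop = FALSE] }
    if (ax == 2) { hi <- arr[, idx_hi, , drop = FALSE]; lo <- arr[, idx_lo, , drop = FALSE] }
    if (ax == 3) { hi <- arr[, , idx_hi, drop = FALSE]; lo <- arr[, , idx_lo, drop = FALSE] }
    step <- ifelse(seq_len(d[ax]) == 1L | seq_len(d[ax]) == d[ax], 1, 2)
    denom <- array(0, d)
    if (ax == 1) denom[] <- step * spacing[1]
    if (ax == 2) denom <- aperm(array(step * spacing[2], d[c(2, 1, 3)]), c(2, 1, 3))
    if (ax == 3) denom <- aperm(array(step * spacing[3], d[c(3, 1, 2)]), c(2, 3, 1))
    g[, ax] <- (hi - lo) / denom
  }
  g
}

#' Jacobian determinant of a deformation field
#'
#' Determinant of the Jacobian of the mapping `x -> x + u(x)` at every voxel
#' (central differences; one-sided at borders). Positive everywhere for a
#' topology-preserving (diffeomorphic) field.
#'
#' @param field a `deformation_field`.
#' @return Numeric array of determinants on the fixed grid.
#' @export
jacobian_determinant <- function(field) {
  d <- field$dim
  J <- vector("list", 3)
  for (c in 1:3)
    J[[c]] <- field_gradient(array(field$displacement[, c], d), field$spacing)
  # rows of the Jacobian of u; full Jacobian is I + du
  a11 <- 1 + J[[1]][, 1]; a12 <- J[[1]][, 2]; a13 <- J[[1]][, 3]
  a21 <- J[[2]][, 1]; a22 <- 1 + J[[2]][, 2]; a23 <- J[[2]][, 3]
  a31 <- J[[3]][, 1]; a32 <- J[[3]][, 2]; a33 <- 1 + J[[3]][, 3]
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  array(det, d)
}

#' Resample an image or mask through a deformation field
#'
#' Pulls the moving image onto the fixed (CT) grid through the registered
#' deformation. Interpolation is `"linear"` for intensity images and must be
#' `"nearest"` for masks and label maps — labels are categorical, and a
#' request to interpolate a mask linearly is rejected.
#'
#' @param field a `deformation_field` from [register_masks()].
#' @param image an [image_volume] or [binary_mask] on the moving grid.
#' @param interpolation `"nearest"` or `"linear"`.
#' @param fill value for samples outside the moving grid.
#' @return The resampled [image_volume] or [binary_mask] on the fixed grid.
#' @export
apply_transform <- function(field, image,
                            interpolation = c("linear", "nearest"),
                            fill = 0) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(image, "binary_mask")
  if (is_mask && interpolation == "linear")
    stop("masks and label maps must use nearest interpolation (labels are categorical)")
  fixed_geom <- list(voxels = array(0, field$dim), spacing = field$spacing,
                     origin = field$origin)
  v <- warp_to_fixed(image$voxels, image, fixed_geom, field$displacement,
                     nearest = (interpolation == "nearest"), fill = fill)
  if (is_mask)
    binary_mask(array(v != 0, field$dim), spacing = field$spacing,
                origin = field$origin)
  else
    image_volume(array(v, field$dim), spacing = field$spacing,
                 origin = field$origin, modality = image$modality)
}

#' Persist a deformation field as 4D NIfTI (3 components, mm)
#'
#' @param field a `deformation_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deformation_field <- function(field, path) {
  arr <- array(field$displacement, c(field$dim, 3))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
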