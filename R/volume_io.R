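#' In-memory 3D image volume
#'
#' Container for a 3D scalar lattice with its physical geometry: per-axis
#' voxel spacing (mm), the physical coordinate of voxel (1,1,1) (mm), and an
#' axis-direction matrix. CT volumes carry Hounsfield units; MRI volumes carry
#' arbitrary signal intensity. Only axis-aligned orientations are supported.
#'
#' @param voxels numeric 3D array.
#' @param spacing numeric length-3, voxel size in mm; strictly positive.
#' @param origin numeric length-3, physical position of the first voxel (mm).
#' @param orientation 3x3 axis-direction matrix (default identity).
#' @param modality `"CT"` or `"MRI"` (informational).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = diag(3), modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("expected 3D volume, got ", length(dim(voxels)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  n_bad <- sum(!is.finite(voxels))
  if (n_bad > 0)
    stop("volume contains ", n_bad, " non-finite voxel(s)")
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         orientation = orientation, modality = modality),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels  spacing %s mm\n",
              x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Binary mask sharing the geometry of a reference volume
#'
#' Masks are stored as logical arrays with the same shape, spacing and origin
#' as the volume they annotate. No implicit resampling ever happens: a mask
#' that does not match its reference geometry is rejected (resampling is the
#' job of the registration module).
#'
#' @param voxels logical (or 0/1 numeric) 3D array.
#' @param reference an `image_volume` supplying the geometry, or `NULL` with
#'   explicit `spacing`/`origin`.
#' @param spacing,origin geometry, used when `reference` is `NULL`.
#' @param require_nonempty error if the mask has no foreground voxel
#'   (tumor masks must be non-empty).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, reference = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), require_nonempty = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("expected 3D mask, got ", length(dim(voxels)), " dimensions")
  v <- voxels
  if (!is.logical(v)) {
    if (any(!v %in% c(0, 1)))
      stop("mask voxels must be 0/1 or logical")
    v <- array(v != 0, dim = dim(v))
  }
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "image_volume"))
    if (!identical(dim(v), dim(reference$voxels)))
      stop("mask shape does not match reference volume")
    spacing <- reference$spacing
    origin <- reference$origin
  }
  if (require_nonempty && !any(v))
    stop("mask has no foreground voxels")
  structure(list(voxels = v, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d foreground (%.1f mm^3)\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              physical_volume(x)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$voxels)

# Geometry equality within tolerance (1e-6 mm on spacing/origin).
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_geometry <- function(a, b, what = "mask") {
  if (!same_geometry(a, b))
    stop(what, " geometry does not match its reference volume")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Loads a 3D NIfTI-1 file. CT values are passed through unmodified (HU
#' calibration is assumed from the source). Geometry (spacing, origin) is
#' taken from the header xform. Non-finite voxels are a hard error.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param expected_modality `"CT"` or `"MRI"`.
#' @return An [image_volume].
#' @export
load_volume <- function(path, expected_modality = c("CT", "MRI")) {
  expected_modality <- match.arg(expected_modality)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), " dimensions in ", path)
  xf <- RNifti::xform(img)
  arr <- array(as.numeric(img), dim = d)
  image_volume(arr,
               spacing = RNifti::pixdim(img)[1:3],
               origin = xf[1:3, 4],
               orientation = sign(xf[1:3, 1:3] + diag(3) * 1e-12),
               modality = expected_modality)
}

#' Read a binary mask from NIfTI
#'
#' @param path path to a 0/1 integer NIfTI file.
#' @param reference optional [image_volume] whose geometry the mask must match.
#' @param require_nonempty error on empty masks (default TRUE: tumor masks).
#' @return A [binary_mask].
#' @export
load_mask <- function(path, reference = NULL, require_nonempty = TRUE) {
  vol <- load_volume(path, "CT")
  m <- binary_mask(vol$voxels != 0, spacing = vol$spacing, origin = vol$origin,
                   require_nonempty = require_nonempty)
  if (!is.null(reference)) check_geometry(m, reference)
  m
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as 0/1 integers; volumes as floating point. Spacing and
#' origin go into an axis-aligned sform.
#'
#' @param x an [image_volume] or [binary_mask].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "binary_mask")) array(as.integer(x$voxels), dim(x$voxels))
         else x$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  m <- diag(c(x$spacing, 1))
  m[1:3, 4] <- x$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Physical volume of a mask
#'
#' Foreground voxel count times the voxel volume (product of spacings).
#'
#' @param mask a [binary_mask].
#' @return Volume in mm^3. An empty mask returns 0 with a warning.
#' @export
physical_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  n <- sum(mask$voxels)
  if (n == 0) warning("empty mask: physical volume is 0")
  n * prod(mask$spacing)
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)` by voxel counting; masks must share geometry.
#'
#' @param a,b [binary_mask] objects on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("masks must share a grid for Dice")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) return(1)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Per-lesion clinical record
#'
#' Manual annotations that are inputs to the pipeline, never inferred:
#' entity, growth type (well-delineated vs infiltrative), TACE approach and
#' baseline diameter. Lesions under 1 cm are excluded from analysis.
#'
#' @param lesion_id identifier string.
#' @param entity one of `"HCC"`, `"ICC"`, `"metastasis"`.
#' @param growth_type `"well_delineated"` or `"infiltrative"`.
#' @param tace_approach `"selective"` or `"lobar"`.
#' @param diameter_cm positive lesion diameter in cm.
#' @return An object of class `lesion_record`.
#' @export
lesion_record <- function(lesion_id, entity = c("HCC", "ICC", "metastasis"),
                          growth_type = c("well_delineated", "infiltrative"),
                          tace_approach = c("selective", "lobar"),
                          diameter_cm) {
  entity <- match.arg(entity)
  growth_type <- match.arg(growth_type)
  tace_approach <- match.arg(tace_approach)
  stopifnot(is.numeric(diameter_cm), diameter_cm > 0)
  structure(list(lesion_id = as.character(lesion_id), entity = entity,
                 growth_type = growth_type, tace_approach = tace_approach,
                 diameter_cm = diameter_cm,
                 eligible = diameter_cm >= 1.0),
            class = "lesion_record")
}
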