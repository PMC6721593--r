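#' Construct an image volume
#'
#' A 3-D scalar grid with physical geometry. World coordinates follow one
#' fixed convention throughout the package: 0-based voxel indices, voxel
#' *center* addressing, so the center of voxel `(i, j, k)` sits at
#' `origin_mm + c(i, j, k) * spacing_mm`. Axis 1 is left-right, so the
#' sagittal midline is a plane of constant axis-1 world coordinate.
#'
#' @param values numeric 3-D array of voxel values.
#' @param spacing_mm positive numeric vector of length 3, voxel size per axis
#'   in millimetres.
#' @param origin_mm numeric vector of length 3, world position (mm) of the
#'   center of voxel (0, 0, 0).
#' @param unit declared voxel unit: `"HU"` for CT attenuation, `"SUV"` or
#'   `"Bq/mL"` for PET, `"mask"` for binary volumes stored as 0/1.
#' @return An object of class `image_volume`: a list with fields `values`,
#'   `spacing_mm`, `origin_mm`, `unit`.
#' @examples
#' vol <- image_volume(array(-100, dim = c(4, 4, 2)), c(1, 1, 5), unit = "HU")
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                         unit = c("HU", "SUV", "Bq/mL", "mask")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array, got ",
         paste(dim(values), collapse = "x"), call. = FALSE)
  if (any(dim(values) < 1L)) stop("grid must be nonempty", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive values", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite values", call. = FALSE)
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm, unit = unit),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s grid, spacing %s mm, unit %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"), x$unit))
  cat(sprintf("  origin (%s) mm, value range [%.3g, %.3g]\n",
              paste(format(x$origin_mm), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' World coordinates of voxel centers along one axis
#'
#' @param vol an [image_volume()].
#' @param axis axis index (1, 2 or 3).
#' @return Numeric vector of voxel-center world coordinates (mm).
#' @keywords internal
axis_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin_mm[axis] + (seq_len(n) - 1) * vol$spacing_mm[axis]
}

# checks that a logical mask shares the grid of its reference volume
check_mask <- function(vol, mask) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(mask), dim(vol$values)))
    stop("mask and volume grids differ: ",
         paste(dim(mask), collapse = "x"), " vs ",
         paste(dim(vol$values), collapse = "x"), call. = FALSE)
  mask
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write an image volume to NIfTI-1
#'
#' The grid is written as NIfTI-1 (gzipped when `path` ends in `.nii.gz`,
#' plain otherwise) with the voxel spacing in `pixdim`. The unit and world
#' origin, which NIfTI-1 has no portable slot for under this package's
#' voxel-center convention, go to a JSON sidecar next to the file (same
#' basename, `.json` extension).
#'
#' @param vol an [image_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("`path` must end in .nii or .nii.gz", call. = FALSE)
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(unit = vol$unit, origin_mm = vol$origin_mm,
         spacing_mm = vol$spacing_mm),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image volume from NIfTI-1
#'
#' Reads the grid and spacing from the NIfTI header and the unit/origin from
#' the JSON sidecar written by [write_volume()]. Without a sidecar, `unit`
#' must be supplied and the origin defaults to zero.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param unit fallback unit when no sidecar is present.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  attributes(values) <- list(dim = dim(values))  # drop NIfTI metadata attrs
  if (length(dim(values)) != 3L)
    stop("expected a 3-D image, got ", length(dim(values)), "-D",
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  origin <- c(0, 0, 0)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    unit <- meta$unit
    if (!is.null(meta$origin_mm)) origin <- as.numeric(meta$origin_mm)
  } else if (is.null(unit)) {
    stop("no sidecar found for ", path, " and no `unit` supplied",
         call. = FALSE)
  }
  image_volume(values, spacing, origin, unit = unit)
}

#' Convert a PET activity concentration map to SUV
#'
#' Body-weight standardized uptake value:
#' `SUV = activity[Bq/mL] * weight[kg] * 1000 / (dose[MBq] * 1e6)`,
#' i.e. tracer concentration normalized by injected dose per gram of body
#' weight (1 kg = 1000 g, 1 MBq = 1e6 Bq). Decay correction is assumed to be
#' already applied to the activity map.
#'
#' @param activity an [image_volume()] with unit `"Bq/mL"`.
#' @param body_weight_kg patient body weight, kg (> 0).
#' @param injected_dose_MBq injected tracer dose, MBq (> 0).
#' @return An [image_volume()] in SUV on the same grid.
#' @examples
#' act <- image_volume(array(5000, dim = c(2, 2, 2)), c(1, 1, 1),
#'                     unit = "Bq/mL")
#' suv <- to_suv(act, body_weight_kg = 60, injected_dose_MBq = 244.2)
#' suv$values[1]  # ~1.228
#' @export
to_suv <- function(activity, body_weight_kg, injected_dose_MBq) {
  stopifnot(inherits(activity, "image_volume"))
  if (activity$unit != "Bq/mL")
    stop("input unit must be Bq/mL, got ", activity$unit, call. = FALSE)
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body_weight_kg must be > 0", call. = FALSE)
  if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 0)
    stop("injected_dose_MBq must be > 0", call. = FALSE)
  suv <- activity$values * body_weight_kg * 1000 / (injected_dose_MBq * 1e6)
  image_volume(suv, activity$spacing_mm, activity$origin_mm, unit = "SUV")
}
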