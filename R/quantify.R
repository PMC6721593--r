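#' Axis-aligned spheroid volume of interest
#'
#' A spheroid (axis-aligned ellipsoid) in world millimetres. A point `p`
#' belongs to the VOI when `sum(((p - center) / semi_axes)^2) <= 1`.
#'
#' @param center_mm world coordinates of the center (length 3, mm).
#' @param semi_axes_mm strictly positive semi-axes per axis (length 3, mm).
#' @return An object of class `spheroid_voi`.
#' @export
spheroid_voi <- function(center_mm, semi_axes_mm) {
  center_mm <- as.numeric(center_mm)
  semi_axes_mm <- as.numeric(semi_axes_mm)
  if (length(center_mm) != 3L || any(!is.finite(center_mm)))
    stop("`center_mm` must be 3 finite values", call. = FALSE)
  if (length(semi_axes_mm) != 3L || any(!is.finite(semi_axes_mm)) ||
      any(semi_axes_mm <= 0))
    stop("`semi_axes_mm` must be 3 strictly positive values", call. = FALSE)
  structure(list(center_mm = center_mm, semi_axes_mm = semi_axes_mm),
            class = "spheroid_voi")
}

#' @export
print.spheroid_voi <- function(x, ...) {
  cat(sprintf("<spheroid_voi> center (%s) mm, semi-axes (%s) mm\n",
              paste(format(x$center_mm, digits = 5), collapse = ", "),
              paste(format(x$semi_axes_mm, digits = 5), collapse = ", ")))
  invisible(x)
}

#' Voxels whose centers fall inside a VOI
#'
#' @param vol an [image_volume()] supplying the grid geometry.
#' @param voi a [spheroid_voi()].
#' @return Logical array on the volume's grid.
#' @export
voi_membership <- function(vol, voi) {
  stopifnot(inherits(vol, "image_volume"), inherits(voi, "spheroid_voi"))
  d2 <- lapply(1:3, function(a) {
    ((axis_coords(vol, a) - voi$center_mm[a]) / voi$semi_axes_mm[a])^2
  })
  dims <- dim(vol$values)
  # separable quadratic form: outer-sum the per-axis terms
  m <- outer(outer(d2[[1]], d2[[2]], "+"), d2[[3]], "+") <= 1
  dim(m) <- dims
  m
}

# voxel-center world coordinates (n x 3 matrix) of TRUE voxels in a mask
mask_centers <- function(vol, mask) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, vol$spacing_mm, "*"), 2, vol$origin_mm, "+")
}

#' Tumor-anchored spheroid VOI
#'
#' Builds the measurement VOI around a segmented lesion: the tumor mask is
#' dilated by a ball of radius `margin_mm` (so the VOI takes in the breast
#' tissue within `margin_mm` of the tumor margin, default 10 mm = 1 cm), and
#' the minimal axis-aligned spheroid containing every dilated voxel center is
#' returned. Construction: center at the dilated bounding-box center,
#' semi-axes initialized at the half-extents (floored at half a voxel per
#' axis), then inflated by the smallest common factor `s >= 1` such that all
#' dilated voxel centers satisfy the membership inequality.
#'
#' @param vol an [image_volume()] supplying the grid geometry (typically the
#'   CT volume).
#' @param tumor_mask logical array on `vol`'s grid; must be nonempty.
#' @param margin_mm dilation radius in mm (default 10).
#' @return A [spheroid_voi()] containing all dilated tumor voxel centers.
#' @export
tumor_voi <- function(vol, tumor_mask, margin_mm = 10) {
  stopifnot(inherits(vol, "image_volume"))
  tumor_mask <- check_mask(vol, tumor_mask)
  if (!any(tumor_mask)) stop("tumor mask is empty", call. = FALSE)
  if (margin_mm < 0) stop("margin_mm must be >= 0", call. = FALSE)
  dil <- dilate_mask(vol, tumor_mask, margin_mm)
  pts <- mask_centers(vol, dil)
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  center <- (lo + hi) / 2
  half <- pmax((hi - lo) / 2, vol$spacing_mm / 2)
  q <- sweep(sweep(pts, 2, center, "-"), 2, half, "/")
  s <- max(1, sqrt(max(rowSums(q^2))))
  spheroid_voi(center, s * half)
}

# dilate a voxel mask by a euclidean ball of radius margin_mm (world mm);
# returns a logical array restricted to the grid
dilate_mask <- function(vol, mask, margin_mm) {
  if (margin_mm == 0) return(mask)
  dims <- dim(vol$values)
  idx <- which(mask, arr.ind = TRUE)
  pad <- ceiling(margin_mm / vol$spacing_mm)
  lo <- pmax(apply(idx, 2, min) - pad, 1)
  hi <- pmin(apply(idx, 2, max) + pad, dims)
  cand_idx <- as.matrix(expand.grid(lapply(1:3, function(a) lo[a]:hi[a])))
  cand <- sweep(sweep(cand_idx - 1, 2, vol$spacing_mm, "*"), 2,
                vol$origin_mm, "+")
  src <- sweep(sweep(idx - 1, 2, vol$spacing_mm, "*"), 2, vol$origin_mm, "+")
  m2 <- margin_mm^2
  hit <- logical(nrow(cand))
  # chunked min-distance scan keeps the distance matrix small
  chunk <- max(1L, floor(2e6 / nrow(src)))
  for (start in seq(1L, nrow(cand), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(cand))
    d2 <- outer(rowSums(cand[rows, , drop = FALSE]^2), rowSums(src^2), "+") -
      2 * tcrossprod(cand[rows, , drop = FALSE], src)
    hit[rows] <- matrixStats_rowMins(d2) <= m2 + 1e-9
  }
  out <- array(FALSE, dims)
  out[cand_idx[hit, , drop = FALSE]] <- TRUE
  out
}

# rowMins without matrixStats
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Mirror a VOI across the sagittal midline
#'
#' Places the contralateral VOI of the same size: the axis-1 (left-right)
#' coordinate of the center is reflected about `midline_x_mm`
#' (`x' = 2 * midline - x`); the remaining coordinates and all semi-axes are
#' unchanged, so the mirrored VOI lands in the same quadrant of the
#' contralateral breast on an aligned grid.
#'
#' @param voi a [spheroid_voi()].
#' @param midline_x_mm world axis-1 coordinate of the sagittal midplane.
#' @return A [spheroid_voi()] of identical size.
#' @export
mirror_voi <- function(voi, midline_x_mm) {
  stopifnot(inherits(voi, "spheroid_voi"))
  center <- voi$center_mm
  center[1] <- 2 * midline_x_mm - center[1]
  spheroid_voi(center, voi$semi_axes_mm)
}

#' Adipose tissue mask within a VOI
#'
#' Selects the voxels whose centers lie inside the VOI and whose CT
#' attenuation falls in the fat window (both endpoints inclusive; default
#' -200 to -50 HU, the standard adipose window).
#'
#' @param ct an [image_volume()] with unit `"HU"`.
#' @param voi a [spheroid_voi()].
#' @param hu_lo,hu_hi fat window bounds in HU.
#' @return Logical array on the CT grid.
#' @export
adipose_mask <- function(ct, voi, hu_lo = -200, hu_hi = -50) {
  stopifnot(inherits(ct, "image_volume"))
  if (ct$unit != "HU")
    stop("adipose masking requires a CT volume in HU, got ", ct$unit,
         call. = FALSE)
  inside <- voi_membership(ct, voi)
  if (!any(inside))
    stop("VOI contains no voxel centers (outside grid?)", call. = FALSE)
  inside & ct$values >= hu_lo & ct$values <= hu_hi
}

#' Mean CT attenuation over a mask
#'
#' Arithmetic mean of the HU values over the masked voxels. Mirroring the
#' study's exclusion of patients with insufficient breast adipose tissue,
#' fewer than `min_voxels` masked voxels raises an error of class
#' `adipoct_insufficient_adipose`.
#'
#' @param ct an [image_volume()] with unit `"HU"`.
#' @param mask logical array on the CT grid.
#' @param min_voxels minimum masked voxel count (default 10).
#' @return Mean attenuation in HU.
#' @export
mean_attenuation <- function(ct, mask, min_voxels = 10) {
  stopifnot(inherits(ct, "image_volume"))
  mask <- check_mask(ct, mask)
  n <- sum(mask)
  if (n < min_voxels) {
    stop(structure(class = c("adipoct_insufficient_adipose", "error",
                             "condition"),
                   list(message = sprintf(
                     "insufficient adipose tissue: %d voxels < min_voxels = %d",
                     n, min_voxels), call = NULL)))
  }
  mean(ct$values[mask])
}

#' Breast adipose tissue attenuation parameters
#'
#' The four adipose parameters from the tumor-adjacent (TAT HU) and
#' contralateral (CAT HU) mean attenuations:
#' `HU difference = TAT HU - CAT HU` and
#' `HU difference % = (CAT HU - TAT HU) / CAT HU * 100`.
#' Because fat attenuation is negative, the percent difference carries the
#' same sign as the difference.
#'
#' @param tat_hu mean attenuation of tumor-adjacent breast adipose tissue, HU.
#' @param cat_hu mean attenuation of contralateral breast adipose tissue, HU
#'   (nonzero).
#' @return A one-row data.frame: `tat_hu`, `cat_hu`, `hu_difference`,
#'   `hu_difference_pct`.
#' @examples
#' adipose_parameters(-92.463, -108.743)
#' @export
adipose_parameters <- function(tat_hu, cat_hu) {
  if (!is.finite(tat_hu) || !is.finite(cat_hu))
    stop("attenuations must be finite", call. = FALSE)
  if (cat_hu == 0)
    stop("cat_hu = 0: not a fat attenuation value", call. = FALSE)
  data.frame(tat_hu = tat_hu, cat_hu = cat_hu,
             hu_difference = tat_hu - cat_hu,
             hu_difference_pct = (cat_hu - tat_hu) / cat_hu * 100)
}

#' Maximum SUV within a VOI
#'
#' @param pet an [image_volume()] with unit `"SUV"`.
#' @param voi a [spheroid_voi()] intersecting the grid.
#' @return Maximum voxel SUV inside the VOI.
#' @export
suv_max <- function(pet, voi) {
  stopifnot(inherits(pet, "image_volume"))
  if (pet$unit != "SUV")
    stop("suv_max requires a PET volume in SUV, got ", pet$unit,
         call. = FALSE)
  inside <- voi_membership(pet, voi)
  if (!any(inside))
    stop("VOI contains no voxel centers (outside grid?)", call. = FALSE)
  max(pet$values[inside])
}

#' Metabolic tumor volume within a VOI
#'
#' Total volume of VOI voxels with SUV at or above the threshold (inclusive;
#' default 2.50). Returns 0 when no voxel qualifies, so lesions whose SUVmax
#' falls below the threshold get MTV = 0.0 cm^3.
#'
#' @param pet an [image_volume()] with unit `"SUV"`.
#' @param voi a [spheroid_voi()].
#' @param suv_threshold inclusive SUV threshold (default 2.50).
#' @return Volume in cm^3.
#' @export
metabolic_tumor_volume <- function(pet, voi, suv_threshold = 2.50) {
  stopifnot(inherits(pet, "image_volume"))
  if (pet$unit != "SUV")
    stop("MTV requires a PET volume in SUV, got ", pet$unit, call. = FALSE)
  inside <- voi_membership(pet, voi)
  n <- sum(pet$values[inside] >= suv_threshold)
  n * prod(pet$spacing_mm) / 1000
}

#' Measure one PET/CT case
#'
#' Runs the full imaging measurement chain on aligned CT, PET and tumor-mask
#' volumes: tumor VOI construction, contralateral mirroring, fat-window
#' masking and mean attenuation on both sides, the four adipose parameters,
#' and SUVmax / MTV of the lesion within the tumor VOI.
#'
#' @param ct CT [image_volume()] in HU.
#' @param pet PET [image_volume()] in SUV, on the same grid as `ct`.
#' @param tumor_mask logical array on the shared grid; nonempty.
#' @param midline_x_mm world axis-1 coordinate of the sagittal midplane.
#' @param margin_mm VOI margin beyond the tumor surface, mm (default 10).
#' @param hu_window fat window, HU (default `c(-200, -50)`).
#' @param suv_threshold MTV threshold (default 2.50).
#' @param min_voxels minimum adipose voxel count per side (default 10).
#' @return One-row data.frame: `tat_hu`, `cat_hu`, `hu_difference`,
#'   `hu_difference_pct`, `suv_max`, `mtv_cm3`, `n_fat_voxels_tumor_side`,
#'   `n_fat_voxels_contralateral`.
#' @export
measure_volumes <- function(ct, pet, tumor_mask, midline_x_mm,
                            margin_mm = 10, hu_window = c(-200, -50),
                            suv_threshold = 2.50, min_voxels = 10) {
  stopifnot(inherits(ct, "image_volume"), inherits(pet, "image_volume"))
  if (!identical(dim(ct$values), dim(pet$values)) ||
      !isTRUE(all.equal(ct$spacing_mm, pet$spacing_mm)) ||
      !isTRUE(all.equal(ct$origin_mm, pet$origin_mm)))
    stop("CT and PET grids are not aligned", call. = FALSE)
  voi_t <- tumor_voi(ct, tumor_mask, margin_mm)
  voi_c <- mirror_voi(voi_t, midline_x_mm)
  side_mean <- function(voi, side) {
    m <- adipose_mask(ct, voi, hu_window[1], hu_window[2])
    hu <- tryCatch(mean_attenuation(ct, m, min_voxels),
      adipoct_insufficient_adipose = function(e) {
        stop(structure(class = c("adipoct_insufficient_adipose", "error",
                                 "condition"),
                       list(message = paste0(side, " side: ",
                                             conditionMessage(e)),
                            call = NULL)))
      })
    list(hu = hu, n = sum(m))
  }
  tat <- side_mean(voi_t, "tumor-adjacent")
  cat_ <- side_mean(voi_c, "contralateral")
  out <- adipose_parameters(tat$hu, cat_$hu)
  out$suv_max <- suv_max(pet, voi_t)
  out$mtv_cm3 <- metabolic_tumor_volume(pet, voi_t, suv_threshold)
  out$n_fat_voxels_tumor_side <- tat$n
  out$n_fat_voxels_contralateral <- cat_$n
  out
}

#' @rdname measure_volumes
#' @param case a `phantom_case` from [make_breast_phantom()].
#' @param ... passed on to [measure_volumes()].
#' @export
measure_case <- function(case, ...) {
  stopifnot(inherits(case, "phantom_case"))
  measure_volumes(case$ct, case$pet, case$tumor_mask, case$midline_x_mm, ...)
}
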