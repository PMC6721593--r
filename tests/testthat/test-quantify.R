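make_grid <- function(dims = c(40, 40, 40), spacing = c(1, 1, 1),
                      fill = 0, unit = "HU") {
  image_volume(array(fill, dims), spacing, unit = unit)
}

test_that("tumor VOI of a spherical mask is the margin-dilated sphere", {
  vol <- make_grid()
  ctr <- c(20, 20, 20)  # world mm, on a voxel center
  idx <- which(array(TRUE, dim(vol$values)), arr.ind = TRUE)
  d2 <- colSums((t(idx - 1) - ctr)^2)
  mask <- array(d2 <= 25, dim(vol$values))
  voi <- tumor_voi(vol, mask, margin_mm = 10)
  expect_equal(voi$center_mm, ctr)
  expect_true(all(abs(voi$semi_axes_mm - 15) <= 0.5))
  # containment: all dilated voxel centers are inside
  dil <- naive_dilate(vol, mask, 10)
  pts <- which(dil, arr.ind = TRUE) - 1
  q <- sweep(sweep(pts, 2, voi$center_mm, "-"), 2, voi$semi_axes_mm, "/")
  expect_true(all(rowSums(q^2) <= 1 + 1e-9))
})

test_that("cubic mask inflation factor matches the brute-force oracle", {
  vol <- make_grid(c(36, 36, 36))
  idx <- which(array(TRUE, dim(vol$values)), arr.ind = TRUE)
  ctr <- c(17, 17, 17)
  inf_norm <- apply(abs(t(t(idx - 1) - ctr)), 1, max)
  mask <- array(inf_norm <= 5, dim(vol$values))
  voi <- tumor_voi(vol, mask, margin_mm = 10)
  dil <- naive_dilate(vol, mask, 10)
  pts <- which(dil, arr.ind = TRUE) - 1
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  H <- (hi - lo) / 2
  q <- sweep(sweep(pts, 2, (lo + hi) / 2, "-"), 2, H, "/")
  s_oracle <- max(1, sqrt(max(rowSums(q^2))))
  expect_equal(voi$semi_axes_mm, s_oracle * H, tolerance = 1e-9,
               ignore_attr = TRUE)
  # continuum limit: corners force inflation toward sqrt(3)
  expect_gt(s_oracle, 1.2)
  expect_lt(s_oracle, sqrt(3) + 0.1)
})

test_that("degenerate one-voxel mask with zero margin floors the semi-axes", {
  vol <- make_grid(c(10, 10, 10), spacing = c(1, 1, 5))
  mask <- array(FALSE, dim(vol$values)); mask[5, 5, 5] <- TRUE
  voi <- tumor_voi(vol, mask, margin_mm = 0)
  expect_equal(voi$semi_axes_mm, c(0.5, 0.5, 2.5))
  expect_error(tumor_voi(vol, array(FALSE, dim(vol$values))), "empty")
})

test_that("random blob VOIs contain every dilated voxel center", {
  set.seed(42)
  vol <- make_grid(c(30, 30, 18), spacing = c(1, 1, 2))
  idx <- which(array(TRUE, dim(vol$values)), arr.ind = TRUE)
  centers <- t(t(idx - 1) * vol$spacing_mm)
  for (i in 1:5) {
    c1 <- runif(3, 10, 20); c2 <- c1 + runif(3, -4, 4)
    r1 <- runif(1, 2, 5); r2 <- runif(1, 2, 5)
    mask <- array(colSums((t(centers) - c1)^2) <= r1^2 |
                    colSums((t(centers) - c2)^2) <= r2^2, dim(vol$values))
    margin <- runif(1, 0, 6)
    voi <- tumor_voi(vol, mask, margin)
    dil <- naive_dilate(vol, mask, margin)
    pts <- t(t(which(dil, arr.ind = TRUE) - 1) * vol$spacing_mm)
    q <- sweep(sweep(pts, 2, voi$center_mm, "-"), 2, voi$semi_axes_mm, "/")
    expect_true(all(rowSums(q^2) <= 1 + 1e-9))
  }
})

test_that("mirroring reflects the center and preserves size", {
  v <- spheroid_voi(c(30, 40, 50), c(20, 15, 10))
  m <- mirror_voi(v, midline_x_mm = 0)
  expect_equal(m$center_mm, c(-30, 40, 50))
  expect_identical(m$semi_axes_mm, v$semi_axes_mm)
  expect_equal(mirror_voi(m, 0), v)
  m2 <- mirror_voi(v, midline_x_mm = 25)
  expect_equal(m2$center_mm[1], 20)
})

test_that("adipose mask applies the inclusive fat window inside the VOI", {
  vol <- make_grid(c(5, 3, 3))
  vol$values[, 2, 2] <- c(-100, -80, -60, -40, 0)
  voi <- spheroid_voi(c(2, 1, 1), c(10, 10, 10))  # covers the whole grid
  m <- adipose_mask(vol, voi)
  expect_equal(sum(m), 3)
  expect_setequal(vol$values[m], c(-100, -80, -60))
  expect_equal(mean_attenuation(vol, m, min_voxels = 3), -80)
  # boundary values are inside the window
  vol$values[, 2, 2] <- c(-200, -50, -200.01, -49.99, 0)
  expect_setequal(vol$values[adipose_mask(vol, voi)], c(-200, -50))
  # uniform fat volume: everything in the VOI is selected
  uni <- make_grid(c(6, 6, 6), fill = -100)
  voi2 <- spheroid_voi(c(2.5, 2.5, 2.5), c(2, 2, 2))
  expect_equal(sum(adipose_mask(uni, voi2)),
               sum(voi_membership(uni, voi2)))
  # VOI fully off-grid
  expect_error(adipose_mask(uni, spheroid_voi(c(100, 100, 100), c(2, 2, 2))),
               "no voxel centers")
  # wrong unit
  suv <- make_grid(fill = 1, unit = "SUV")
  expect_error(adipose_mask(suv, voi2), "HU")
})

test_that("insufficient adipose tissue raises the dedicated error", {
  vol <- make_grid(c(5, 3, 3))
  vol$values[1:5] <- -100
  mask <- vol$values == -100
  expect_error(mean_attenuation(vol, mask, min_voxels = 10),
               class = "adipoct_insufficient_adipose")
  expect_equal(mean_attenuation(vol, mask, min_voxels = 5), -100)
})

test_that("adipose parameter formulas match the worked example", {
  p <- adipose_parameters(-92.463, -108.743)
  expect_equal(p$hu_difference, 16.280, tolerance = 1e-9)
  expect_equal(p$hu_difference_pct, 14.971, tolerance = 5e-5)
  z <- adipose_parameters(-100, -100)
  expect_equal(z$hu_difference, 0)
  expect_equal(z$hu_difference_pct, 0)
  p2 <- adipose_parameters(-90, -100)
  expect_equal(p2$hu_difference, 10)
  expect_equal(p2$hu_difference_pct, 10)
  expect_error(adipose_parameters(-90, 0), "cat_hu")
  # sign agreement whenever CAT is negative
  set.seed(3)
  for (i in 1:20) {
    tat <- runif(1, -130, -60); cat_ <- runif(1, -130, -60)
    pp <- adipose_parameters(tat, cat_)
    expect_equal(sign(pp$hu_difference_pct), sign(pp$hu_difference))
  }
})

test_that("SUVmax reads the programmed peak", {
  sp <- small_phantom_spec(noise_sd_hu = 0, noise_sd_suv = 0, fat_hu_sd = 0)
  case <- make_breast_phantom(sp, seed = 1)
  voi <- tumor_voi(case$ct, case$tumor_mask)
  expect_equal(suv_max(case$pet, voi), 8.44)
  # uniform background
  uni <- make_grid(c(6, 6, 6), fill = 0.5, unit = "SUV")
  expect_equal(suv_max(uni, spheroid_voi(c(2.5, 2.5, 2.5), c(2, 2, 2))), 0.5)
  # noisy peak stays near the programmed value (order-statistic bound)
  spn <- small_phantom_spec(noise_sd_suv = 0.05)
  noisy <- make_breast_phantom(spn, seed = 2)
  expect_lt(abs(suv_max(noisy$pet, voi) - 8.44), 5 * 0.05)
  expect_error(suv_max(case$ct, voi), "SUV")
})

test_that("MTV counts threshold-inclusive voxels and scales by voxel volume", {
  # every VOI voxel exactly at threshold: full voxelized VOI volume
  uni <- make_grid(c(10, 10, 10), fill = 2.50, unit = "SUV")
  voi <- spheroid_voi(c(4.5, 4.5, 4.5), c(3, 3, 3))
  n_voi <- sum(voi_membership(uni, voi))
  expect_equal(metabolic_tumor_volume(uni, voi), n_voi / 1000)
  # monotone nonincreasing in the threshold; zero iff SUVmax below it
  set.seed(7)
  vals <- array(runif(1000, 0, 6), c(10, 10, 10))
  pet <- image_volume(vals, c(1, 1, 1), unit = "SUV")
  mtvs <- sapply(seq(0, 7, by = 0.5), function(th)
    metabolic_tumor_volume(pet, voi, th))
  expect_true(all(diff(mtvs) <= 0))
  smax <- suv_max(pet, voi)
  expect_gt(metabolic_tumor_volume(pet, voi, smax), 0)
  expect_equal(metabolic_tumor_volume(pet, voi, smax + 1e-9), 0)
})

test_that("sub-threshold lesions get MTV 0 and a 6.2 mm sphere ~0.998 cm3", {
  sp_low <- small_phantom_spec(tumor_suv_peak = 1.10, noise_sd_suv = 0)
  low <- make_breast_phantom(sp_low, seed = 1)
  voi <- tumor_voi(low$ct, low$tumor_mask)
  expect_lt(suv_max(low$pet, voi), 2.50)
  expect_equal(metabolic_tumor_volume(low$pet, voi), 0)
  sp_hot <- small_phantom_spec(tumor_suv_peak = 5, noise_sd_suv = 0)
  hot <- make_breast_phantom(sp_hot, seed = 1)
  mtv <- metabolic_tumor_volume(hot$pet, tumor_voi(hot$ct, hot$tumor_mask))
  expect_lt(abs(mtv - 0.998) / 0.998, 0.05)
})

test_that("measure_case runs the whole chain and labels side errors", {
  sp <- small_phantom_spec(fat_hu_mean = -100, fat_hu_sd = 0,
                           peritumoral_delta_hu = 0, noise_sd_hu = 0,
                           noise_sd_suv = 0)
  case <- make_breast_phantom(sp, seed = 1)
  m <- measure_case(case)
  expect_equal(m$hu_difference, 0)
  expect_equal(m$tat_hu, -100)
  expect_gte(m$n_fat_voxels_tumor_side, 10)
  # measured attenuations always stay inside the fat window
  noisy <- measure_case(make_breast_phantom(small_phantom_spec(), seed = 4))
  expect_true(noisy$tat_hu >= -200 && noisy$tat_hu <= -50)
  expect_true(noisy$cat_hu >= -200 && noisy$cat_hu <= -50)
  # removing the contralateral breast triggers a labeled exclusion
  gone <- case
  nx <- dim(gone$ct$values)[1]
  gone$ct$values[1:floor(nx / 2), , ] <- 0
  err <- tryCatch(measure_case(gone), error = function(e) e)
  expect_s3_class(err, "adipoct_insufficient_adipose")
  expect_match(conditionMessage(err), "contralateral")
  # misaligned grids are rejected
  bad_pet <- image_volume(case$pet$values, c(2, 2, 2), unit = "SUV")
  expect_error(measure_volumes(case$ct, bad_pet, case$tumor_mask,
                               case$midline_x_mm), "aligned")
})
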