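# run code under an explicit seed, leaving the caller's RNG state untouched
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of a synthetic breast PET/CT phantom
#'
#' Describes a simple two-breast geometry on a regular grid: two
#' mirror-symmetric fat ellipsoids about the sagittal midplane, a concentric
#' fibroglandular core in each, and a spherical tumor in one breast. Fat
#' voxels within `peritumoral_reach_mm` of the tumor surface carry a
#' programmed additive attenuation shift, emulating the elevated density of
#' cancer-associated adipose tissue. All lengths in mm, CT values in HU, PET
#' values in SUV.
#'
#' @param grid_shape voxels per axis (axis 1 = left-right).
#' @param spacing_mm voxel size per axis; default 1 x 1 x 5 mm (5 mm CT slice
#'   thickness).
#' @param breast_offset_mm distance of each breast center from the midline.
#' @param breast_semi_axes_mm semi-axes of the breast ellipsoids.
#' @param gland_scale fibroglandular core as a fraction of the breast
#'   semi-axes.
#' @param fat_hu_mean,fat_hu_sd fat attenuation mean (must lie in the
#'   -200..-50 HU fat window) and per-voxel heterogeneity.
#' @param gland_hu_mean,tumor_hu_mean,background_hu soft-tissue means, HU.
#' @param tumor_center_offset_mm tumor center relative to the tumor-side
#'   breast center.
#' @param tumor_radius_mm tumor sphere radius.
#' @param peritumoral_delta_hu additive HU shift applied to fat within
#'   `peritumoral_reach_mm` of the tumor surface.
#' @param peritumoral_reach_mm reach of the shift; must be >= 10 so the 1-cm
#'   measurement shell samples shifted fat. Default 12: the enclosing-spheroid
#'   VOI can bulge slightly past the 10 mm dilation on a discrete grid, and a
#'   12 mm reach keeps every fat voxel inside the VOI shifted.
#' @param tumor_suv_peak,background_suv PET uptake inside/outside the tumor.
#' @param noise_sd_hu,noise_sd_suv additive Gaussian acquisition noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(160, 100, 16),
                         spacing_mm = c(1, 1, 5),
                         breast_offset_mm = 40,
                         breast_semi_axes_mm = c(35, 35, 30),
                         gland_scale = 0.4,
                         fat_hu_mean = -100, fat_hu_sd = 4,
                         gland_hu_mean = 40, tumor_hu_mean = 30,
                         background_hu = 20,
                         tumor_center_offset_mm = c(15, 8, 0),
                         tumor_radius_mm = 10,
                         peritumoral_delta_hu = 9,
                         peritumoral_reach_mm = 12,
                         tumor_suv_peak = 8.44, background_suv = 0.5,
                         noise_sd_hu = 3, noise_sd_suv = 0.05) {
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               breast_offset_mm = breast_offset_mm,
               breast_semi_axes_mm = as.numeric(breast_semi_axes_mm),
               gland_scale = gland_scale,
               fat_hu_mean = fat_hu_mean, fat_hu_sd = fat_hu_sd,
               gland_hu_mean = gland_hu_mean, tumor_hu_mean = tumor_hu_mean,
               background_hu = background_hu,
               tumor_center_offset_mm = as.numeric(tumor_center_offset_mm),
               tumor_radius_mm = tumor_radius_mm,
               peritumoral_delta_hu = peritumoral_delta_hu,
               peritumoral_reach_mm = peritumoral_reach_mm,
               tumor_suv_peak = tumor_suv_peak,
               background_suv = background_suv,
               noise_sd_hu = noise_sd_hu, noise_sd_suv = noise_sd_suv)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (length(s$grid_shape) != 3L || any(s$grid_shape < 2L))
    stop("grid_shape must be 3 values >= 2", call. = FALSE)
  if (length(s$spacing_mm) != 3L || any(s$spacing_mm <= 0))
    stop("spacing_mm must be strictly positive per axis", call. = FALSE)
  if (s$fat_hu_mean < -200 || s$fat_hu_mean > -50)
    stop("fat_hu_mean must lie in the fat window [-200, -50] HU",
         call. = FALSE)
  if (s$peritumoral_reach_mm < 10)
    stop("peritumoral_reach_mm must be >= 10 mm so the measurement shell ",
         "samples shifted fat", call. = FALSE)
  if (s$tumor_radius_mm <= 0) stop("tumor_radius_mm must be > 0",
                                   call. = FALSE)
  if (any(c(s$fat_hu_sd, s$noise_sd_hu, s$noise_sd_suv) < 0))
    stop("noise standard deviations must be >= 0", call. = FALSE)
  # tumor sphere must sit inside the breast ellipsoid (conservative bound)
  off <- abs(s$tumor_center_offset_mm)
  if (sum(((off + s$tumor_radius_mm) / s$breast_semi_axes_mm)^2) > 1)
    stop("tumor radius exceeds the breast region", call. = FALSE)
  # tumor must not cross the sagittal midline
  if (s$breast_offset_mm + s$tumor_center_offset_mm[1] <= s$tumor_radius_mm)
    stop("tumor crosses the sagittal midline", call. = FALSE)
  invisible(s)
}

#' Generate a synthetic breast PET/CT phantom case
#'
#' Deterministic given `(spec, seed)`. CT fat voxels are drawn from
#' `Normal(fat_hu_mean, fat_hu_sd)`; fat within `peritumoral_reach_mm` of the
#' tumor surface is shifted by `+peritumoral_delta_hu`; gland, tumor and
#' background voxels sit at their programmed means; global Gaussian
#' acquisition noise (`noise_sd_hu`) is added on top. The PET volume holds
#' `tumor_suv_peak` inside the tumor and `background_suv` elsewhere, plus
#' `noise_sd_suv` Gaussian noise, floored at 0.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; identical `(spec, seed)` give bit-identical
#'   cases.
#' @return An object of class `phantom_case`: list with `ct`, `pet`
#'   ([image_volume()]s), `tumor_mask` (logical array), `midline_x_mm`, and
#'   `truth` (programmed tumor-side fat HU mean, contralateral fat HU mean,
#'   tumor volume in mm^3, SUV peak).
#' @export
make_breast_phantom <- function(spec = phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  dims <- spec$grid_shape
  sp <- spec$spacing_mm
  cx <- (0:(dims[1] - 1)) * sp[1]
  cy <- (0:(dims[2] - 1)) * sp[2]
  cz <- (0:(dims[3] - 1)) * sp[3]
  midline <- (dims[1] - 1) / 2 * sp[1]
  b_center_y <- (dims[2] - 1) / 2 * sp[2]
  b_center_z <- (dims[3] - 1) / 2 * sp[3]
  bc_t <- c(midline + spec$breast_offset_mm, b_center_y, b_center_z)
  bc_c <- c(midline - spec$breast_offset_mm, b_center_y, b_center_z)

  ellipsoid <- function(center, semi) {
    dx2 <- ((cx - center[1]) / semi[1])^2
    dy2 <- ((cy - center[2]) / semi[2])^2
    dz2 <- ((cz - center[3]) / semi[3])^2
    m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    dim(m) <- dims
    m
  }
  breast <- ellipsoid(bc_t, spec$breast_semi_axes_mm) |
    ellipsoid(bc_c, spec$breast_semi_axes_mm)
  gland <- ellipsoid(bc_t, spec$gland_scale * spec$breast_semi_axes_mm) |
    ellipsoid(bc_c, spec$gland_scale * spec$breast_semi_axes_mm)

  tc <- bc_t + spec$tumor_center_offset_mm
  dx2 <- (cx - tc[1])^2
  dy2 <- (cy - tc[2])^2
  dz2 <- (cz - tc[3])^2
  dist2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  dim(dist2) <- dims
  tumor <- dist2 <= spec$tumor_radius_mm^2
  if (!any(tumor))
    stop("tumor sphere contains no voxel centers; enlarge the radius or ",
         "refine the grid", call. = FALSE)

  fat <- breast & !gland & !tumor
  gland <- gland & !tumor
  reach2 <- (spec$tumor_radius_mm + spec$peritumoral_reach_mm)^2
  peritumoral <- fat & dist2 <= reach2

  ct_vals <- array(spec$background_hu, dims)
  ct_vals[gland] <- spec$gland_hu_mean
  ct_vals[tumor] <- spec$tumor_hu_mean
  pet_vals <- array(spec$background_suv, dims)
  pet_vals[tumor] <- spec$tumor_suv_peak

  with_seed(seed, {
    ct_vals[fat] <- stats::rnorm(sum(fat), spec$fat_hu_mean, spec$fat_hu_sd)
    ct_vals[peritumoral] <- ct_vals[peritumoral] + spec$peritumoral_delta_hu
    if (spec$noise_sd_hu > 0)
      ct_vals <- ct_vals + stats::rnorm(length(ct_vals), 0, spec$noise_sd_hu)
    if (spec$noise_sd_suv > 0)
      pet_vals <- pmax(pet_vals +
                         stats::rnorm(length(pet_vals), 0, spec$noise_sd_suv),
                       0)
  })

  structure(list(
    ct = image_volume(ct_vals, sp, unit = "HU"),
    pet = image_volume(pet_vals, sp, unit = "SUV"),
    tumor_mask = tumor,
    midline_x_mm = midline,
    truth = list(
      tumor_side_fat_hu = spec$fat_hu_mean + spec$peritumoral_delta_hu,
      contralateral_fat_hu = spec$fat_hu_mean,
      tumor_volume_mm3 = sum(tumor) * prod(sp),
      suv_peak = spec$tumor_suv_peak),
    spec = spec, seed = as.integer(seed)),
    class = "phantom_case")
}

#' Write a phantom case to disk
#'
#' Writes `<prefix>_ct.nii.gz`, `<prefix>_pet.nii.gz`,
#' `<prefix>_mask.nii.gz` (with JSON sidecars) and `<prefix>_truth.csv`.
#'
#' @param case a `phantom_case`.
#' @param prefix output path prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_phantom_case <- function(case, prefix) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(ct = paste0(prefix, "_ct.nii.gz"),
             pet = paste0(prefix, "_pet.nii.gz"),
             mask = paste0(prefix, "_mask.nii.gz"),
             truth = paste0(prefix, "_truth.csv"))
  write_volume(case$ct, paths["ct"])
  write_volume(case$pet, paths["pet"])
  mask_vol <- image_volume(array(as.numeric(case$tumor_mask),
                                 dim(case$tumor_mask)),
                           case$ct$spacing_mm, case$ct$origin_mm,
                           unit = "mask")
  write_volume(mask_vol, paths["mask"])
  utils::write.csv(data.frame(midline_x_mm = case$midline_x_mm,
                              as.data.frame(case$truth)),
                   paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Specification of a simulated breast cancer cohort
#'
#' Defaults emulate the published study population: 287 patients, T stage
#' 47.4/44.6/8.0% (T1/T2/T3), 66.2% node-negative, ER+ 74.2%, PR+ 61.7%
#' marginally (drawn conditional on ER so that triple-negative tumors arise
#' at a realistic ~11% rate), HER2+ 49.5%, Ki67+ 61.7%, histologic grade
#' 23.4/49.7/26.9%. Contralateral fat attenuation is Normal(-97.54, 7) HU
#' with a negative BMI dependence; the tumor-adjacent shift (TAT - CAT) has a
#' stage-, receptor- and grade-dependent location. Recurrence times follow an
#' exponential proportional-hazards model on the named numeric covariates
#' (mean-centered), with administrative censoring uniform on the follow-up
#' window; when `baseline_hazard` is `NULL` it is calibrated so the expected
#' event fraction equals `target_event_fraction` (default 10.5%).
#'
#' @param n_patients cohort size (>= 2).
#' @param t_stage_freq named frequencies for T1/T2/T3 (sum to 1).
#' @param n_positive_by_t probability of nodal involvement given T stage.
#' @param n_split split of N1/N2/N3 within node-positive patients.
#' @param er_pos_freq probability of ER positivity.
#' @param pr_pos_by_er probability of PR positivity given ER status.
#' @param her2_pos_freq,ki67_pos_freq marginal positivity probabilities.
#' @param grade_freq frequencies of histologic grades 1-3.
#' @param age_mean,age_sd,age_range age distribution (years), truncated.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param cat_hu_mean,cat_hu_sd contralateral fat attenuation (HU).
#' @param bmi_cat_slope HU change in CAT per BMI unit (negative: denser fat
#'   in leaner patients).
#' @param delta_intercept,delta_t2,delta_t3,delta_er_neg,delta_pr_neg,delta_grade3
#'   location model of the TAT shift (HU): baseline plus additive terms for
#'   T2/T3 stage, ER/PR negativity and grade 3.
#' @param delta_sd residual SD of the TAT shift (HU).
#' @param suv_median,suv_sdlog lognormal SUVmax of the primary tumor.
#' @param mtv_sdlog residual lognormal spread of MTV given SUVmax.
#' @param hazard_coef named list of per-unit log-hazard coefficients on
#'   numeric cohort columns; default `list(tat_hu = log(1.10))`, i.e. hazard
#'   ratio 1.10 per 1-HU increase of TAT HU.
#' @param baseline_hazard exponential baseline hazard per month, or `NULL` to
#'   calibrate to `target_event_fraction`.
#' @param target_event_fraction expected fraction of observed recurrences.
#' @param censor_range_months administrative censoring window (months).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 287,
                        t_stage_freq = c(T1 = 0.474, T2 = 0.446, T3 = 0.080),
                        n_positive_by_t = c(T1 = 0.20, T2 = 0.42, T3 = 0.70),
                        n_split = c(N1 = 0.598, N2 = 0.216, N3 = 0.186),
                        er_pos_freq = 0.742,
                        pr_pos_by_er = c(positive = 0.78, negative = 0.15),
                        her2_pos_freq = 0.495, ki67_pos_freq = 0.617,
                        grade_freq = c(0.234, 0.497, 0.269),
                        age_mean = 52.5, age_sd = 10.5,
                        age_range = c(30, 85),
                        bmi_mean = 23.8, bmi_sd = 3.3,
                        cat_hu_mean = -97.54, cat_hu_sd = 7,
                        bmi_cat_slope = -0.58,
                        delta_intercept = 6.0, delta_t2 = 3.0,
                        delta_t3 = 5.0, delta_er_neg = 1.8,
                        delta_pr_neg = 1.8, delta_grade3 = 1.5,
                        delta_sd = 5.0,
                        suv_median = 4.06, suv_sdlog = 1.0, mtv_sdlog = 0.5,
                        hazard_coef = list(tat_hu = log(1.10)),
                        baseline_hazard = NULL,
                        target_event_fraction = 0.105,
                        censor_range_months = c(6.1, 88.9)) {
  spec <- as.list(environment())
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  if (s$n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  freqs <- c(s$t_stage_freq, s$n_positive_by_t, s$n_split, s$er_pos_freq,
             s$pr_pos_by_er, s$her2_pos_freq, s$ki67_pos_freq, s$grade_freq,
             s$target_event_fraction)
  if (any(freqs < 0 | freqs > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  if (abs(sum(s$t_stage_freq) - 1) > 1e-8)
    stop("t_stage_freq must sum to 1", call. = FALSE)
  if (abs(sum(s$grade_freq) - 1) > 1e-8)
    stop("grade_freq must sum to 1", call. = FALSE)
  if (!is.null(s$baseline_hazard) && s$baseline_hazard <= 0)
    stop("baseline_hazard must be > 0", call. = FALSE)
  if (length(s$censor_range_months) != 2L ||
      any(s$censor_range_months <= 0) ||
      diff(s$censor_range_months) <= 0)
    stop("censor_range_months must be a positive increasing window",
         call. = FALSE)
  if (s$cat_hu_sd^2 <= (s$bmi_cat_slope * s$bmi_sd)^2)
    stop("cat_hu_sd too small for the programmed BMI dependence",
         call. = FALSE)
  invisible(s)
}

# expected fraction of observed events for exponential event times with
# per-subject rates `lambda` under uniform censoring on [a, b]:
# P(T < C) = 1 - (exp(-lambda a) - exp(-lambda b)) / (lambda (b - a))
expected_event_fraction <- function(lambda, censor_range) {
  a <- censor_range[1]; b <- censor_range[2]
  p <- 1 - (exp(-lambda * a) - exp(-lambda * b)) / (lambda * (b - a))
  p[lambda < 1e-12] <- 0
  mean(p)
}

# solve for the exponential baseline hazard giving the target expected event
# fraction over the realized linear predictors
calibrate_baseline_hazard <- function(lp, censor_range, target) {
  f <- function(log_h0)
    expected_event_fraction(exp(log_h0 + lp), censor_range) - target
  exp(stats::uniroot(f, c(-25, 5), tol = 1e-12)$root)
}

#' Simulate a breast cancer cohort with recurrence follow-up
#'
#' Draws covariates from the frequency tables of a [cohort_spec()], builds
#' the adipose parameters (CAT HU, TAT HU = CAT + shift, HU difference, HU
#' difference %), generates recurrence times from an exponential
#' proportional-hazards model `h(t) = h0 * exp(sum(beta * (x - mean(x))))`
#' over the named numeric columns in `spec$hazard_coef`, applies uniform
#' administrative censoring, and returns the observed follow-up table.
#' Deterministic given `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return A data.frame with one row per patient: demographics, stage and
#'   receptor covariates, `tat_hu`, `cat_hu`, `hu_difference`,
#'   `hu_difference_pct`, `suv_max`, `mtv_cm3`, `followup_months`, and
#'   `recurrence` (1 = recurrence observed, 0 = censored).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  n <- spec$n_patients
  with_seed(seed, {
    age <- round(pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                           spec$age_range[1]), spec$age_range[2]))
    menopausal <- factor(ifelse(age + stats::rnorm(n, 0, 3) > 50,
                                "postmenopausal", "premenopausal"),
                         levels = c("premenopausal", "postmenopausal"))
    bmi <- stats::rnorm(n, spec$bmi_mean, spec$bmi_sd)
    t_stage <- factor(sample(names(spec$t_stage_freq), n, replace = TRUE,
                             prob = spec$t_stage_freq),
                      levels = names(spec$t_stage_freq))
    n_pos <- stats::runif(n) < spec$n_positive_by_t[as.character(t_stage)]
    n_cat <- ifelse(n_pos,
                    sample(names(spec$n_split), n, replace = TRUE,
                           prob = spec$n_split), "N0")
    n_stage <- factor(n_cat, levels = c("N0", "N1", "N2", "N3"))
    n_positive <- factor(ifelse(n_pos, "N1-3", "N0"),
                         levels = c("N0", "N1-3"))
    grade <- factor(sample(c("grade1", "grade2", "grade3"), n,
                           replace = TRUE, prob = spec$grade_freq),
                    levels = c("grade1", "grade2", "grade3"))
    er <- factor(ifelse(stats::runif(n) < spec$er_pos_freq,
                        "positive", "negative"),
                 levels = c("positive", "negative"))
    pr <- factor(ifelse(stats::runif(n) < spec$pr_pos_by_er[as.character(er)],
                        "positive", "negative"),
                 levels = c("positive", "negative"))
    her2 <- factor(ifelse(stats::runif(n) < spec$her2_pos_freq,
                          "positive", "negative"),
                   levels = c("positive", "negative"))
    ki67 <- factor(ifelse(stats::runif(n) < spec$ki67_pos_freq,
                          "positive", "negative"),
                   levels = c("negative", "positive"))
    triple_negative <- factor(ifelse(er == "negative" & pr == "negative" &
                                       her2 == "negative", "yes", "no"),
                              levels = c("no", "yes"))

    resid_sd <- sqrt(spec$cat_hu_sd^2 - (spec$bmi_cat_slope * spec$bmi_sd)^2)
    cat_hu <- spec$cat_hu_mean + spec$bmi_cat_slope * (bmi - spec$bmi_mean) +
      stats::rnorm(n, 0, resid_sd)
    delta_mu <- spec$delta_intercept +
      spec$delta_t2 * (t_stage == "T2") + spec$delta_t3 * (t_stage == "T3") +
      spec$delta_er_neg * (er == "negative") +
      spec$delta_pr_neg * (pr == "negative") +
      spec$delta_grade3 * (grade == "grade3")
    delta <- delta_mu + stats::rnorm(n, 0, spec$delta_sd)
    tat_hu <- cat_hu + delta

    suv <- exp(stats::rnorm(n, log(spec$suv_median), spec$suv_sdlog))
    mtv <- ifelse(suv < 2.50, 0,
                  (suv - 2.50) * exp(stats::rnorm(n, 0, spec$mtv_sdlog)))

    cohort <- data.frame(
      id = seq_len(n), age = age, bmi = bmi, menopausal = menopausal,
      t_stage = t_stage, n_stage = n_stage, n_positive = n_positive,
      histologic_grade = grade, er = er, pr = pr, her2 = her2, ki67 = ki67,
      triple_negative = triple_negative,
      tat_hu = tat_hu, cat_hu = cat_hu, hu_difference = tat_hu - cat_hu,
      hu_difference_pct = (cat_hu - tat_hu) / cat_hu * 100,
      suv_max = suv, mtv_cm3 = mtv)

    lp <- rep(0, n)
    for (nm in names(spec$hazard_coef)) {
      x <- cohort[[nm]]
      if (is.null(x) || !is.numeric(x))
        stop("hazard_coef names must be numeric cohort columns; bad: ", nm,
             call. = FALSE)
      lp <- lp + spec$hazard_coef[[nm]] * (x - mean(x))
    }
    h0 <- spec$baseline_hazard
    if (is.null(h0))
      h0 <- calibrate_baseline_hazard(lp, spec$censor_range_months,
                                      spec$target_event_fraction)
    lambda <- h0 * exp(lp)
    event_time <- stats::rexp(n, rate = lambda)
    censor_time <- stats::runif(n, spec$censor_range_months[1],
                                spec$censor_range_months[2])
    cohort$followup_months <- pmin(event_time, censor_time)
    cohort$recurrence <- as.integer(event_time <= censor_time)
    cohort
  })
}

#' Simulate paired reader measurements
#'
#' Two independent noisy observations of each underlying attenuation value,
#' emulating two readers independently placing VOIs; used to exercise the
#' concordance correlation analysis. With truth variance `v`, the population
#' concordance between the readers is `v / (v + reader_sd^2)`.
#'
#' @param truth_values numeric vector of underlying values (e.g. TAT HU).
#' @param reader_sd per-reader measurement SD (>= 0).
#' @param seed integer seed.
#' @return A list with numeric vectors `reader1` and `reader2`.
#' @export
simulate_reader_pair <- function(truth_values, reader_sd, seed = 1L) {
  if (length(truth_values) == 0)
    stop("truth_values must be nonempty", call. = FALSE)
  if (!is.finite(reader_sd) || reader_sd < 0)
    stop("reader_sd must be >= 0", call. = FALSE)
  n <- length(truth_values)
  with_seed(seed, list(
    reader1 = truth_values + stats::rnorm(n, 0, reader_sd),
    reader2 = truth_values + stats::rnorm(n, 0, reader_sd)))
}
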