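#' Study configuration
#'
#' Assembles the configuration driving [run_study()]: the phantom and cohort
#' specifications, the measurement settings (fat window, VOI margin, SUV
#' threshold), the reader-noise level for the agreement analysis, and the
#' root seed. Every stage seed is derived from the root seed, so a config
#' fully determines the report.
#'
#' @param seed root seed.
#' @param n_phantom_cases phantom cases generated and measured for the
#'   imaging-chain check (0 to skip).
#' @param phantom named list of [phantom_spec()] overrides.
#' @param cohort named list of [cohort_spec()] overrides.
#' @param reader_sd per-reader SD (HU) for the simulated agreement analysis.
#' @param voi_margin_mm VOI margin beyond the tumor surface.
#' @param fat_window fat window in HU.
#' @param suv_threshold MTV threshold.
#' @param min_voxels minimum adipose voxels per VOI.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_phantom_cases = 2,
                         phantom = list(), cohort = list(),
                         reader_sd = 1.6, voi_margin_mm = 10,
                         fat_window = c(-200, -50), suv_threshold = 2.50,
                         min_voxels = 10) {
  if (fat_window[1] >= fat_window[2] || fat_window[2] > 0)
    stop("fat_window must be an increasing HU range below 0", call. = FALSE)
  if (suv_threshold < 0 || voi_margin_mm < 0 || reader_sd < 0)
    stop("thresholds must be nonnegative", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_phantom_cases = n_phantom_cases,
                 phantom = phantom, cohort = cohort, reader_sd = reader_sd,
                 voi_margin_mm = voi_margin_mm, fat_window = fat_window,
                 suv_threshold = suv_threshold, min_voxels = min_voxels),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the [study_config()] arguments; `phantom:` and
#' `cohort:` blocks hold [phantom_spec()] / [cohort_spec()] overrides.
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(study_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Baseline characteristics table
#'
#' Categorical variables as count and percentage (rounded half-up to one
#' decimal), continuous variables as median and range.
#'
#' @param cohort a cohort data.frame from [simulate_cohort()].
#' @return A data.frame with columns `variable`, `level`, `n`, `pct`,
#'   `median`, `range_lo`, `range_hi`.
#' @export
baseline_table <- function(cohort) {
  cat_vars <- c("menopausal", "t_stage", "n_stage", "histologic_grade",
                "er", "pr", "her2", "ki67", "triple_negative", "recurrence")
  num_vars <- c("age", "bmi", "suv_max", "mtv_cm3", "tat_hu", "cat_hu",
                "hu_difference", "hu_difference_pct", "followup_months")
  n <- nrow(cohort)
  rows <- list()
  for (v in num_vars) {
    x <- cohort[[v]]
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = NA_character_, n = NA_integer_, pct = NA_real_,
      median = stats::median(x), range_lo = min(x), range_hi = max(x))
  }
  for (v in cat_vars) {
    tab <- table(as.factor(cohort[[v]]))
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = names(tab), n = as.integer(tab),
      pct = round_half_up(100 * as.integer(tab) / n, 1),
      median = NA_real_, range_lo = NA_real_, range_hi = NA_real_)
  }
  do.call(rbind, rows)
}

adipose_params <- c("tat_hu", "cat_hu", "hu_difference", "hu_difference_pct")

#' Group comparison of adipose parameters
#'
#' Compares the four adipose parameters across each clinico-histological
#' factor: Student's t for two groups, Kruskal-Wallis (with Conover-Iman
#' post-hoc) for three or more.
#'
#' @param cohort a cohort data.frame.
#' @param factors factor columns to compare across.
#' @return A list with `means` (factor, group, n, and mean/sd per parameter)
#'   and `tests` (factor, parameter, method, statistic, p_value).
#' @export
group_comparison_table <- function(cohort,
                                   factors = c("t_stage", "n_positive",
                                               "histologic_grade", "er",
                                               "pr", "her2", "ki67",
                                               "recurrence")) {
  means <- list(); tests <- list()
  for (f in factors) {
    g <- as.factor(cohort[[f]])
    m <- data.frame(factor = f, group = levels(g),
                    n = as.integer(table(g)))
    for (p in adipose_params) {
      m[[paste0(p, "_mean")]] <- as.numeric(tapply(cohort[[p]], g, mean))
      m[[paste0(p, "_sd")]] <- as.numeric(tapply(cohort[[p]], g, stats::sd))
      gc <- group_compare(cohort[[p]], g)
      tests[[length(tests) + 1]] <- data.frame(
        factor = f, parameter = p, method = gc$method,
        statistic = gc$statistic, p_value = gc$p_value)
    }
    means[[length(means) + 1]] <- m
  }
  list(means = do.call(rbind, means), tests = do.call(rbind, tests))
}

# fit one Cox model, degrading to an NA row when the partial likelihood is
# monotone (e.g. a stage level without events in a small simulated cohort)
safe_cox <- function(data, covariates, model_label, ...) {
  tryCatch(cox_regression(data, covariates, model_label, ...),
           error = function(e) {
             if (!grepl("diverged", conditionMessage(e))) stop(e)
             out <- data.frame(model = model_label,
                               term = paste(covariates, collapse = "+"),
                               coefficient = NA_real_,
                               hazard_ratio = NA_real_, ci_lo = NA_real_,
                               ci_hi = NA_real_, p_value = NA_real_,
                               n = nrow(data),
                               n_events = sum(data$recurrence))
             class(out) <- c("survival_fit", "data.frame")
             out
           })
}

#' Univariate Cox table over the standard covariate battery
#'
#' @param cohort a cohort data.frame.
#' @param variables covariates fitted one at a time.
#' @return A `survival_fit` data.frame, one block per variable.
#' @export
univariate_survival_table <- function(cohort,
                                      variables = c("age", "bmi",
                                                    "menopausal", "t_stage",
                                                    "n_positive",
                                                    "histologic_grade", "er",
                                                    "pr", "her2", "ki67",
                                                    "triple_negative",
                                                    "suv_max", "mtv_cm3",
                                                    "tat_hu", "cat_hu",
                                                    "hu_difference",
                                                    "hu_difference_pct")) {
  do.call(rbind, lapply(variables, function(v)
    safe_cox(cohort, v, model_label = "univariate")))
}

#' Multivariate Cox models for the adipose parameters
#'
#' Three adjustment sets per adipose parameter: model 1 adjusts for age, T
#' stage and nodal status; model 2 adds ER, PR and Ki67 status; model 3 adds
#' SUVmax and MTV of the primary tumor.
#'
#' @param cohort a cohort data.frame.
#' @param params adipose parameters modeled (one model per parameter).
#' @return A list with `fits` (all terms of every fitted model) and
#'   `adipose_terms` (the adipose-parameter rows only, the headline table).
#' @export
multivariate_models_table <- function(cohort,
                                      params = c("tat_hu", "hu_difference",
                                                 "hu_difference_pct")) {
  sets <- list(
    model1 = c("age", "t_stage", "n_positive"),
    model2 = c("age", "t_stage", "n_positive", "er", "pr", "ki67"),
    model3 = c("age", "t_stage", "n_positive", "er", "pr", "ki67",
               "suv_max", "mtv_cm3"))
  fits <- list()
  for (p in params) {
    for (m in names(sets)) {
      fits[[length(fits) + 1]] <-
        safe_cox(cohort, c(p, sets[[m]]),
                 model_label = paste(m, p, sep = ":"))
    }
  }
  fits <- do.call(rbind, fits)
  adip <- fits[fits$term %in% params, , drop = FALSE]
  rownames(adip) <- NULL
  list(fits = fits, adipose_terms = adip)
}

#' Run the full simulated study
#'
#' Orchestrates the analysis end to end: generate and measure phantom cases
#' (imaging-chain check), simulate the cohort, run the reader-agreement,
#' group-comparison, correlation, Cox, ROC-cutoff, Kaplan-Meier and
#' stratified-recurrence analyses, and collect everything in a report object.
#' Deterministic given the config (one root seed expanded into per-stage
#' seeds).
#'
#' @param config a [study_config()].
#' @return An object of class `study_report`: a list of tables plus `config`
#'   and `config_md5`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  report <- list(config = unclass(config), config_md5 = config_hash(config))

  # imaging chain on phantom cases: programmed truth vs measured readout
  if (config$n_phantom_cases > 0) {
    pspec <- do.call(phantom_spec, config$phantom)
    rows <- lapply(seq_len(config$n_phantom_cases), function(i) {
      case <- make_breast_phantom(pspec, seed = seed + 100L + i)
      meas <- measure_case(case, margin_mm = config$voi_margin_mm,
                           hu_window = config$fat_window,
                           suv_threshold = config$suv_threshold,
                           min_voxels = config$min_voxels)
      cbind(data.frame(case = i,
                       truth_tat_hu = case$truth$tumor_side_fat_hu,
                       truth_cat_hu = case$truth$contralateral_fat_hu,
                       truth_suv_peak = case$truth$suv_peak,
                       truth_tumor_volume_mm3 = case$truth$tumor_volume_mm3),
            meas)
    })
    report$phantom_measurements <- do.call(rbind, rows)
  }

  cspec <- do.call(cohort_spec, config$cohort)
  cohort <- simulate_cohort(cspec, seed = seed + 202L)
  report$cohort <- cohort
  report$baseline <- baseline_table(cohort)

  # inter-reader agreement on simulated repeat measurements
  agree <- lapply(c(tat_hu = "tat_hu", cat_hu = "cat_hu"), function(p) {
    pair <- simulate_reader_pair(cohort[[p]], config$reader_sd,
                                 seed = seed + 303L + match(p, adipose_params))
    concordance_correlation(pair$reader1, pair$reader2)
  })
  report$agreement <- cbind(parameter = names(agree),
                            do.call(rbind, agree))

  report$paired_tat_cat <- paired_t_test(cohort$tat_hu, cohort$cat_hu)
  report$correlations <- do.call(rbind, lapply(
    list(c("bmi", "tat_hu"), c("bmi", "cat_hu"),
         c("suv_max", "tat_hu"), c("suv_max", "hu_difference"),
         c("mtv_cm3", "tat_hu")),
    function(pair) {
      sc <- spearman_correlation(cohort[[pair[1]]], cohort[[pair[2]]])
      data.frame(x = pair[1], y = pair[2], rho = sc$rho,
                 p_value = sc$p_value)
    }))

  gc <- group_comparison_table(cohort)
  report$group_means <- gc$means
  report$group_tests <- gc$tests

  report$univariate <- univariate_survival_table(cohort)
  mv <- multivariate_models_table(cohort)
  report$multivariate <- mv$adipose_terms
  report$multivariate_full <- mv$fits

  # ROC cutoffs, KM stratification and 5-year RFS for the adipose parameters
  cut_rows <- lapply(c("tat_hu", "hu_difference", "hu_difference_pct"),
                     function(p) {
    cr <- optimal_cutoff(cohort[[p]], cohort$recurrence)
    grp <- factor(ifelse(cohort[[p]] >= cr$threshold, "high", "low"),
                  levels = c("low", "high"))
    lr <- log_rank(cohort$followup_months, cohort$recurrence, grp)
    km <- kaplan_meier(cohort$followup_months, cohort$recurrence, grp)
    data.frame(parameter = p, cr,
               rfs5yr_low = survival_at(km, 60, "low"),
               rfs5yr_high = survival_at(km, 60, "high"),
               logrank_chisq = lr$chi_square, logrank_p = lr$p_value)
  })
  report$cutoffs <- do.call(rbind, cut_rows)

  tat_cut <- report$cutoffs$threshold[report$cutoffs$parameter == "tat_hu"]
  report$stratified_recurrence <-
    stratified_recurrence_table(cohort, "tat_hu", tat_cut)

  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed", x$config$seed, "config md5", x$config_md5, "\n")
  cat(sprintf("  cohort: %d patients, %d recurrences (%.1f%%)\n",
              nrow(x$cohort), sum(x$cohort$recurrence),
              100 * mean(x$cohort$recurrence)))
  cat("  tables:", paste(setdiff(names(x), c("config", "cohort")),
                         collapse = ", "), "\n")
  invisible(x)
}

format_md_table <- function(df, digits = 3) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits + 2)
  }
  cells <- rbind(names(df), rep("---", ncol(df)),
                 as.matrix(format(df, digits = digits, trim = TRUE)))
  cells[is.na(cells) | cells == "NA"] <- "NE"
  paste0("| ", apply(cells, 1, paste, collapse = " | "), " |")
}

#' Render a study report to files
#'
#' Writes every table as CSV, a combined markdown rendering, and a
#' machine-readable JSON report (tables, config and config hash). Cells that
#' are not evaluable render as `NE` in markdown.
#'
#' @param report a `study_report` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("csv", "markdown", "json")`.
#' @return Character vector of written paths, invisibly.
#' @export
render_tables <- function(report, out_dir,
                          formats = c("csv", "markdown", "json")) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- Filter(is.data.frame, unclass(report))
  written <- character(0)
  if ("csv" %in% formats) {
    for (nm in names(tables)) {
      path <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], path, row.names = FALSE)
      written <- c(written, path)
    }
  }
  if ("markdown" %in% formats) {
    path <- file.path(out_dir, "report.md")
    lines <- c("# Simulated study report", "",
               paste0("Seed ", report$config$seed, ", config md5 `",
                      report$config_md5, "`."), "")
    for (nm in setdiff(names(tables), "cohort")) {
      lines <- c(lines, paste("##", nm), "",
                 format_md_table(tables[[nm]]), "")
    }
    writeLines(lines, path)
    written <- c(written, path)
  }
  if ("json" %in% formats) {
    path <- file.path(out_dir, "report.json")
    payload <- c(list(config = report$config, config_md5 = report$config_md5,
                      paired_tat_cat = report$paired_tat_cat),
                 tables[setdiff(names(tables), "cohort")])
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, path)
  }
  invisible(written)
}
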