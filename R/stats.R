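#' Lin's concordance correlation coefficient
#'
#' Agreement between two continuous measurements, combining precision
#' (Pearson correlation) and accuracy (bias from the identity line):
#' `CCC = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. The 95% confidence interval uses the Fisher
#' z-transform with Lin's (1989) asymptotic variance.
#'
#' @param x,y numeric vectors of equal length n >= 3, each with nonzero
#'   variance.
#' @param conf_level confidence level (default 0.95).
#' @return A one-row data.frame: `estimate`, `ci_lo`, `ci_hi`, `n`.
#' @examples
#' concordance_correlation(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
concordance_correlation <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0)
    stop("zero variance: concordance undefined", call. = FALSE)
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  if (1 - ccc^2 < 1e-12) {
    ci <- c(ccc, ccc)
  } else {
    r <- sxy / sqrt(sx2 * sy2)
    u2 <- (mx - my)^2 / sqrt(sx2 * sy2)
    # Lin 1989 variance of the z-transformed estimate
    sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              2 * ccc^3 * (1 - ccc) * u2 / (r * (1 - ccc^2)^2) -
              ccc^4 * u2^2 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    z <- atanh(ccc)
    hw <- stats::qnorm(1 - (1 - conf_level) / 2) * sqrt(max(sz2, 0))
    ci <- tanh(c(z - hw, z + hw))
  }
  data.frame(estimate = ccc, ci_lo = ci[1], ci_hi = ci[2], n = n)
}

#' Paired t test
#'
#' Two-sided paired t test on the within-pair differences `x - y`.
#'
#' @param x,y numeric vectors of equal length n >= 2.
#' @return A list: `statistic`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t undefined", call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Compare a continuous measurement across groups
#'
#' Two groups: Student's t test (pooled variance). Three or more groups:
#' Kruskal-Wallis test with tie correction, followed by Conover-Iman pairwise
#' post-hoc comparisons (rank-based t statistics with the pooled rank
#' variance, df = N - k) when the omnibus test is significant at `alpha`.
#'
#' @param values numeric vector.
#' @param groups grouping vector (coerced to factor); every group needs >= 2
#'   members.
#' @param alpha significance level gating the post-hoc step (default 0.05).
#' @return A list with `method` (`"student_t"` or `"kruskal_wallis"`),
#'   `statistic`, `p_value`, per-group `means`, and for Kruskal-Wallis `df`
#'   and a `posthoc` data.frame (`group1`, `group2`, `statistic`, `p_value`)
#'   or `NULL`.
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(as.factor(groups[keep]))
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("every group needs >= 2 members; smallest has ", min(sizes),
         call. = FALSE)
  means <- tapply(values, groups, mean)
  if (k == 2) {
    tt <- stats::t.test(values ~ groups, var.equal = TRUE)
    return(list(method = "student_t", statistic = unname(tt$statistic),
                p_value = tt$p.value, means = means))
  }
  kw <- stats::kruskal.test(values, groups)
  posthoc <- NULL
  if (kw$p.value < alpha)
    posthoc <- conover_iman(values, groups, unname(kw$statistic))
  list(method = "kruskal_wallis", statistic = unname(kw$statistic),
       df = unname(kw$parameter), p_value = kw$p.value, means = means,
       posthoc = posthoc)
}

# Conover-Iman pairwise comparisons after Kruskal-Wallis: t statistics on
# mean ranks with the pooled rank variance S2, scaled by (N - 1 - H)/(N - k),
# df = N - k
conover_iman <- function(values, groups, H) {
  r <- rank(values)
  N <- length(values)
  k <- nlevels(groups)
  rbar <- tapply(r, groups, mean)
  n_g <- as.numeric(table(groups))
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  pool <- S2 * (N - 1 - H) / (N - k)
  pairs <- utils::combn(levels(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  i1 <- match(out$group1, levels(groups))
  i2 <- match(out$group2, levels(groups))
  se <- sqrt(pool * (1 / n_g[i1] + 1 / n_g[i2]))
  out$statistic <- (rbar[i1] - rbar[i2]) / se
  out$p_value <- 2 * stats::pt(-abs(out$statistic), df = N - k)
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p-value from the
#' large-sample t approximation.
#'
#' @param x,y numeric vectors of equal length n >= 3, non-constant.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Cox partial likelihood with Efron tie handling via
#' [survival::coxph()] and returns per-covariate coefficients, hazard ratios,
#' Wald confidence intervals and p-values. Perfect separation (monotone
#' likelihood) and constant covariates are raised as errors.
#'
#' @param data data.frame holding follow-up and covariates.
#' @param covariates character vector of covariate column names.
#' @param model_label label recorded in the output (e.g. `"univariate"`,
#'   `"model1"`).
#' @param time_col,event_col follow-up time and event indicator columns.
#' @param conf_level confidence level for the Wald interval.
#' @return A data.frame of class `survival_fit`: `model`, `term`,
#'   `coefficient`, `hazard_ratio`, `ci_lo`, `ci_hi`, `p_value`, `n`,
#'   `n_events`.
#' @export
cox_regression <- function(data, covariates, model_label = "univariate",
                           time_col = "followup_months",
                           event_col = "recurrence", conf_level = 0.95) {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  missing_cols <- setdiff(c(covariates, time_col, event_col), names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (sum(data[[event_col]]) < 1)
    stop("no events in the data", call. = FALSE)
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2)
      stop("constant covariate: ", cv, call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop("Cox model diverged (monotone likelihood?): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit, conf.int = conf_level)
  co <- sm$coefficients
  ci <- sm$conf.int
  out <- data.frame(model = model_label, term = rownames(co),
                    coefficient = co[, "coef"],
                    hazard_ratio = co[, "exp(coef)"],
                    ci_lo = ci[, 3], ci_hi = ci[, 4],
                    p_value = co[, "Pr(>|z|)"],
                    n = sm$n, n_events = sm$nevent,
                    row.names = NULL)
  class(out) <- c("survival_fit", "data.frame")
  out
}

#' Kaplan-Meier recurrence-free survival curve
#'
#' Product-limit estimator of the survivor function, optionally by group.
#'
#' @param time,event follow-up times and event indicators (1 = event).
#' @param group optional grouping vector.
#' @return An object of class `km_curve`: data.frame with `group`, `time`,
#'   `n_risk`, `n_event`, `surv`.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  if (length(time) < 1) stop("need at least one record", call. = FALSE)
  df <- data.frame(time = time, event = event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    out <- data.frame(group = "all", time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  } else {
    df$group <- as.factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    out <- data.frame(
      group = rep(sub("^group=", "", names(fit$strata)), fit$strata),
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      surv = fit$surv)
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at a time point
#'
#' Reads the Kaplan-Meier step function at time `t` (e.g. `t = 60` months for
#' the 5-year recurrence-free survival rate).
#'
#' @param km a [kaplan_meier()] curve.
#' @param t time point.
#' @param group group to evaluate (default the first).
#' @return Survival probability S(t).
#' @export
survival_at <- function(km, t, group = NULL) {
  stopifnot(inherits(km, "km_curve"))
  g <- if (is.null(group)) km$group[1] else group
  sub <- km[km$group == g, , drop = FALSE]
  prior <- sub$time <= t
  if (!any(prior)) return(1)
  sub$surv[max(which(prior))]
}

#' Two-group log-rank test
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level grouping vector, each group nonempty.
#' @return A list: `chi_square`, `df`, `p_value`, per-group observed and
#'   expected event counts.
#' @export
log_rank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2 || any(table(group) < 1))
    stop("log_rank needs exactly two nonempty groups", call. = FALSE)
  df <- data.frame(time = time, event = event, group = group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(chi_square = unname(sd_$chisq), df = length(sd_$n) - 1,
       p_value = stats::pchisq(sd_$chisq, length(sd_$n) - 1,
                               lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

#' Youden-optimal ROC cutoff
#'
#' Scans candidate thresholds at the midpoints between consecutive distinct
#' observed scores (larger scores indicating events, the orientation of all
#' adipose parameters here) and returns the threshold maximizing Youden's
#' J = sensitivity + specificity - 1. Ties are broken toward higher
#' sensitivity, i.e. the lowest tied threshold.
#'
#' @param scores numeric vector.
#' @param event_labels logical or 0/1 vector; both classes must be present.
#' @return A one-row data.frame of class `cutoff_result`: `threshold`,
#'   `sensitivity`, `specificity`, `youden_j`.
#' @export
optimal_cutoff <- function(scores, event_labels) {
  event <- as.logical(event_labels)
  if (length(scores) != length(event))
    stop("scores and labels must have equal length", call. = FALSE)
  if (!any(event) || all(event))
    stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2)
    stop("scores are constant: no candidate thresholds", call. = FALSE)
  cand <- (u[-1] + u[-length(u)]) / 2
  sens <- vapply(cand, function(th) mean(scores[event] >= th), numeric(1))
  spec <- vapply(cand, function(th) mean(scores[!event] < th), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # lowest threshold among ties
  out <- data.frame(threshold = cand[best], sensitivity = sens[best],
                    specificity = spec[best], youden_j = j[best])
  class(out) <- c("cutoff_result", "data.frame")
  out
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Recurrence rates stratified by stage and a dichotomized score
#'
#' Within each stage stratum, counts recurrences among patients below
#' (`low`) and at/above (`high`) the cutoff, reports percentages rounded
#' half-up to one decimal, and compares the two arms with a two-sided
#' Fisher's exact test. Strata with an empty arm are flagged not-evaluable.
#'
#' @param data cohort data.frame.
#' @param score_col numeric column to dichotomize (e.g. `"tat_hu"`).
#' @param cutoff threshold; `high` means `score >= cutoff`.
#' @param strata named list mapping stratum labels to stage levels, default
#'   `list("T1" = "T1", "T2-T3" = c("T2", "T3"))`.
#' @param stage_col,event_col stage and event indicator columns.
#' @return A data.frame with one row per stratum: event/total counts and
#'   percentages per arm, Fisher p-value, and an `evaluable` flag.
#' @export
stratified_recurrence_table <- function(data, score_col, cutoff,
                                        strata = list("T1" = "T1",
                                                      "T2-T3" = c("T2", "T3")),
                                        stage_col = "t_stage",
                                        event_col = "recurrence") {
  rows <- lapply(names(strata), function(lab) {
    sub <- data[data[[stage_col]] %in% strata[[lab]], , drop = FALSE]
    high <- sub[[score_col]] >= cutoff
    ev <- as.logical(sub[[event_col]])
    n_low <- sum(!high); n_high <- sum(high)
    e_low <- sum(ev & !high); e_high <- sum(ev & high)
    evaluable <- n_low > 0 && n_high > 0
    p <- NA_real_
    if (evaluable) {
      tab <- matrix(c(e_low, n_low - e_low, e_high, n_high - e_high),
                    nrow = 2, byrow = TRUE)
      p <- stats::fisher.test(tab)$p.value
    }
    data.frame(stratum = lab,
               low_events = e_low, low_total = n_low,
               low_pct = if (n_low > 0)
                 round_half_up(100 * e_low / n_low, 1) else NA_real_,
               high_events = e_high, high_total = n_high,
               high_pct = if (n_high > 0)
                 round_half_up(100 * e_high / n_high, 1) else NA_real_,
               fisher_p = p, evaluable = evaluable)
  })
  do.call(rbind, rows)
}
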