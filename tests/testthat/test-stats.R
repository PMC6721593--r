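test_that("concordance correlation matches hand-computed values", {
  expect_equal(concordance_correlation(c(1, 2, 3), c(1, 2, 3))$estimate, 1)
  ccc <- concordance_correlation(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ccc$estimate, 4 / 7, tolerance = 1e-12)
  expect_true(ccc$ci_lo <= ccc$estimate && ccc$estimate <= ccc$ci_hi)
  expect_equal(concordance_correlation(c(-1, 0, 1), c(1, 0, -1))$estimate, -1)
  expect_error(concordance_correlation(rep(1, 5), 1:5), "variance")
})

test_that("CCC is symmetric and bounded by the Pearson correlation", {
  set.seed(101)
  for (i in 1:10) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30, sd = 0.7) + runif(1, -1, 1)
    a <- concordance_correlation(x, y)$estimate
    b <- concordance_correlation(y, x)$estimate
    expect_equal(a, b, tolerance = 1e-12)
    expect_lte(abs(a), abs(cor(x, y)) + 1e-12)
  }
})

test_that("paired t test matches hand arithmetic and rejects degeneracy", {
  y <- c(5, 9, 2)
  x <- y + c(1, 2, 3)  # differences mean 2, sd 1
  res <- paired_t_test(x, y)
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  expect_error(paired_t_test(y, y), "zero-variance")
  # simulated cohort: TAT systematically above CAT
  co <- simulate_cohort(cohort_spec(), seed = 2)
  res2 <- paired_t_test(co$tat_hu, co$cat_hu)
  expect_gt(res2$mean_difference, 0)
  expect_lt(res2$p_value, 0.001)
})

test_that("group comparison: Student t for 2 groups, Kruskal-Wallis beyond", {
  two <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_identical(two$method, "student_t")
  expect_equal(two$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  kw <- group_compare(c(1:3, 4:6, 7:9), rep(c("a", "b", "c"), each = 3))
  expect_identical(kw$method, "kruskal_wallis")
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)  # hand rank arithmetic
  # Conover-Iman on the same fixture, frozen from hand computation:
  # S2 = 7.5, pooled scale = 1, se = sqrt(2/3), t = 3 / se
  ph <- kw$posthoc
  expect_equal(nrow(ph), 3)
  t12 <- ph$statistic[ph$group1 == "a" & ph$group2 == "b"]
  expect_equal(abs(t12), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ph$p_value[ph$group1 == "a" & ph$group2 == "b"],
               2 * pt(-3 / sqrt(2 / 3), 6), tolerance = 1e-12)
  # identical distributions: H = 0, p = 1, no post-hoc
  same <- group_compare(rep(1:10, 3), rep(c("a", "b", "c"), each = 10))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_null(same$posthoc)
  expect_error(group_compare(1:5, c("a", "a", "a", "a", "b")), ">= 2 members")
})

test_that("well-separated groups are all distinguished post hoc", {
  set.seed(5)
  vals <- c(rnorm(40, 0), rnorm(40, 2), rnorm(40, 4))
  g <- rep(c("T1", "T2", "T3"), each = 40)
  res <- group_compare(vals, g)
  expect_lt(res$p_value, 0.001)
  expect_true(all(res$posthoc$p_value < 0.05))
})

test_that("Spearman correlation matches the rank formula", {
  mono <- spearman_correlation(1:10, exp(1:10))
  expect_equal(mono$rho, 1)
  res <- spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6, tolerance = 1e-12)  # 1 - 6*4/(4*15)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("Cox coefficients match the grid-search partial likelihood oracle", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  df <- data.frame(followup_months = time, recurrence = event, x = x)
  fit <- cox_regression(df, "x")
  expect_lt(abs(fit$coefficient - cox_pl_oracle(time, event, x)), 1e-3)
  # random tie-free fixtures up to 8 subjects
  set.seed(17)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    d <- data.frame(followup_months = sample(seq(1, 40), n),
                    recurrence = rbinom(n, 1, 0.8),
                    x = round(rnorm(n), 2))
    if (sum(d$recurrence) < 2 || length(unique(d$x)) < 2) next
    f <- tryCatch(cox_regression(d, "x"), error = function(e) NULL)
    if (is.null(f)) next  # separation in a random tiny fixture
    expect_lt(abs(f$coefficient -
                    cox_pl_oracle(d$followup_months, d$recurrence, d$x)),
              1e-3)
  }
})

test_that("Cox regression handles null, divergent and invalid inputs", {
  set.seed(23)
  n <- 400
  df <- data.frame(followup_months = rexp(n, 0.01),
                   recurrence = rbinom(n, 1, 0.5),
                   grp = factor(sample(c("lo", "hi"), n, replace = TRUE),
                                levels = c("lo", "hi")))
  fit <- cox_regression(df, "grp")
  expect_lt(abs(fit$coefficient), 0.35)
  expect_true(fit$ci_lo <= fit$hazard_ratio && fit$hazard_ratio <= fit$ci_hi)
  # monotone likelihood: covariate perfectly orders the event times
  sep <- data.frame(followup_months = 1:4, recurrence = 1,
                    x = c(3, 2, 1, 0))
  expect_error(cox_regression(sep, "x"), "diverged")
  expect_error(cox_regression(df, "nope"), "missing columns")
  df$const <- 1
  expect_error(cox_regression(df, "const"), "constant")
  df0 <- df; df0$recurrence <- 0
  expect_error(cox_regression(df0, "grp"), "no events")
})

test_that("Kaplan-Meier matches hand product-limit values", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(survival_at(km2, 1), 2 / 3)
  expect_equal(survival_at(km2, 2.5), 2 / 3)
  expect_equal(survival_at(km2, 3), 0)
  expect_equal(survival_at(km2, 0.5), 1)
  cens <- kaplan_meier(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(cens$surv == 1))
  # without censoring the estimator is the empirical survivor function
  set.seed(9)
  t <- sort(sample(1:100, 20)); e <- rep(1, 20)
  km3 <- kaplan_meier(t, e)
  expect_equal(km3$surv, 1 - seq_along(t) / 20)
})

test_that("log-rank agrees with the observed-expected oracle", {
  t <- c(1, 2, 3, 4, 5, 6); e <- rep(1, 6)
  g <- rep(c("A", "B"), 3)
  res <- log_rank(t, e, g)
  expect_equal(res$chi_square, logrank_oracle(t, e, g), tolerance = 1e-9)
  # identical groups: statistic 0
  same <- log_rank(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                   rep(c("A", "B"), each = 3))
  expect_lt(same$chi_square, 1e-9)
  expect_error(log_rank(t, e, rep("A", 6)), "two nonempty")
})

test_that("Youden cutoff scan matches exhaustive enumeration", {
  perfect <- optimal_cutoff(c(10, 12, 1, 2), c(1, 1, 0, 0))
  expect_equal(perfect$threshold, 6)
  expect_equal(perfect$youden_j, 1)
  tied <- optimal_cutoff(c(3, 5, 2, 4), c(1, 1, 0, 0))
  expect_equal(tied$threshold, 2.5)  # tie broken toward higher sensitivity
  expect_equal(tied$youden_j, 0.5)
  set.seed(31)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    s <- round(rnorm(n), 1)
    lab <- rbinom(n, 1, 0.4)
    if (!any(lab) || all(lab) || length(unique(s)) < 2) next
    res <- optimal_cutoff(s, lab)
    orc <- youden_scan_oracle(s, lab)
    expect_equal(res$threshold, orc$th)
    expect_equal(res$youden_j, orc$j, tolerance = 1e-12)
  }
  # uninformative scores: J stays near zero
  set.seed(32)
  null <- optimal_cutoff(rnorm(400), rbinom(400, 1, 0.5))
  expect_lt(null$youden_j, 0.25)
  expect_error(optimal_cutoff(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("Fisher exact p equals hypergeometric enumeration, transpose-safe", {
  tab <- matrix(c(14, 96, 14, 27), nrow = 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-9)
  expect_equal(fisher.test(t(tab))$p.value, p, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(rpois(4, 8), 2)
    expect_equal(fisher.test(m)$p.value, fisher_enum_oracle(m),
                 tolerance = 1e-9)
  }
})

test_that("stratified recurrence table counts, rounds and tests correctly", {
  co <- data.frame(
    t_stage = factor(c(rep("T1", 10), rep("T2", 6), rep("T3", 4))),
    tat_hu = c(rep(-90, 5), rep(-70, 5), rep(-90, 3), rep(-70, 3),
               rep(-90, 2), rep(-70, 2)),
    recurrence = c(rep(0, 10), 1, 0, 0, 1, 1, 0, 0, 0, 1, 1))
  tab <- stratified_recurrence_table(co, "tat_hu", cutoff = -82.5)
  expect_equal(tab$stratum, c("T1", "T2-T3"))
  # T1: zero recurrences in both arms
  expect_equal(tab$low_pct[1], 0)
  expect_equal(tab$high_pct[1], 0)
  expect_equal(tab$fisher_p[1], 1)
  t23 <- tab[2, ]
  expect_equal(t23$low_events + t23$high_events, 5)
  expect_equal(t23$low_total + t23$high_total, 10)
  m <- matrix(c(t23$low_events, t23$low_total - t23$low_events,
                t23$high_events, t23$high_total - t23$high_events),
              2, byrow = TRUE)
  expect_equal(t23$fisher_p, fisher.test(m)$p.value)
  # an empty stratum arm is flagged not evaluable
  co2 <- co[co$tat_hu < -80 | co$t_stage != "T1", ]
  tab2 <- stratified_recurrence_table(co2, "tat_hu", cutoff = -82.5)
  expect_false(tab2$evaluable[1])
  expect_true(is.na(tab2$fisher_p[1]))
})
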