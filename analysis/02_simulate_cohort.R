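#!/usr/bin/env Rscript

# Simulate the default 287-patient cohort: covariates at the published
# frequencies, contralateral fat attenuation Normal(-97.54, 7) HU with a
# negative BMI dependence, a stage/receptor-dependent tumor-adjacent shift,
# and recurrence times from an exponential proportional-hazards model
# (hazard ratio 1.10 per HU of TAT HU) calibrated to a ~10.5% event rate
# under administrative censoring on 6.1-88.9 months.

suppressPackageStartupMessages(library(adipoct))

dir.create("results", showWarnings = FALSE)
cohort <- simulate_cohort(cohort_spec(), seed = 20260101)
write.csv(cohort, "results/cohort.csv", row.names = FALSE)

base <- baseline_table(cohort)
write.csv(base, "results/baseline_table.csv", row.names = FALSE)

cat(sprintf("Simulated %d patients; %d recurrences (%.1f%%), median follow-up %.1f months\n",
            nrow(cohort), sum(cohort$recurrence),
            100 * mean(cohort$recurrence),
            median(cohort$followup_months)))
cat(sprintf("TAT HU median %.2f, CAT HU median %.2f, HU difference median %.2f\n",
            median(cohort$tat_hu), median(cohort$cat_hu),
            median(cohort$hu_difference)))
cat("Cohort written to results/cohort.csv, baseline table to results/baseline_table.csv\n")
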