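#!/usr/bin/env Rscript

# Run the full simulated study end to end and render every analysis table:
# baseline characteristics, reader agreement (Lin's CCC), adipose-parameter
# group comparisons, univariate Cox battery, the three multivariate
# adjustment models, ROC cutoffs with Kaplan-Meier 5-year RFS by arm, and
# the recurrence table stratified by T stage and dichotomized TAT HU.

suppressPackageStartupMessages(library(adipoct))

report <- run_study(study_config(seed = 20260101))
files <- render_tables(report, "results/report")

print(report)
cat("\nROC cutoffs and KM stratification:\n")
print(report$cutoffs, digits = 4, row.names = FALSE)
cat("\nStratified recurrence (TAT HU cutoff within T stage):\n")
print(report$stratified_recurrence, digits = 4, row.names = FALSE)
cat("\nAdipose terms of the multivariate models:\n")
print(report$multivariate[, c("model", "hazard_ratio", "ci_lo", "ci_hi",
                              "p_value")], digits = 4, row.names = FALSE)
cat("\n", length(files), "files rendered under results/report\n")
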