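#!/usr/bin/env Rscript
# Stage 5: validation-set performance report.
#
# MAD, RMSE, Pearson r, R2 (squared predicted-vs-chronological
# correlation) and adjusted R2, Bland-Altman agreement with 1.96-SD limits,
# and the age-binned accuracy table (bins 0-20-40-60-90, thresholds
# 3/4/5/6 years).
#
# Usage: Rscript analysis/05_evaluate.R

suppressPackageStartupMessages(library(epiage))

model <- read_model("results/model_unisex.json")
valid <- read_methylation_table("results/validation.csv")

rep <- evaluate_model(model, valid)
print(rep)
write_evaluation_report(rep,
                        json_path = "results/evaluation.json",
                        table_path = "results/accuracy_table.csv",
                        scatter_path = "results/bland_altman_points.csv")
cat("Wrote results/evaluation.json, results/accuracy_table.csv, results/bland_altman_points.csv\n")
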