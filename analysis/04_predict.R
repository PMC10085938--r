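#!/usr/bin/env Rscript
# Stage 4: apply the tuned unisex model to the validation set.
#
# Point predictions with backtransformation plus 95% residual-only
# prediction intervals; negative estimates (possible for extreme
# methylation profiles, since the backtransform is only bounded below by
# -1) are flagged, not clamped. Pass --published to use the shipped
# seven-CpG model instead of the tuned one (its markers must all be
# present in the table).
#
# Usage: Rscript analysis/04_predict.R [--published] [--level <p>]

suppressPackageStartupMessages(library(epiage))
args <- commandArgs(trailingOnly = TRUE)
level <- as.numeric(if (length(i <- which(args == "--level")) && i < length(args))
  args[i + 1L] else 0.95)

model <- if ("--published" %in% args) published_model() else
  read_model("results/model_unisex.json")
d <- read_methylation_table("results/validation.csv")

mk <- names(model$coefficients)
X <- as.data.frame(d)[mk]
complete <- stats::complete.cases(X)
pi <- prediction_interval(model, X[complete, , drop = FALSE], level = level)

out <- data.frame(sample_id = d$sample_id[complete],
                  chronological_age = d$age[complete],
                  estimated_age = pi$fit,
                  pi_lower = pi$lower, pi_upper = pi$upper,
                  flag_negative_estimate = pi$fit < 0)
utils::write.table(out, "results/predictions.csv", sep = ",",
                   row.names = FALSE, quote = FALSE)
cat(sprintf("Predicted %d samples (%d dropped for missing markers) at %.0f%% intervals.\n",
            nrow(out), sum(!complete), 100 * level))
cat(sprintf("Mean interval width %.2f years; %d negative estimates flagged.\n",
            mean(out$pi_upper - out$pi_lower), sum(out$flag_negative_estimate)))
cat("Wrote results/predictions.csv\n")
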