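#!/usr/bin/env Rscript
# Stage 1: simulate a study-shaped cohort.
#
# Generates 230 donors (102 male / 128 female), ages 1-88 years skewed
# toward a mean of ~38, with the eight-marker panel (SST-like marker
# missing in two thirds of samples) and methylation linear in transformed
# age at a generative cut-off of 20 years. Also emits the matching
# minisequencing peak-height table so stage 0 of the real workflow
# (peak quantification) can be exercised.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>]

suppressPackageStartupMessages(library(epiage))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed")) && i < length(args))
  args[i + 1L] else 1L)
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(seed = seed, age_distribution = "study")
sim <- generate_dataset(cfg)
d <- sim$dataset

write_methylation_table(d, "results/methylation_table.csv")
peaks <- generate_peak_table(d, seed = seed + 1L)
utils::write.table(peaks, "results/peak_table.csv", sep = ",",
                   row.names = FALSE, quote = FALSE)
jsonlite::write_json(list(
  seed = seed, n = nrow(d),
  n_male = sum(d$sex == "male"), n_female = sum(d$sex == "female"),
  age_mean = mean(d$age), age_range = range(d$age),
  generative_cutoff = cfg$generative_cutoff,
  marker_panel = cfg$markers
), "results/ground_truth.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("Simulated %d donors (%d M / %d F), ages %g-%g (mean %.1f), %d markers.\n",
            nrow(d), sum(d$sex == "male"), sum(d$sex == "female"),
            min(d$age), max(d$age), mean(d$age), length(dataset_markers(d))))
cat(sprintf("Peak table: %d marker calls; SST missing in %.1f%% of samples.\n",
            nrow(peaks), 100 * mean(is.na(d$SST))))
cat("Wrote results/methylation_table.csv, results/peak_table.csv, results/ground_truth.json\n")
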