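#!/usr/bin/env Rscript
# Condition-level statistics in the style of per-cell quantitative
# microscopy panels: mean +/- s.e.m per condition and two-tailed
# Student's t for every metric. Consumes the tables written by
# analysis/02 and 03 (re-running them if absent); writes results/report/.

suppressPackageStartupMessages(library(junctionquant))
if (!file.exists("results/profiles_all.csv"))
  source("analysis/02_compartment_ratios.R", local = new.env())

prof <- read.csv("results/profiles_all.csv")
pa <- prof[prof$channel == "markerA", ]
# unique per-cell ids across conditions
pa$uid <- paste(pa$condition, pa$cell_id, sep = "_")
metrics <- data.frame(cell_id = pa$uid,
                      ratio_membrane = pa$ratio_membrane,
                      ratio_nucleus = pa$ratio_nucleus,
                      intensity_per_area = pa$intensity_per_area)
conds <- data.frame(cell_id = pa$uid, condition = pa$condition)
rep <- batch_report(metrics, conds)
paths <- write_report(rep, "results/report")

shift <- nuclear_membrane_shift(
  transform(prof, cell_id = paste(condition, cell_id, sep = "_")),
  data.frame(cell_id = paste(prof$condition, prof$cell_id, sep = "_"),
             condition = prof$condition))
write.csv(shift, "results/report/nuclear_membrane_shift.csv",
          row.names = FALSE)

print(rep$comparisons[, c("metric", "mean_a", "mean_b", "sem_a", "sem_b",
                          "p_value", "stars")], digits = 3)
cat("report bundle written to results/report\n")
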