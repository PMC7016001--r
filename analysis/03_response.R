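#!/usr/bin/env Rscript
# Response-to-loading analysis: pixel-count collapse under loading
# (repeated-measures ANOVA) and the per-sample Delta1/Delta2 statistics.

suppressMessages(library(meniscusqmri))

analysis <- readRDS("scratch/analysis.rds")

pc <- analysis$pixel_counts
wide <- reshape(pc, idvar = "sample", timevar = "load", direction = "wide")
counts <- as.matrix(wide[, -1])
cat("mean analysis-mask pixels:",
    paste(round(colMeans(counts)), collapse = " > "), "\n")
rm_anova <- compare_pixel_counts(counts)
print(rm_anova)

dl <- analysis$deltas
agg <- aggregate(value ~ contrast + roi + delta, dl, function(v)
  c(mean = mean(v, na.rm = TRUE), sd = sd(v[!is.na(v)])))
agg <- do.call(data.frame, agg)
names(agg)[4:5] <- c("mean_pct", "sd_pct")
write.csv(agg, "results/delta_summary.csv", row.names = FALSE)
cat("\ncohort Delta2 for T1 (percent, decreases negative):\n")
print(subset(agg, contrast == "T1" & delta == "Delta2"))
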