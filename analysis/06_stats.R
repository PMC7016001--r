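#!/usr/bin/env Rscript
# The statistical plan: loading effects (Friedman + Dunn), grade effects
# (Kruskal-Wallis), Delta comparisons (t-test / ANOVA), and the
# qMRI-stiffness Spearman correlations, all at alpha = 0.005.

suppressMessages(library(meniscusqmri))

analysis <- readRDS("scratch/analysis.rds")
alpha <- 0.005

t1 <- table1_report(analysis, alpha = alpha)
fr <- t1$friedman
sig_t1 <- subset(fr, group == "all" & contrast == "T1" & p <= alpha)
cat("T1 loading effect significant in", nrow(sig_t1), "of 4 ROIs (all samples)\n")

apexI <- subset(fr, group == "I" & contrast == "T1rho" & roi == "I")
base3 <- subset(fr, group == ">=III" & contrast == "T1rho" & roi == "III")
cat(sprintf("apex T1rho, intact subgroup: p = %.2g (%s)\n",
            apexI$p, apexI$flags))
cat(sprintf("base T1rho, >=III subgroup: p = %.2g (%s)\n",
            base3$p, base3$flags))

t2 <- table2_report(analysis, alpha = alpha)
co <- correlation_report(analysis)
cat("\nSpearman rho, unloaded entire-sample medians vs Elastic Modulus:\n")
print(transform(co, rho = round(rho, 2), p = signif(p, 2)))

dir.create("results", showWarnings = FALSE)
write.csv(fr, "results/friedman_tests.csv", row.names = FALSE)
write.csv(t1$kruskal, "results/kruskal_tests.csv", row.names = FALSE)
write.csv(t2$tests, "results/delta_tests.csv", row.names = FALSE)
write.csv(co, "results/correlations.csv", row.names = FALSE)
cat("\nstatistical reports written under results/\n")
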