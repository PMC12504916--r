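#!/usr/bin/env Rscript

# Stage the Becker-dystrophy muscles by baseline fat fraction (preserved
# <= 13.5%, progressing in between, end-stage >= 81.5% and excluded),
# then produce the descriptive cohort summary (median [IQR] per group and
# biomarker) and the between-biomarker Spearman correlations.
#
# Reads results/metrics.csv; writes results/summary.csv and
# results/correlations.csv.

library(p31quant)

metrics <- read.csv("results/metrics.csv")
metrics$category <- ifelse(metrics$group == "CTRL", "CTRL",
                           categorize(metrics$ff_baseline))
n_end <- sum(metrics$category == "BMD_end")
analyzed <- metrics[metrics$category != "BMD_end", ]
message(sprintf("%d end-stage muscles excluded from the summary.", n_end))

summary_tab <- summarize_cohort(analyzed)
write.csv(summary_tab, "results/summary.csv", row.names = FALSE)
print(summary_tab)

pairs <- combn(c("mg", "ph_wt", "pde_gatp"), 2)
cors <- apply(pairs, 2, function(p) {
  ok <- is.finite(analyzed[[p[1]]]) & is.finite(analyzed[[p[2]]])
  s <- spearman(analyzed[[p[1]]][ok], analyzed[[p[2]]][ok])
  data.frame(x = p[1], y = p[2], rho = s$rho, p = s$p, n = s$n)
})
cors <- do.call(rbind, cors)
write.csv(cors, "results/correlations.csv", row.names = FALSE)
print(cors)
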