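#!/usr/bin/env Rscript
# Stage 5: dual-reporter statistics for the simulated validation assay:
# GFP:mCherry ratios per replicate, fold change of each construct versus
# the 21-bp spacer control, and ANOVA + Tukey-HSD group letters.

library(insulatr)

fixture <- file.path("results", "fixture")
records <- read_assay(file.path(fixture, "assay.tsv"))

rt <- ratios(records)
summ <- fold_change_vs_control(rt$summary, control = "spacer21")
grp <- compare_groups(rt$per_replicate, alpha = 0.05)
summ$letters <- grp$letters$letters[match(summ$construct_id,
                                          grp$letters$construct_id)]
summ$gfp_pct_of_control <- round(100 * (1 + summ$fc), 1)
summ <- summ[order(summ$fc), ]

write.table(summ, file.path("results", "assay_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("one-way ANOVA across %d constructs: p = %.3g\n",
            nrow(summ), grp$anova_p))
for (i in seq_len(nrow(summ))) {
  cat(sprintf("  %-10s n=%d mean ratio %.4f  FC %+.3f  (GFP %.1f%% of control)  group %s\n",
              summ$construct_id[i], summ$n[i], summ$mean_ratio[i],
              summ$fc[i], summ$gfp_pct_of_control[i], summ$letters[i]))
}
cat("constructs sharing no letter differ at alpha = 0.05 (Tukey HSD)\n")
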