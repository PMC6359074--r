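#!/usr/bin/env Rscript
# Per-metabolite statistics: two-way Type-II ANOVA (diet, reaction norm,
# interaction) with the post hoc extreme-class t contrast, regression on
# triglyceride level, the importance-vs-significance set comparison, and
# PCA sanity checks (all metabolites vs the top-10 diet differentiators).

suppressMessages(library(metshift))

tab <- read_abundance_table("results/table_preprocessed.tsv",
                            log_transformed = TRUE)
tab$log_base <- exp(1)
meta <- read_sample_metadata("results/meta.tsv")

an <- anova_two_way(tab, meta)
write.table(an, "results/univariate_anova.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("metabolites with raw p < 0.05: diet %d, reaction norm %d, interaction %d\n",
            sum(an$p_diet < 0.05), sum(an$p_rn < 0.05),
            sum(an$p_interaction < 0.05)))
cat(sprintf("after BH correction (q < 0.05): diet %d, reaction norm %d\n",
            sum(an$q_diet < 0.05), sum(an$q_rn < 0.05)))

tr <- triglyceride_regression(tab, meta)
write.table(tr, "results/triglyceride_regression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
neg <- tr$metabolite[tr$q < 0.05 & tr$r < 0]
cat(sprintf("metabolites negatively correlated with triglyceride (q < 0.05): %d\n",
            length(neg)))

imp <- read.delim("results/importance_diet.tsv")
ov <- importance_significance_overlap(imp, setNames(an$p_diet, an$metabolite))
cat(sprintf("of %d diet-significant metabolites, %d are not among the %d most important\n",
            ov$n_significant, ov$significant_not_important,
            ov$n_important_considered))

pc_all <- pca_scores(tab)
pc_top <- pca_scores(tab, head(imp$metabolite, 10))
sep_stat <- function(pc) {
  s1 <- pc$scores[, 1]
  abs(mean(s1[meta$diet == "HFD"]) - mean(s1[meta$diet == "ND"])) /
    sd(s1)
}
cat(sprintf("PC1 diet separation (|standardized mean difference|): all %d metabolites %.2f; top 10 %.2f\n",
            ncol(tab$values), sep_stat(pc_all), sep_stat(pc_top)))
cat(sprintf("PC1 variance fraction: all %.2f; top-10 %.2f\n",
            pc_all$variance_fraction[1], pc_top$variance_fraction[1]))
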