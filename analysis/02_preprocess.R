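#!/usr/bin/env Rscript
# Preprocess the simulated feature table the way the pipeline expects real
# exports to be treated: impute each metabolite's missing cells to its
# minimum detected value, log-transform, and screen for outlier samples by
# the robust z-score of per-sample median abundance (removal stays an
# explicit, logged step; none is expected on clean synthetic data).

suppressMessages(library(metshift))

tab <- read_abundance_table("results/table_raw.tsv")
pp <- impute_min_and_log(tab)
cat(sprintf("imputed %d of %d cells to per-metabolite minima, natural log\n",
            pp$report$imputed_cell_count, length(tab$values)))

scores <- flag_outlier_samples(pp$table, robust_z_cutoff = 5)
write.table(scores, "results/outlier_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
flagged <- scores$sample_id[scores$flagged]
if (length(flagged)) {
  cat("flagged outlier samples:", paste(flagged, collapse = ", "), "\n")
  pp$table <- drop_samples(pp$table, flagged)
} else cat("no outlier samples flagged (cutoff 5)\n")

write_abundance_table(pp$table, "results/table_preprocessed.tsv")
cat("wrote results/table_preprocessed.tsv\n")
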