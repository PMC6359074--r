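#!/usr/bin/env Rscript
# Network-difference statistics: edge symmetric difference between the
# ground-truth condition graphs, an edge-count-matched Pearson correlation
# baseline for the complete data, the three-way edge overlap
# (HFD / ND / complete) with per-edge correlations, and the p-value of the
# matched correlation cutoff.

suppressMessages(library(metshift))

tab <- read_abundance_table("results/table_preprocessed.tsv",
                            log_transformed = TRUE)
tab$log_base <- exp(1)
meta <- read_sample_metadata("results/meta.tsv")
g_nd <- read_edge_list("results/truth/graph_nd.tsv")
g_hfd <- read_edge_list("results/truth/graph_hfd.tsv")

e <- esd(g_hfd, g_nd)
cat("truth-network edge symmetric difference: "); print(e)

mt <- match_edge_count_threshold(tab, 129)
cat(sprintf("correlation network matched to 129 edges: cutoff |r| = %.4f, %d edges\n",
            mt$threshold, mt$achieved_edges))
cat(sprintf("cutoff p-value at n = %d: %.3g\n", nrow(tab$values),
            as.numeric(correlation_pvalue(mt$threshold, nrow(tab$values)))))
write_edge_list(mt$network, "results/corrnet_edges.tsv")

sub_nd <- subset_samples(tab, meta, meta$diet == "ND")$table
sub_hfd <- subset_samples(tab, meta, meta$diet == "HFD")$table
fit_c <- read_edge_list("results/ggm_complete_edges.tsv")
fit_nd <- read_edge_list("results/ggm_nd_edges.tsv")
fit_hfd <- read_edge_list("results/ggm_hfd_edges.tsv")
ov <- overlap3(fit_hfd, fit_nd, fit_c,
               tables = list(HFD = sub_hfd, ND = sub_nd, complete = tab))
print(ov)
write.table(ov$per_edge, "results/overlap3_per_edge.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if ("membership_not_highest_r" %in% names(ov$per_edge))
  cat(sprintf("edges whose own dataset lacks the highest |r|: %d of %d\n",
              sum(ov$per_edge$membership_not_highest_r, na.rm = TRUE),
              nrow(ov$per_edge)))
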