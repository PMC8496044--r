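#!/usr/bin/env Rscript
# Stage 2: per-patient DDR pathway profiling.
#
# Median-scales the cohort gene by gene, ranks each sample's genes, and
# runs the weighted running-sum enrichment statistic for all 27 DDR
# pathways with a 1000-permutation gene-label null, giving a samples x
# pathways NES matrix.  Hierarchical clustering (Euclidean, average
# linkage) orders both axes for the pathway heatmap.

suppressPackageStartupMessages(library(ddrimmune))

seed <- 1L
expr <- read_expression("results/cohort/expression.tsv")
ddr <- read_gmt("results/cohort/ddr.gmt")

activity <- score_cohort(expr, ddr, n_perm = 1000,
                         seed = stage_seed(seed, "score"))
print(activity)

write_matrix_tsv(activity$nes, "results/ddr_nes.tsv", id_label = "sample")
write.table(activity$results, "results/ddr_enrichment_long.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cl <- cluster_matrix(activity$nes, axis = "both")
jsonlite::write_json(
  list(rows = rownames(activity$nes)[cl$row_order],
       columns = colnames(activity$nes)[cl$col_order]),
  "results/ddr_nes_clustering.json", auto_unbox = TRUE, digits = NA)

if (requireNamespace("pheatmap", quietly = TRUE)) {
  grDevices::png("results/ddr_nes_heatmap.png", width = 1400, height = 900)
  pheatmap::pheatmap(activity$nes, clustering_method = "average",
                     fontsize_col = 7, fontsize_row = 5,
                     main = "DDR pathway NES per sample")
  grDevices::dev.off()
}

sig_frac <- mean(activity$results$fdr_q < 0.25)
cat(sprintf("scored %d samples x %d pathways; %.1f%% of cells at q < 0.25\n",
            nrow(activity$nes), ncol(activity$nes), 100 * sig_frac))
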