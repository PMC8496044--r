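#!/usr/bin/env Rscript
# Stage 4: DDR-immune correlation matrices.
#
# Correlates every DDR pathway's NES against every immune feature
# (Spearman, BH over the whole matrix), and the DDR pathways against each
# other, then reports which pathway is most negatively associated with the
# immune content score.

suppressPackageStartupMessages(library(ddrimmune))

nes <- read_expression("results/ddr_nes.tsv")            # samples x pathways
imm_raw <- read.delim("results/immune_features.tsv", check.names = FALSE)
kinds <- unlist(imm_raw[1, -1])
imm <- as.matrix(imm_raw[-1, -1, drop = FALSE])
storage.mode(imm) <- "double"
rownames(imm) <- imm_raw[-1, 1]
imm <- imm[rownames(nes), , drop = FALSE]

ddr_immune <- spearman_matrix(nes, imm)
ddr_ddr <- spearman_matrix(nes)

for (nm in c("rho", "p", "q")) {
  write_matrix_tsv(ddr_immune[[nm]], sprintf("results/ddr_immune_%s.tsv", nm),
                   id_label = "pathway")
  write_matrix_tsv(ddr_ddr[[nm]], sprintf("results/ddr_ddr_%s.tsv", nm),
                   id_label = "pathway")
}
write.table(ddr_immune$long, "results/ddr_immune_long.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

content_col <- ddr_immune$rho[, "immune_content_score"]
ranked <- sort(content_col)
cat("DDR pathways most negatively correlated with the immune content score:\n")
print(round(head(ranked, 5), 3))
top <- names(ranked)[1]
cat(sprintf("\nstrongest negative association: %s (rho = %.3f, q = %.3g)\n",
            top, ranked[1],
            ddr_immune$q[top, "immune_content_score"]))
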