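#!/usr/bin/env Rscript
# Stage 3: per-patient immune landscape.
#
# Builds the immune feature block: the immune content score (mean
# across-sample z-score of the immune-specific gene list), NES of the
# immune pathway collection, and cell-type fractions from non-negative
# least squares against the signature matrix.

suppressPackageStartupMessages(library(ddrimmune))

seed <- 1L
expr <- read_expression("results/cohort/expression.tsv")
immune_genes <- read_gene_list("results/cohort/immune_genes.txt")
immune_sets <- read_gmt("results/cohort/immune.gmt")
signature <- read_signature("results/cohort/signature.tsv")

features <- build_immune_features(expr, immune_genes = immune_genes,
                                  immune_sets = immune_sets,
                                  signature = signature, method = "nnls",
                                  n_perm = 1000,
                                  seed = stage_seed(seed, "immune"))
print(features)
write_immune_features(features, "results/immune_features.tsv")

frac <- features$values[, features$kinds == "cell_fraction", drop = FALSE]
cat("mean cell-type fractions across the cohort:\n")
print(round(colMeans(frac), 3))
rmse <- mean(vapply(features$deconvolution, function(d) d$rmse, numeric(1)))
cat(sprintf("mean deconvolution RMSE (scaled space): %.3f\n", rmse))
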