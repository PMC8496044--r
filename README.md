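# ddrimmune

Patient-level profiling of DNA damage response (DDR) pathway activity from
bulk tumor transcriptomes, and its correlation with the tumor immune
landscape.

Tumors that repair DNA efficiently tend to present fewer immunogenic
signals; which *specific* repair sub-pathways track with a cold immune
microenvironment is the question this package operationalizes.  It takes a
log2 expression matrix (genes × samples), scores 27 curated DDR pathways in
every sample, builds per-sample immune features (an immune content score,
immune pathway activity, deconvolved immune-cell fractions), and asks which
DDR pathways correlate — typically negatively — with immune infiltration.
It is aimed at computational biologists analyzing bulk RNA-Seq tumor
cohorts, and ships a synthetic cohort generator with planted ground truth
so the entire analysis is testable without any external data.

## Method

**Per-sample pathway activity.** Expression is median-scaled gene by gene
(x_gs − median_s x_gs), each sample's genes are ranked by the centered
value (descending, ties broken by symbol), and each pathway G is scored
with the weighted Kolmogorov–Smirnov running sum: walking down the ranked
list, hits add |r_i|^w / Σ_{j∈G} |r_j|^w and misses subtract 1/(N − |G|);
the enrichment score ES is the extremum of the running sum (w = 1 by
default).  A gene-label permutation null (1000 random same-size sets)
calibrates each score:

    NES = ES / mean(|ES_null|, same sign),   p = (1 + #{|ES_null| ≥ |ES|, same sign}) / (1 + #same-sign)

with Benjamini–Hochberg correction per sample across pathways.  The result
is a samples × 27 NES matrix, hierarchically clustered for the pathway
heatmap.

**Immune landscape.** The immune content score of a sample is the mean
across-sample z-score of an immune-specific gene list; immune pathway NES
come from the same enrichment engine; cell-type fractions come from
non-negative least squares (or ν-SVR) of the sample on a signature matrix
over shared genes, clipped and renormalized to the simplex.

**Association.** Every DDR pathway × immune feature pair gets Spearman's ρ
(average ranks for ties; exact permutation p below n = 10, t approximation
otherwise) with BH correction over the whole matrix as one family.  A
two-tailed Fisher's exact test and fold-change quartile grouping support
the proteomics-style over-representation side analysis.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic cohort (80 samples × 12,000 genes, target Spearman ρ = −0.6
planted between the homologous-DNA-pairing/strand-exchange latent and the
immune infiltration latent):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_score_pathways.R
Rscript analysis/03_immune_landscape.R
Rscript analysis/04_correlate.R
Rscript analysis/05_protein_ora.R
```

Stage 1 reports the cohort it built:

```
SyntheticCohort: 12000 genes x 80 samples, 27 planted pathways
  designated pathway: HOMOLOGOUS_DNA_PAIRING_AND_STRAND_EXCHANGE (target rho -0.60, realized -0.617)
```

and stage 4 recovers that structure from expression alone:

```
DDR pathways most negatively correlated with the immune content score:
HOMOLOGOUS_DNA_PAIRING_AND_STRAND_EXCHANGE
                                    -0.605
              NUCLEOTIDE_POOL_SANITIZATION
                                    -0.231
...
strongest negative association: HOMOLOGOUS_DNA_PAIRING_AND_STRAND_EXCHANGE (rho = -0.605, q = 2.47e-07)
```

The estimated ρ = −0.605 is the pipeline's end-to-end read-out of the
planted −0.6: the strand-exchange pathway's per-sample NES, computed from
ranked expression with no knowledge of the latents, anti-correlates with
the immune content score, and no other DDR pathway comes close.  All
tables land under `results/` (NES matrix, long enrichment table, immune
features, ρ/p/q matrices, clustering orders).  Stage 5 shows the
fold-change quartile grouping and Fisher over-representation on a
synthetic protein table (planted set p = 7.9e-05, random control p = 0.3).

Programmatic use mirrors the scripts:

```r
library(ddrimmune)
cohort <- generate_cohort(cohort_config(seed = 1))
activity <- score_cohort(cohort$expr, cohort$collection, seed = 1)
features <- build_immune_features(cohort$expr,
                                  immune_genes = cohort$immune_genes,
                                  signature = cohort$signature, seed = 1)
cors <- spearman_matrix(activity$nes, features$values)
```

The packaged DDR collection (`ddr_pathways()`), immune gene list and
immune pathway GMT are synthetic, documented stand-ins — curated from
well-known pathway genes, not redistributed database files — and every
reader accepts user-supplied replacements.

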