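#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the generator's parameters.  Defaults describe a
#' mid-sized bulk RNA-Seq tumor cohort: 80 samples, 12,000 genes, a planted
#' rank correlation of -0.6 between the designated repair sub-pathway
#' latent and the immune infiltration latent, unit log2 effect per unit
#' latent and residual noise sd 0.3 on the log2 scale.
#'
#' @param n_samples number of samples (>= 8).
#' @param n_genes total genes in the simulated universe; must accommodate
#'   all pathway/immune/signature genes.
#' @param collection `GeneSetCollection` to plant; default [ddr_pathways()].
#' @param designated_pathway name of the set whose latent is coupled to the
#'   immune latent (the homologous DNA pairing and strand exchange analogue).
#' @param target_rho target Spearman correlation in (-1, 1) between the
#'   designated pathway latent and the immune latent.
#' @param effect_size log2 shift per unit latent for planted genes.
#' @param noise_sd residual Gaussian noise sd (log2 scale), > 0.
#' @param n_cell_types number of immune cell types in the signature (a
#'   stromal component is added on top).
#' @param immune_gene_count how many genes from the packaged immune list to
#'   plant (NULL = all).
#' @param mix_scale weight of the cell-mixture component added to
#'   signature genes' expression.
#' @param seed integer root seed.
#' @return a validated `CohortConfig` list.
#' @export
cohort_config <- function(n_samples = 80L, n_genes = 12000L,
                          collection = NULL,
                          designated_pathway = "HOMOLOGOUS_DNA_PAIRING_AND_STRAND_EXCHANGE",
                          target_rho = -0.6, effect_size = 1.0,
                          noise_sd = 0.3, n_cell_types = 5L,
                          immune_gene_count = NULL, mix_scale = 1.0,
                          seed = 1L) {
  if (is.null(collection)) collection <- ddr_pathways()
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (n_samples < 8L) stop("n_samples must be >= 8")
  if (abs(target_rho) >= 1) stop("target_rho must lie in (-1, 1)")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!designated_pathway %in% names(collection)) {
    stop("designated_pathway '", designated_pathway,
         "' not present in the collection")
  }
  if (n_cell_types < 2L) stop("need at least 2 immune cell types")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 collection = collection,
                 designated_pathway = designated_pathway,
                 target_rho = target_rho, effect_size = effect_size,
                 noise_sd = noise_sd, n_cell_types = as.integer(n_cell_types),
                 immune_gene_count = immune_gene_count,
                 mix_scale = mix_scale, seed = as.integer(seed)),
            class = "CohortConfig")
}

# Dirichlet draws via normalized gammas; alpha may differ per row.
rdirichlet_rows <- function(alpha_matrix) {
  g <- matrix(stats::rgamma(length(alpha_matrix), shape = alpha_matrix),
              nrow = nrow(alpha_matrix))
  sweep(g, 1, rowSums(g), "/")
}

# Curated immune lineage markers used for synthetic signature columns.
immune_marker_table <- function() {
  list(
    T_cells_CD8 = c("CD8A", "CD8B", "GZMK", "GZMA", "PRF1", "KLRG1", "EOMES",
                    "LAG3", "CD3D", "CCL4"),
    T_cells_CD4 = c("CD4", "IL7R", "CD3E", "CD28", "CCR7", "TCF7", "LTB",
                    "CD40LG", "ICOS", "SELL"),
    B_cells = c("CD19", "MS4A1", "CD79A", "CD79B", "BLNK", "IGHM", "TCL1A",
                "BANK1", "CR2", "FCRL2"),
    NK_cells = c("NKG7", "KLRD1", "KLRF1", "NCR1", "GNLY", "FGFBP2", "XCL1",
                 "XCL2", "KIR2DL3", "PRF1"),
    Monocytes = c("CD14", "LYZ", "FCN1", "S100A8", "S100A9", "CSF1R",
                  "ITGAM", "CD68", "MNDA", "FCGR3A"),
    Neutrophils = c("FCGR3B", "CSF3R", "CXCR2", "FPR1", "MME", "CEACAM8",
                    "ELANE", "MPO", "S100A12", "SLC25A37")
  )
}

#' Generate a synthetic immune-cell signature matrix
#'
#' Builds a genes x cell-types reference with marker-block structure: each
#' cell type's curated lineage markers are strongly expressed in its own
#' column and weakly elsewhere; a `Stromal` column with fibroblast-type
#' markers is appended so that the total immune fraction can vary between
#' samples.  Values are non-negative (linear abundance scale).  This is a
#' labelled synthetic stand-in, not a published reference profile.
#'
#' @param n_cell_types number of immune cell types (2-6).
#' @param include_stromal append the non-immune stromal column?
#' @param marker_high,marker_low mean abundance of a marker in its own /
#'   other columns.
#' @return genes x cell-types non-negative matrix; the immune columns are
#'   recorded in `attr(, "immune_cell_types")`.
#' @export
generate_signature <- function(n_cell_types = 5L, include_stromal = TRUE,
                               marker_high = 12, marker_low = 0.5) {
  marker_tab <- immune_marker_table()
  if (n_cell_types < 2L || n_cell_types > length(marker_tab)) {
    stop("n_cell_types must be between 2 and ", length(marker_tab))
  }
  marker_tab <- marker_tab[seq_len(n_cell_types)]
  stromal_markers <- c("COL1A1", "COL1A2", "FN1", "ACTA2", "PDGFRB", "THY1",
                       "DCN", "LUM", "FAP", "VIM")
  if (include_stromal) marker_tab$Stromal <- stromal_markers
  genes <- unique(unlist(marker_tab))
  types <- names(marker_tab)
  sig <- matrix(stats::rgamma(length(genes) * length(types), shape = 2,
                              scale = marker_low / 2),
                nrow = length(genes), dimnames = list(genes, types))
  for (ty in types) {
    m <- marker_tab[[ty]]
    sig[m, ty] <- sig[m, ty] +
      marker_high * (0.75 + 0.5 * stats::runif(length(m)))
  }
  attr(sig, "immune_cell_types") <- setdiff(types, "Stromal")
  sig
}

#' Generate a synthetic bulk expression cohort with planted structure
#'
#' Simulates, directly on the log2 scale, a tumor cohort with the
#' statistical structure the downstream analysis assumes:
#' \enumerate{
#'   \item per-sample pathway activity latents (standard Gaussian), with
#'     the designated pathway's latent and the immune infiltration latent
#'     drawn from a bivariate Gaussian whose Pearson parameter
#'     `2*sin(pi*target_rho/6)` makes their rank correlation equal
#'     `target_rho` (Gaussian copula);
#'   \item per-gene log-normal baselines, plus `effect_size` times the
#'     latent of every pathway containing the gene, plus `effect_size`
#'     times the immune latent for immune genes, plus Gaussian noise;
#'   \item per-sample cell-type fractions from a Dirichlet whose immune
#'     concentrations are tilted upward by the immune latent, and a
#'     cell-mixture expression component for signature genes;
#'   \item the signature matrix itself, via [generate_signature()].
#' }
#' Everything is a pure function of the configuration (including its seed).
#'
#' @param config a [cohort_config()].
#' @return a `SyntheticCohort`: list with `expr` (genes x samples, log2),
#'   `truth_latents` (samples x pathways + `immune_infiltration`),
#'   `truth_fractions` (samples x cell types, rows sum to 1),
#'   `immune_genes`, `signature`, `collection`, `config` and
#'   `realized_rho` (empirical Spearman between the designated latent and
#'   the immune latent).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  coll <- config$collection
  n_s <- config$n_samples

  immune_all <- immune_gene_list()
  immune_genes <- if (is.null(config$immune_gene_count)) immune_all
                  else utils::head(immune_all, config$immune_gene_count)
  signature <- generate_signature(config$n_cell_types)
  core <- unique(c(unlist(coll$sets), immune_genes, rownames(signature)))
  if (length(core) > config$n_genes) {
    stop(sprintf("pathway/immune/signature genes (%d) exceed n_genes (%d)",
                 length(core), config$n_genes))
  }
  filler <- setdiff(sprintf("GENE%05d", seq_len(config$n_genes)), core)
  filler <- filler[seq_len(config$n_genes - length(core))]
  genes <- c(core, filler)
  samples <- sprintf("S%03d", seq_len(n_s))

  # latents: one per pathway, plus the immune latent; designated + immune
  # share a Gaussian copula with the requested rank correlation
  r_pearson <- 2 * sin(pi * config$target_rho / 6)
  z1 <- stats::rnorm(n_s)
  z2 <- r_pearson * z1 + sqrt(1 - r_pearson^2) * stats::rnorm(n_s)
  latents <- matrix(stats::rnorm(n_s * length(coll)), nrow = n_s,
                    dimnames = list(samples, names(coll)))
  latents[, config$designated_pathway] <- z1
  immune_latent <- z2

  # per-gene pathway membership effect: sum of containing pathways' latents
  signal <- matrix(0, length(genes), n_s, dimnames = list(genes, samples))
  for (p in names(coll)) {
    g <- coll$sets[[p]]
    signal[g, ] <- signal[g, ] +
      config$effect_size * matrix(latents[, p], length(g), n_s, byrow = TRUE)
  }
  signal[immune_genes, ] <- signal[immune_genes, ] +
    config$effect_size * matrix(immune_latent, length(immune_genes), n_s,
                                byrow = TRUE)

  # cell fractions: stromal concentration fixed, immune concentrations
  # scaled by exp(0.7 * immune latent) so total immune fraction rises with it
  types <- colnames(signature)
  immune_types <- attr(signature, "immune_cell_types")
  alpha <- matrix(3, n_s, length(types), dimnames = list(samples, types))
  alpha[, immune_types] <- 1.5 * exp(0.7 * immune_latent)
  fractions <- rdirichlet_rows(alpha)
  dimnames(fractions) <- list(samples, types)

  mixture <- signature %*% t(fractions)          # linear scale
  signal[rownames(signature), ] <- signal[rownames(signature), ] +
    config$mix_scale * log2(1 + mixture)

  baseline <- stats::rlnorm(length(genes), meanlog = 1.0, sdlog = 0.6)
  expr <- baseline + signal +
    matrix(stats::rnorm(length(genes) * n_s, sd = config$noise_sd),
           length(genes), n_s)
  dimnames(expr) <- list(genes, samples)

  truth <- cbind(latents, immune_infiltration = immune_latent)
  structure(list(expr = expr, truth_latents = truth,
                 truth_fractions = fractions, immune_genes = immune_genes,
                 signature = signature, collection = coll, config = config,
                 realized_rho = spearman_rho(z1, immune_latent)),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d genes x %d samples, %d planted pathways\n",
              nrow(x$expr), ncol(x$expr), length(x$collection)))
  cat(sprintf("  designated pathway: %s (target rho %.2f, realized %.3f)\n",
              x$config$designated_pathway, x$config$target_rho,
              x$realized_rho))
  invisible(x)
}

#' Generate noisy mixtures of signature columns
#'
#' Fixture generator for the deconvolution step: draws flat-Dirichlet
#' cell-type fractions, mixes the signature columns accordingly and adds
#' Gaussian noise on the signature's own (linear) scale.
#'
#' @param signature genes x cell-types non-negative matrix.
#' @param n_samples number of mixtures.
#' @param noise_sd Gaussian noise sd; 0 gives exactly linear mixtures.
#' @param seed integer seed.
#' @return list with `mixtures` (genes x samples) and `truth_fractions`
#'   (samples x cell types, rows sum to 1).
#' @export
generate_mixture_set <- function(signature, n_samples, noise_sd = 0, seed = 1L) {
  validate_signature(signature)
  set.seed(as.integer(seed))
  k <- ncol(signature)
  fr <- rdirichlet_rows(matrix(1, n_samples, k))
  dimnames(fr) <- list(sprintf("M%03d", seq_len(n_samples)),
                       colnames(signature))
  mix <- signature %*% t(fr)
  if (noise_sd > 0) {
    mix <- mix + matrix(stats::rnorm(length(mix), sd = noise_sd),
                        nrow(mix), ncol(mix))
  }
  dimnames(mix) <- list(rownames(signature), rownames(fr))
  list(mixtures = mix, truth_fractions = fr)
}

#' Generate a synthetic protein fold-change table
#'
#' Simulates a tumor-vs-normal proteomic comparison: each protein is
#' upregulated with probability `frac_up`; log2 fold changes are
#' half-normal in the chosen direction.  Members of a planted set get
#' their odds of upregulation multiplied by `planted_or` and a fold-change
#' boost, so over-representation analysis should flag the set.
#'
#' @param n_proteins number of background proteins (planted members are
#'   drawn from them).
#' @param frac_up baseline probability of upregulation in (0, 1).
#' @param seed integer seed.
#' @param planted_size number of proteins in the planted set (0 = none).
#' @param planted_or odds multiplier for upregulation of planted members.
#' @return list with `table` (data.frame: protein, fold_change) and
#'   `planted_set` (character vector, possibly empty).
#' @export
generate_protein_table <- function(n_proteins = 500L, frac_up = 0.4,
                                   seed = 1L, planted_size = 25L,
                                   planted_or = 5) {
  if (frac_up <= 0 || frac_up >= 1) stop("frac_up must lie in (0, 1)")
  set.seed(as.integer(seed))
  ids <- sprintf("PROT%04d", seq_len(n_proteins))
  planted <- if (planted_size > 0) sample(ids, planted_size) else character(0)
  odds <- frac_up / (1 - frac_up)
  p_up <- ifelse(ids %in% planted, (odds * planted_or) / (1 + odds * planted_or),
                 frac_up)
  up <- stats::rbinom(n_proteins, 1, p_up) == 1
  mag <- abs(stats::rnorm(n_proteins, mean = 0.8, sd = 0.8))
  mag[ids %in% planted & up] <- mag[ids %in% planted & up] + 0.8
  fc <- ifelse(up, 2^mag, 2^-mag)
  list(table = data.frame(protein = ids, fold_change = fc,
                          stringsAsFactors = FALSE),
       planted_set = planted)
}

#' Write a complete synthetic input bundle to a directory
#'
#' Emits everything the pipeline reads: expression TSV, DDR and immune
#' GMTs, immune gene list, signature TSV and a truth JSON (latents,
#' fractions, realized correlation), so a run can be reproduced from files
#' alone.
#'
#' @param cohort a `SyntheticCohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    ddr_gmt = file.path(dir, "ddr.gmt"),
    immune_gmt = file.path(dir, "immune.gmt"),
    immune_genes = file.path(dir, "immune_genes.txt"),
    signature = file.path(dir, "signature.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix_tsv(cohort$expr, paths["expression"])
  write_gmt(cohort$collection, paths["ddr_gmt"])
  write_gmt(immune_pathways(), paths["immune_gmt"])
  writeLines(cohort$immune_genes, paths["immune_genes"])
  write_matrix_tsv(cohort$signature, paths["signature"], id_label = "gene")
  jsonlite::write_json(
    list(realized_rho = cohort$realized_rho,
         designated_pathway = cohort$config$designated_pathway,
         target_rho = cohort$config$target_rho,
         seed = cohort$config$seed,
         truth_latents = as.data.frame(cohort$truth_latents),
         truth_fractions = as.data.frame(cohort$truth_fractions)),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
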