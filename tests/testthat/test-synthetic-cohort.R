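# small planted collection shared by several tests (filler-gene members)
toy_collection <- function() {
  gene_set_collection(list(PWA = sprintf("TOYA%03d", 1:20),
                           PWB = sprintf("TOYB%03d", 1:15)),
                      source_label = "toy")
}

test_that("cohort generation is a pure function of its configuration", {
  cfg <- cohort_config(n_samples = 10, n_genes = 400,
                       collection = toy_collection(),
                       designated_pathway = "PWA", seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth_fractions, b$truth_fractions)
  expect_identical(a$realized_rho, b$realized_rho)
  c2 <- generate_cohort(cohort_config(n_samples = 10, n_genes = 400,
                                      collection = toy_collection(),
                                      designated_pathway = "PWA", seed = 6))
  expect_false(identical(a$expr, c2$expr))
})

test_that("generated cohorts satisfy their structural invariants", {
  co <- generate_cohort(cohort_config(n_samples = 12, n_genes = 600, seed = 2))
  expect_true(all(unlist(co$collection$sets) %in% rownames(co$expr)))
  expect_true(all(co$immune_genes %in% rownames(co$expr)))
  expect_equal(unname(rowSums(co$truth_fractions)), rep(1, 12), tolerance = 1e-12)
  expect_false(anyDuplicated(rownames(co$expr)) > 0)
  expect_identical(dim(co$expr), c(600L, 12L))
  expect_true(all(is.finite(co$expr)))
  # config validation
  expect_error(cohort_config(n_samples = 4), ">= 8")
  expect_error(cohort_config(target_rho = 1), "target_rho")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(designated_pathway = "NOPE"), "not present")
  expect_error(generate_cohort(cohort_config(n_genes = 100)), "exceed")
})

test_that("the Gaussian copula hits the target rank correlation on average", {
  rhos <- vapply(1:200, function(s) {
    generate_cohort(cohort_config(n_samples = 500, n_genes = 300,
                                  collection = toy_collection(),
                                  designated_pathway = "PWA",
                                  immune_gene_count = 10,
                                  seed = 1000 + s))$realized_rho
  }, numeric(1))
  expect_lt(abs(mean(rhos) - (-0.6)), 0.03)
})

test_that("an uncoupled generator gives near-zero realized correlation", {
  hits <- vapply(1:100, function(s) {
    r <- generate_cohort(cohort_config(n_samples = 80, n_genes = 300,
                                       collection = toy_collection(),
                                       designated_pathway = "PWA",
                                       immune_gene_count = 10,
                                       target_rho = 0,
                                       seed = 2000 + s))$realized_rho
    abs(r) < 0.25
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a zero effect size leaves planted pathways without enrichment signal", {
  co <- generate_cohort(cohort_config(n_samples = 16, n_genes = 500,
                                      collection = toy_collection(),
                                      designated_pathway = "PWA",
                                      effect_size = 0, seed = 31))
  pa <- score_cohort(co$expr, co$collection, n_perm = 200, seed = 7)
  expect_lt(abs(mean(pa$nes)), 0.4)
})

test_that("mixture sets are simplex-valid and exactly decomposable when noiseless", {
  sig <- generate_signature(4, include_stromal = FALSE)
  ms <- generate_mixture_set(sig, 5, noise_sd = 0, seed = 9)
  expect_equal(unname(rowSums(ms$truth_fractions)), rep(1, 5), tolerance = 1e-12)
  for (i in 1:5) {
    r <- deconvolve(ms$mixtures[, i], sig, method = "nnls")
    expect_equal(r$fractions, ms$truth_fractions[i, ], tolerance = 1e-6)
  }
  one <- generate_mixture_set(sig, 1, seed = 2)
  expect_identical(ncol(one$mixtures), 1L)
})

test_that("protein tables show the requested upregulation rate and planted signal", {
  pt <- generate_protein_table(n_proteins = 100, frac_up = 0.5, seed = 3,
                               planted_size = 0)
  n_up <- sum(pt$table$fold_change > 1)
  expect_true(abs(n_up - 50) < 20)   # binomial tolerance ~ 5 sd

  # planted set is flagged by ORA in >= 90% of seeds
  flagged <- vapply(1:50, function(s) {
    g <- generate_protein_table(n_proteins = 500, frac_up = 0.4,
                                seed = 100 + s, planted_size = 25,
                                planted_or = 5)
    fg <- g$table$protein[g$table$fold_change > 1]
    fisher_ora(fg, g$table$protein, g$planted_set)$p_two_tailed < 0.05
  }, logical(1))
  expect_gte(mean(flagged), 0.9)

  # without planting, ORA p-values over random sets are not inflated
  set.seed(41)
  ps <- vapply(1:100, function(s) {
    g <- generate_protein_table(n_proteins = 200, frac_up = 0.4,
                                seed = 300 + s, planted_size = 0)
    fg <- g$table$protein[g$table$fold_change > 1]
    fisher_ora(fg, g$table$protein,
               sample(g$table$protein, 20))$p_two_tailed
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_error(generate_protein_table(frac_up = 1.2), "frac_up")
})

test_that("written cohort bundles round-trip through the readers", {
  co <- generate_cohort(cohort_config(n_samples = 10, n_genes = 400, seed = 15))
  dir <- withr::local_tempdir()
  paths <- write_cohort_bundle(co, dir)
  expect_true(all(file.exists(paths)))
  expr_back <- read_expression(paths[["expression"]])
  expect_equal(expr_back, co$expr, tolerance = 1e-12)
  ddr_back <- read_gmt(paths[["ddr_gmt"]])
  expect_identical(ddr_back$sets, co$collection$sets)
  expect_identical(read_gene_list(paths[["immune_genes"]]), co$immune_genes)
  sig_back <- read_signature(paths[["signature"]])
  expect_equal(sig_back, co$signature, tolerance = 1e-12,
               ignore_attr = "immune_cell_types")
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$realized_rho, co$realized_rho, tolerance = 1e-12)
})
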