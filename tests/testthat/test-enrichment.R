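test_that("median scaling centers every gene at zero", {
  m <- make_expr(c(1, 5, 2, 5, 3, 5), 2, 3, genes = c("A", "B"))
  cen <- median_center(m)
  expect_equal(unname(cen["A", ]), c(-1, 0, 1))
  expect_equal(unname(cen["B", ]), c(0, 0, 0))

  set.seed(1)
  big <- make_expr(rnorm(1000), 100, 10)
  expect_lt(max(abs(apply(median_center(big), 1, median))), 1e-12)

  one <- make_expr(1:3, 3, 1)
  expect_error(median_center(one), ">= 2 samples")
  neg <- make_expr(c(1, -2, 2, -2), 2, 2)
  expect_error(median_center(neg, mode = "divide"), "positive")
})

test_that("rank_genes sorts descending with symbol tie-break and ignores row order", {
  m <- make_expr(c(2, -1, 0, 0, 0, 0), 3, 2, genes = c("A", "B", "C"))
  rk <- rank_genes(m, "S01")
  expect_identical(rk$genes, c("A", "C", "B"))

  tie <- make_expr(c(1, 1, 0, 0), 2, 2, genes = c("B", "A"))
  expect_identical(rank_genes(tie, "S01")$genes, c("A", "B"))

  set.seed(3)
  big <- make_expr(rnorm(200), 100, 2)
  shuf <- big[sample(nrow(big)), ]
  expect_identical(rank_genes(big, "S02"), rank_genes(shuf, "S02"))
  expect_error(rank_genes(big, "nope"), "unknown sample")
})

test_that("enrichment score reproduces the worked running-sum examples", {
  rk <- make_ranked(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  top2 <- enrichment_score(rk, c("g1", "g2"))
  expect_equal(top2$es, 1)                       # all hits precede all misses
  mixed <- enrichment_score(rk, c("g1", "g3"))
  expect_equal(mixed$running_sum,
               c(0.625, 0.625 - 1/3, 0.625 - 1/3 + 0.375, 1/3, 0),
               tolerance = 1e-12)
  expect_equal(mixed$es, 2/3, tolerance = 1e-12)
  expect_identical(mixed$peak_index, 3L)
  bottom <- enrichment_score(rk, "g5")
  expect_lt(bottom$es, 0)                        # single hit at the end
  expect_error(enrichment_score(rk, "absent"), "no overlap")
  expect_error(enrichment_score(rk, paste0("g", 1:5)), "universe")
})

test_that("enrichment score matches the brute-force oracle and the C++ kernel", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    k <- sample(1:(n - 1), 1)
    hit_idx <- sort(sample(n, k))
    hit <- seq_len(n) %in% hit_idx
    genes <- sprintf("g%03d", seq_len(n))
    rk <- make_ranked(scores, genes)
    w <- sample(c(0, 1, 1.5), 1)
    got <- enrichment_score(rk, genes[hit_idx], weight = w)
    expect_equal(got$es, oracle_es(scores, hit, w), tolerance = 1e-12)
    expect_equal(got$es,
                 ddrimmune:::es_stat_cpp(abs(scores)^w, as.integer(hit_idx)),
                 tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(20:100, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- sprintf("g%03d", seq_len(n))
    k <- sample(2:10, 1)
    idx <- sort(sample(n, k))
    rk <- make_ranked(unname(stats), names(stats))
    mine <- enrichment_score(rk, names(stats)[idx], weight = 1)$es
    ref <- fgsea::calcGseaStat(stats, idx, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("es is invariant to positive rescaling and negates under list reversal", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    genes <- sprintf("g%03d", seq_len(n))
    idx <- sort(sample(n, sample(2:(n - 2), 1)))
    rk <- make_ranked(scores, genes)
    es1 <- enrichment_score(rk, genes[idx])$es
    rk_scaled <- make_ranked(scores * 7.5, genes)
    expect_equal(enrichment_score(rk_scaled, genes[idx])$es, es1,
                 tolerance = 1e-12)
    rk_rev <- make_ranked(rev(-scores), rev(genes))
    expect_equal(enrichment_score(rk_rev, genes[idx])$es, -es1,
                 tolerance = 1e-12)
  }
})

test_that("zero-score gene sets fall back to uniform hit increments", {
  scores <- c(3, 2, 0, 0, -1, -4)
  genes <- sprintf("g%d", 1:6)
  rk <- make_ranked(scores, genes)
  r <- enrichment_score(rk, c("g3", "g4"))
  expect_equal(r$es, oracle_es(rk$scores, rk$genes %in% c("g3", "g4")))
  expect_true(is.finite(r$es))
})

test_that("permutation null is seeded, reproducible, and supports boundary sizes", {
  rk <- make_ranked(sort(rnorm(50), decreasing = TRUE))
  a <- permutation_null(rk, set_size = 5, n_perm = 50, seed = 99)
  b <- permutation_null(rk, set_size = 5, n_perm = 50, seed = 99)
  expect_identical(a, b)
  expect_length(a, 50L)
  expect_true(all(abs(a) <= 1))
  edge <- permutation_null(rk, set_size = 49, n_perm = 5, seed = 1)
  expect_true(all(is.finite(edge)))
  expect_error(permutation_null(rk, set_size = 50, n_perm = 5), "set_size")
})

test_that("random single-gene sets hit uniform positions under flat scores", {
  # with equal |scores| and one hit at position j, the running sum jumps by
  # 1 at j after drifting down by (j-1)/(n-1); so es > 0 iff j is in the
  # top half and the hit position can be recovered from es exactly.  The
  # recovered positions of the C++ permutation null must be uniform.
  n <- 21L
  rk <- make_ranked(rep(1, n))
  es <- permutation_null(rk, set_size = 1, n_perm = 4200, seed = 8)
  j <- ifelse(es > 0, round((1 - es) * (n - 1)) + 1, round(-es * (n - 1)) + 1)
  expect_true(all(j >= 1 & j <= n))
  tab <- table(factor(j, levels = 1:n))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("normalize_es follows the same-sign convention with smoothed p", {
  r <- normalize_es(0.5, c(0.25, 0.25, -0.4))
  expect_equal(r$nes, 2)
  expect_equal(r$p_nominal, 1 / 3)   # (1+0)/(1+2)
  r2 <- normalize_es(0.3, c(0.3, 0.1, -0.2))
  expect_equal(r2$p_nominal, 2 / 3)  # ties count as extreme
  r3 <- normalize_es(-0.5, c(0.2, 0.3))
  expect_false(r3$defined)
  expect_true(is.na(r3$nes))
  expect_equal(normalize_es(0, c(0.1, -0.1))$nes, 0)
})

test_that("score_cohort composes ranking, scoring and calibration per sample", {
  set.seed(77)
  expr <- make_expr(rnorm(400), 100, 4)
  coll <- gene_set_collection(list(PW = rownames(expr)[11:25]))
  pa <- score_cohort(expr, coll, n_perm = 200, seed = 5)
  expect_identical(dim(pa$nes), c(4L, 1L))
  # replicate one cell by hand with the same per-sample seed
  s <- "S02"
  set.seed(sample_seed(5, s))
  rk <- rank_genes(median_center(expr), s)
  es <- enrichment_score(rk, coll$sets$PW)
  null <- ddrimmune:::perm_es_null_cpp(abs(rk$scores), es$n_hits, 200L)
  ref <- normalize_es(es$es, null)
  expect_equal(pa$nes[s, "PW"], ref$nes, tolerance = 1e-12)
  row <- pa$results[pa$results$sample == s, ]
  expect_equal(row$p_nominal, ref$p_nominal)
  expect_equal(row$es, es$es)
})

test_that("score_cohort is reproducible and invariant to sample order", {
  set.seed(13)
  expr <- make_expr(rnorm(1200), 200, 6)
  coll <- gene_set_collection(list(A = rownames(expr)[1:12],
                                   B = rownames(expr)[50:70]))
  p1 <- score_cohort(expr, coll, n_perm = 100, seed = 3)
  p2 <- score_cohort(expr, coll, n_perm = 100, seed = 3)
  expect_identical(p1$nes, p2$nes)
  shuffled <- expr[, c(4, 1, 6, 2, 5, 3)]
  p3 <- score_cohort(shuffled, coll, n_perm = 100, seed = 3)
  expect_identical(p3$nes[colnames(expr), ], p1$nes)
})

test_that("degenerate samples are flagged and NA-filled", {
  # middle sample sits exactly at each gene's median -> all-zero ranking
  m <- make_expr(c(0, 1, 2,  5, 6, 7,  1, 2, 3), 3, 3)
  m <- t(apply(m, 1, sort))
  dimnames(m) <- list(c("A", "B", "C"), c("S1", "S2", "S3"))
  coll <- gene_set_collection(list(PW = c("A", "B")))
  expect_warning(
    pa <- score_cohort(m, coll, n_perm = 50, min_size = 1, max_size = 10),
    "degenerate")
  expect_true(all(is.na(pa$nes["S2", ])))
  expect_identical(pa$degenerate_samples, "S2")
})

test_that("cluster_matrix orders axes deterministically", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  colnames(m) <- c("x", "y")
  cl <- cluster_matrix(m, axis = "rows")
  expect_equal(cl$row_tree$height[1], 0)               # identical rows first
  expect_setequal(abs(cl$row_tree$merge[1, ]), c(1, 2))

  # 1-D points at 0, 1, 3: single linkage merges (a,b) at 1 then c at 2
  pts <- cbind(v = c(0, 1, 3), w = 0)
  rownames(pts) <- c("a", "b", "c")
  sl <- cluster_matrix(pts, axis = "rows", linkage = "single")
  expect_equal(sl$row_tree$height, c(1, 2))

  # planted two-block structure separates perfectly
  set.seed(9)
  blocks <- rbind(matrix(rnorm(50, 0, 0.1), 10),
                  matrix(rnorm(50, 8, 0.1), 10))
  rownames(blocks) <- sprintf("r%02d", 1:20)
  ord <- cluster_matrix(blocks, axis = "rows")$row_order
  first_half <- ord[1:10]
  expect_true(all(first_half <= 10) || all(first_half > 10))
})

test_that("cluster_matrix imputes undefined cells and needs two items", {
  m <- rbind(a = c(1, NA), b = c(0, 0), c = c(2, 2))
  expect_message(cl <- cluster_matrix(m, axis = "rows"), "imputed")
  expect_length(cl$row_order, 3L)
  expect_error(cluster_matrix(m[1, , drop = FALSE], axis = "rows"), ">= 2")
})
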