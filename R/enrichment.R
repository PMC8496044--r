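#' Median-scale an expression matrix gene by gene
#'
#' For each gene, subtracts (default) or divides by the across-sample
#' median, so each sample's profile becomes a deviation from the cohort's
#' typical expression of that gene.  Subtraction is the natural choice for
#' log-space data; division is available for users working on a linear
#' scale.
#'
#' @param expr numeric matrix, genes x samples (log2 scale assumed).
#' @param mode `"center"` (subtract the per-gene median) or `"divide"`.
#' @return matrix of the same shape; with `"center"`, every gene row has
#'   median 0.
#' @export
median_center <- function(expr, mode = c("center", "divide")) {
  mode <- match.arg(mode)
  validate_expression(expr)
  if (ncol(expr) < 2L) {
    stop("median scaling needs >= 2 samples (a one-sample median is degenerate)")
  }
  med <- apply(expr, 1L, stats::median)
  if (mode == "center") {
    expr - med
  } else {
    if (any(med <= 0)) {
      stop("'divide' mode requires strictly positive per-gene medians")
    }
    expr / med
  }
}

#' Rank one sample's genes by median-scaled expression
#'
#' Genes are sorted by the sample's centered value, descending; ties are
#' broken by ascending gene symbol so the ordering is deterministic.  With
#' `metric = "rank"` the score is the centered integer rank
#' (rank - (N+1)/2), a robust signed alternative.
#'
#' @param centered output of [median_center()].
#' @param sample_id column to rank.
#' @param metric `"centered"` (default: the centered value itself) or
#'   `"rank"`.
#' @return a `RankedList`: list with `sample_id`, `genes` (descending
#'   score), `scores`.
#' @export
rank_genes <- function(centered, sample_id, metric = c("centered", "rank")) {
  metric <- match.arg(metric)
  if (!sample_id %in% colnames(centered)) {
    stop("unknown sample: ", sample_id)
  }
  v <- centered[, sample_id]
  g <- rownames(centered)
  if (metric == "rank") {
    v <- rank(v, ties.method = "average") - (length(v) + 1) / 2
  }
  ord <- order(-v, g, method = "radix")
  structure(list(sample_id = sample_id, genes = g[ord], scores = v[ord],
                 genes_norm = normalize_symbols(g[ord])),
            class = "RankedList")
}

#' @export
print.RankedList <- function(x, ...) {
  cat(sprintf("RankedList for sample '%s': %d genes, score range [%.3g, %.3g]\n",
              x$sample_id, length(x$genes),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list; member genes ("hits") add
#' `|score|^weight / sum(|score|^weight over hits)`, non-members subtract
#' `1/(N - N_hits)`.  The enrichment score (ES) is the running-sum value of
#' maximal absolute deviation from zero; positive ES means the set
#' concentrates at the top of the list.  If all hit scores are zero the
#' hit increments fall back to uniform `1/N_hits`.
#'
#' @param ranked a `RankedList` from [rank_genes()].
#' @param gene_set character vector of member symbols (or one element of a
#'   `GeneSetCollection`'s `$sets`).
#' @param weight exponent on |score| for hit increments; 1 is the classic
#'   weighted statistic, 0 the unweighted Kolmogorov-Smirnov form.
#' @return list with `es` (in [-1, 1]), `running_sum` (length N),
#'   `peak_index` (first position attaining the extremum; an exact tie
#'   between the positive and negative extremum resolves to the positive
#'   side), `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "RankedList"))
  gene_set <- normalize_symbols(gene_set)
  genes_norm <- ranked$genes_norm %||% normalize_symbols(ranked$genes)
  hit <- genes_norm %in% gene_set
  n <- length(ranked$genes)
  k <- sum(hit)
  if (k == 0L) stop("gene set has no overlap with the ranked list")
  if (k == n) stop("gene set equals the gene universe; no misses to score against")
  absw <- abs(ranked$scores)^weight
  nr <- sum(absw[hit])
  inc <- numeric(n)
  inc[hit] <- if (nr > 0) absw[hit] / nr else 1 / k
  inc[!hit] <- -1 / (n - k)
  rs <- cumsum(inc)
  mx <- max(rs)
  mn <- min(rs)
  # a tie between the positive and negative extremum (possible at
  # weight 0) resolves to the positive side; the tolerance keeps the
  # choice stable under floating-point summation order
  if (mx >= -mn - 1e-12) {
    peak <- which.max(rs)
  } else {
    peak <- which.min(rs)
  }
  list(es = rs[peak], running_sum = rs, peak_index = peak, n_hits = k)
}

#' Per-sample RNG seed
#'
#' Derives a deterministic seed from the root seed and a sample
#' identifier, so per-sample permutation nulls are reproducible regardless
#' of the order samples are processed in.
#'
#' @param seed integer root seed.
#' @param sample_id sample identifier string.
#' @return integer seed in [0, 2^31 - 2].
#' @export
sample_seed <- function(seed, sample_id) {
  codes <- utf8ToInt(as.character(sample_id))
  h <- sum(as.numeric(codes) * seq_along(codes) * 131) + as.numeric(seed)
  as.integer(h %% 2147483647)
}

#' Gene-label permutation null for the enrichment score
#'
#' Draws `n_perm` random gene subsets of size `set_size` (without
#' replacement) from the ranked list and returns their enrichment scores.
#' This is the pre-ranked GSEA convention; sample permutation is
#' ill-defined when scoring each sample against its own ranking.
#'
#' @inheritParams enrichment_score
#' @param set_size number of genes per random set, `1 <= set_size < N`.
#' @param n_perm number of permutations.
#' @param seed optional integer; if given, seeds R's RNG first so the null
#'   is reproducible in isolation.
#' @return numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000L, weight = 1,
                             seed = NULL) {
  stopifnot(inherits(ranked, "RankedList"))
  if (!is.null(seed)) set.seed(seed)
  absw <- abs(ranked$scores)^weight
  perm_es_null_cpp(absw, as.integer(set_size), as.integer(n_perm))
}

#' Normalize an enrichment score against its permutation null
#'
#' `nes = es / mean(|null es| over null values of the same sign)`; the
#' nominal p-value is the same-sign tail proportion with add-one smoothing
#' so p is never 0: `p = (1 + #same-sign null with |es_null| >= |es|) /
#' (1 + #same-sign null)`.  If the null contains no same-sign values the
#' result is flagged undefined (NA) rather than zero-filled, because silent
#' zeros would bias downstream correlations.
#'
#' @param es observed enrichment score.
#' @param null numeric vector of null enrichment scores.
#' @return list with `nes`, `p_nominal`, and `defined` (FALSE when the
#'   same-sign null is empty).
#' @export
normalize_es <- function(es, null) {
  if (length(null) == 0L) stop("empty null distribution")
  if (es == 0) {
    return(list(nes = 0, p_nominal = 1, defined = TRUE))
  }
  same <- if (es > 0) null[null > 0] else null[null < 0]
  if (length(same) == 0L) {
    return(list(nes = NA_real_, p_nominal = NA_real_, defined = FALSE))
  }
  nes <- es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(nes = nes, p_nominal = p, defined = TRUE)
}

#' Score a cohort: per-sample pathway activity matrix
#'
#' The per-patient loop: median-scale the expression matrix, rank each
#' sample's genes, compute the weighted running-sum enrichment score of
#' every surviving gene set, calibrate it against a gene-label permutation
#' null (cached per set size within each sample), and adjust nominal
#' p-values per sample across pathways by Benjamini-Hochberg.
#'
#' A sample whose ranking metric is all zero after centering cannot be
#' ranked meaningfully; its row is flagged and filled with NA.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param collection a `GeneSetCollection`.
#' @param weight hit-increment exponent (see [enrichment_score()]).
#' @param n_perm permutations per null.
#' @param min_size,max_size set-size filter after intersection with
#'   `rownames(expr)` (see [filter_gene_sets()]).
#' @param seed integer seed; results are bit-reproducible given
#'   (inputs, parameters, seed).
#' @param metric ranking metric, `"centered"` or `"rank"`.
#' @param median_mode `"center"` or `"divide"` (see [median_center()]).
#' @return a `PathwayActivity` object: list with `nes` (samples x pathways
#'   matrix), `results` (long data.frame: sample, pathway, es, nes,
#'   p_nominal, fdr_q, n_hits, peak_index), `params`, and
#'   `degenerate_samples`.
#' @export
score_cohort <- function(expr, collection, weight = 1, n_perm = 1000L,
                         min_size = 5L, max_size = 500L, seed = 1L,
                         metric = c("centered", "rank"),
                         median_mode = c("center", "divide")) {
  metric <- match.arg(metric)
  median_mode <- match.arg(median_mode)
  validate_expression(expr)
  collection <- filter_gene_sets(collection, expr, min_size, max_size)
  centered <- median_center(expr, mode = median_mode)
  samples <- colnames(expr)
  pathways <- names(collection)

  nes_mat <- matrix(NA_real_, length(samples), length(pathways),
                    dimnames = list(samples, pathways))
  rows <- vector("list", length(samples))
  degenerate <- character(0)
  sizes <- lengths(collection$sets)

  for (si in seq_along(samples)) {
    s <- samples[si]
    # seed derived from (root seed, sample id) so results do not depend on
    # the order samples are visited in
    set.seed(sample_seed(seed, s))
    ranked <- rank_genes(centered, s, metric = metric)
    if (all(ranked$scores == 0)) {
      warning("sample '", s, "' is degenerate after centering; row set to NA")
      degenerate <- c(degenerate, s)
      next
    }
    absw <- abs(ranked$scores)^weight
    null_cache <- new.env(parent = emptyenv())
    res <- data.frame(sample = s, pathway = pathways, es = NA_real_,
                      nes = NA_real_, p_nominal = NA_real_, fdr_q = NA_real_,
                      n_hits = NA_integer_, peak_index = NA_integer_,
                      stringsAsFactors = FALSE)
    for (pi in seq_along(pathways)) {
      sc <- enrichment_score(ranked, collection$sets[[pi]], weight = weight)
      key <- as.character(sc$n_hits)
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- perm_es_null_cpp(absw, sc$n_hits,
                                              as.integer(n_perm))
      }
      nz <- normalize_es(sc$es, null_cache[[key]])
      res$es[pi] <- sc$es
      res$nes[pi] <- nz$nes
      res$p_nominal[pi] <- nz$p_nominal
      res$n_hits[pi] <- sc$n_hits
      res$peak_index[pi] <- sc$peak_index
    }
    res$fdr_q <- bh_fdr(res$p_nominal)
    nes_mat[si, ] <- res$nes
    rows[[si]] <- res
  }

  structure(
    list(nes = nes_mat,
         results = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
         params = list(weight = weight, n_perm = n_perm, min_size = min_size,
                       max_size = max_size, seed = seed, metric = metric,
                       median_mode = median_mode,
                       fdr = "Benjamini-Hochberg per sample across pathways",
                       pathway_sizes = stats::setNames(sizes, pathways)),
         degenerate_samples = degenerate),
    class = "PathwayActivity")
}

#' @export
print.PathwayActivity <- function(x, ...) {
  cat(sprintf("PathwayActivity: %d samples x %d pathways (n_perm=%d, weight=%g)\n",
              nrow(x$nes), ncol(x$nes), x$params$n_perm, x$params$weight))
  if (length(x$degenerate_samples)) {
    cat("  degenerate samples:", paste(x$degenerate_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hierarchically cluster a pathway activity (or any numeric) matrix
#'
#' Standard agglomerative clustering for heatmap ordering.  Undefined
#' cells are imputed to 0 for the distance computation only (with a
#' message).  `hclust` merge order is deterministic for a given distance
#' matrix; ties resolve to the smaller index.
#'
#' @param mat numeric matrix (e.g. the `nes` slot of a `PathwayActivity`),
#'   or a `PathwayActivity` object.
#' @param axis `"both"`, `"rows"` or `"columns"`.
#' @param distance distance metric passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `row_order`, `col_order` (leaf-order permutations, or
#'   NULL for an unclustered axis) and the `hclust` trees `row_tree`,
#'   `col_tree`.
#' @export
cluster_matrix <- function(mat, axis = c("both", "rows", "columns"),
                           distance = "euclidean", linkage = "average") {
  axis <- match.arg(axis)
  if (inherits(mat, "PathwayActivity")) mat <- mat$nes
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (anyNA(mat)) {
    message("cluster_matrix: ", sum(is.na(mat)),
            " undefined cell(s) imputed to 0 for distance computation")
    mat[is.na(mat)] <- 0
  }
  one_axis <- function(m) {
    if (nrow(m) < 2L) stop("need >= 2 items on the clustered axis")
    d <- stats::dist(m, method = distance)
    if (any(!is.finite(d))) {
      idx <- which(!is.finite(as.matrix(d)), arr.ind = TRUE)[1, ]
      stop(sprintf("non-finite distance between '%s' and '%s'",
                   rownames(m)[idx[1]], rownames(m)[idx[2]]))
    }
    stats::hclust(d, method = linkage)
  }
  row_tree <- col_tree <- NULL
  if (axis %in% c("both", "rows")) row_tree <- one_axis(mat)
  if (axis %in% c("both", "columns")) col_tree <- one_axis(t(mat))
  list(row_order = if (!is.null(row_tree)) row_tree$order,
       col_order = if (!is.null(col_tree)) col_tree$order,
       row_tree = row_tree, col_tree = col_tree)
}
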