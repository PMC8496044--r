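# Independent brute-force oracles, deliberately written as direct
# transcriptions of the definitions, sharing no code with the package.

# Running-sum enrichment score by literal walk down the list.
oracle_es <- function(scores, hit, weight = 1) {
  n <- length(scores)
  k <- sum(hit)
  nr <- sum(abs(scores[hit])^weight)
  running <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (nr > 0) abs(scores[i])^weight / nr else 1 / k
    } else {
      cur <- cur - 1 / (n - k)
    }
    running[i] <- cur
  }
  # tie between positive and negative extremum resolves positive
  if (max(running) >= -min(running) - 1e-12) max(running) else min(running)
}

# Spearman's rho as rank-transform-then-Pearson, with explicit formulas.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Exhaustive two-sided permutation p-value for Spearman's rho, generating
# permutations by depth-first recursion over remaining indices.
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  obs <- abs(oracle_spearman(x, y))
  count <- 0L
  total <- 0L
  recurse <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      total <<- total + 1L
      if (abs(oracle_spearman(x, y[prefix])) >= obs - 1e-12) {
        count <<- count + 1L
      }
      return(invisible())
    }
    for (r in remaining) recurse(c(prefix, r), setdiff(remaining, r))
  }
  recurse(integer(0), seq_len(n))
  count / total
}

# Two-tailed Fisher p by enumerating every table with the observed
# margins, using binomial coefficients directly.
oracle_fisher_two_tailed <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  tot <- choose(m + n, k)
  prob <- function(x) choose(m, x) * choose(n, k - x) / tot
  obs <- prob(a)
  xs <- max(0, k - n):min(k, m)
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <= obs * (1 + 1e-7)])
}

# Build a RankedList directly (bypasses expression-matrix plumbing).
make_ranked <- function(scores, genes = sprintf("g%02d", seq_along(scores)),
                        sample_id = "s1") {
  ord <- order(-scores, genes, method = "radix")
  structure(list(sample_id = sample_id, genes = genes[ord],
                 scores = scores[ord],
                 genes_norm = toupper(genes[ord])),
            class = "RankedList")
}

# Small labelled expression matrix from a vector of values.
make_expr <- function(values, n_genes, n_samples,
                      genes = sprintf("G%03d", seq_len(n_genes)),
                      samples = sprintf("S%02d", seq_len(n_samples))) {
  matrix(values, n_genes, n_samples, dimnames = list(genes, samples))
}

# Random gene-set collection for round-trip property tests.
random_collection <- function(n_sets, universe, min_n = 1L, max_n = 12L) {
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(universe, sample(min_n:max_n, 1))
  })
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  gene_set_collection(sets, sprintf("description %d", seq_len(n_sets)),
                      source_label = "random")
}
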