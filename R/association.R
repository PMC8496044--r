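#' Spearman rank correlation of two vectors
#'
#' Ranks both vectors with average ranks for ties, then takes the Pearson
#' correlation of the ranks.  Returns NA for constant input.
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# Two-sided p for Spearman's rho: t approximation for n >= 10, exhaustive
# permutation enumeration below that (all n! orderings of one vector).
spearman_p <- function(x, y, rho) {
  n <- length(x)
  if (is.na(rho)) return(NA_real_)
  if (n >= 10L) {
    r2 <- min(rho^2, 1)
    if (r2 >= 1) return(0)
    tstat <- abs(rho) * sqrt((n - 2) / (1 - r2))
    return(2 * stats::pt(-tstat, df = n - 2))
  }
  perms <- all_permutations(n)
  ry <- rank(y, ties.method = "average")
  rx <- rank(x, ties.method = "average")
  hits <- 0L
  for (i in seq_len(nrow(perms))) {
    rp <- stats::cor(rx, ry[perms[i, ]])
    if (abs(rp) >= abs(rho) - 1e-12) hits <- hits + 1L
  }
  hits / nrow(perms)
}

# All permutations of 1:n as a matrix (n! rows); n <= 9 enforced.
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 9L)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlation matrix between two feature blocks
#'
#' Correlates every column of `A` with every column of `B` across shared
#' samples (rows).  Two-sided p-values use the t approximation for
#' n >= 10 and exhaustive permutation enumeration for smaller cohorts;
#' q-values are Benjamini-Hochberg over all defined cells jointly (the
#' whole matrix is treated as one family).  Constant columns yield
#' undefined (NA) cells, never 0.
#'
#' @param A samples x features numeric matrix (rownames = sample ids).
#' @param B optional second block with identical rownames; defaults to `A`
#'   (the pathway intercorrelation case, giving a symmetric matrix with
#'   unit diagonal).
#' @return a `CorrelationMatrix`: list with matrices `rho`, `p`, `q`
#'   (rows = colnames(A), cols = colnames(B)) and `long`, a data.frame of
#'   all defined cells.
#' @export
spearman_matrix <- function(A, B = NULL) {
  symmetric <- is.null(B)
  if (symmetric) B <- A
  stopifnot(is.matrix(A), is.matrix(B), is.numeric(A), is.numeric(B))
  if (nrow(A) != nrow(B) || !identical(rownames(A), rownames(B))) {
    stop("A and B must share the same samples in the same order")
  }
  if (nrow(A) < 4L) stop("need >= 4 samples for correlation analysis")
  const_A <- apply(A, 2, function(v) stats::sd(v) == 0)
  const_B <- apply(B, 2, function(v) stats::sd(v) == 0)
  if (any(const_A) || any(const_B)) {
    message("spearman_matrix: constant feature(s) give undefined cells: ",
            paste(unique(c(colnames(A)[const_A], colnames(B)[const_B])),
                  collapse = ", "))
  }
  rA <- apply(A, 2, rank, ties.method = "average")
  rB <- apply(B, 2, rank, ties.method = "average")
  rho <- suppressWarnings(stats::cor(rA, rB))
  rho[const_A, ] <- NA_real_
  rho[, const_B] <- NA_real_

  p <- matrix(NA_real_, ncol(A), ncol(B),
              dimnames = list(colnames(A), colnames(B)))
  n <- nrow(A)
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      if (!is.na(rho[i, j])) p[i, j] <- spearman_p(A[, i], B[, j], rho[i, j])
    }
  }
  if (symmetric) diag(p) <- 0
  p[is.na(rho)] <- NA_real_
  q <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  idx <- which(!is.na(rho), arr.ind = TRUE)
  long <- data.frame(row = rownames(rho)[idx[, 1]],
                     col = colnames(rho)[idx[, 2]],
                     rho = rho[idx], p = p[idx], q = q[idx],
                     stringsAsFactors = FALSE)
  structure(list(rho = rho, p = p, q = q, long = long,
                 n_samples = n, symmetric = symmetric,
                 fdr = "Benjamini-Hochberg over all defined cells jointly"),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf("CorrelationMatrix: %d x %d features over %d samples (%s)\n",
              nrow(x$rho), ncol(x$rho), x$n_samples,
              if (x$symmetric) "symmetric" else "two blocks"))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up BH with monotone enforcement; undefined (NA) entries
#' are excluded from the family and returned NA.
#'
#' @param p_values numeric vector of p-values in [0, 1] (NAs allowed).
#' @return q-values, same length and order; `q >= p` element-wise.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Two-tailed Fisher's exact over-representation test
#'
#' Builds the 2x2 table (in-set vs out-of-set) x (foreground vs rest of
#' background) and computes the two-tailed p-value by summing all
#' hypergeometric outcomes whose probability does not exceed the observed
#' table's (the convention of mainstream implementations).  The odds ratio
#' is the sample odds ratio `(a*d)/(b*c)`, infinite when `b*c = 0` with
#' `a*d > 0`.
#'
#' @param foreground character vector of selected ids (e.g. upregulated
#'   proteins); must be a subset of `background`.
#' @param background character vector: the tested universe.
#' @param set a gene set: character vector of member ids (intersected with
#'   the background).
#' @param set_name optional label.
#' @return an `ORAResult`: list with `set_name`, counts `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `p_two_tailed`.
#' @export
fisher_ora <- function(foreground, background, set, set_name = "set") {
  foreground <- unique(normalize_symbols(foreground))
  background <- unique(normalize_symbols(background))
  set <- unique(normalize_symbols(set))
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of background (offending ids: ",
         paste(utils::head(setdiff(foreground, background), 5), collapse = ", "),
         ")")
  }
  set <- intersect(set, background)
  a <- length(intersect(set, foreground))
  b <- length(foreground) - a
  cc <- length(set) - a
  d <- length(background) - a - b - cc
  p <- fisher_two_tailed(a, b, cc, d)
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  structure(list(set_name = set_name, a = a, b = b, c = cc, d = d,
                 odds_ratio = or, p_two_tailed = p),
            class = "ORAResult")
}

# Two-tailed hypergeometric p: probability mass of all tables (fixed
# margins) no more likely than the observed one, with the standard
# relative tolerance guarding ties in floating point.
fisher_two_tailed <- function(a, b, c, d) {
  m <- a + c            # in-set in background
  n <- b + d            # out-of-set
  k <- a + b            # foreground size
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' @export
print.ORAResult <- function(x, ...) {
  cat(sprintf("ORA '%s': table (%d, %d; %d, %d), OR = %.3g, two-tailed p = %.3g\n",
              x$set_name, x$a, x$b, x$c, x$d, x$odds_ratio, x$p_two_tailed))
  invisible(x)
}

#' Run over-representation tests for a whole collection
#'
#' Applies [fisher_ora()] to every set and BH-adjusts across sets.
#'
#' @inheritParams fisher_ora
#' @param collection a `GeneSetCollection`.
#' @return data.frame: set, a, b, c, d, odds_ratio, p, q.
#' @export
ora_collection <- function(foreground, background, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  rows <- lapply(names(collection), function(nm) {
    r <- fisher_ora(foreground, background, collection$sets[[nm]], nm)
    data.frame(set = nm, a = r$a, b = r$b, c = r$c, d = r$d,
               odds_ratio = r$odds_ratio, p = r$p_two_tailed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Assign fold-change quartile groups to upregulated proteins
#'
#' Upregulated entries (fold change > 1) are split into quartiles Q1..Q4
#' by ascending fold change (Q4 = highest fold changes); entries tied at a
#' quartile boundary all go to the lower group, so the assignment is
#' deterministic.  Downregulated entries are left ungrouped (NA).
#'
#' @param table data.frame with columns `protein` and `fold_change`
#'   (positive reals, tumor/normal).
#' @return the table with added columns `direction` ("up"/"down") and
#'   `quantile_group` ("Q1".."Q4" or NA).
#' @export
quantile_groups <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("protein", "fold_change") %in% colnames(table)))
  fc <- table$fold_change
  if (any(!is.finite(fc) | fc <= 0)) stop("fold changes must be positive and finite")
  table$direction <- ifelse(fc > 1, "up", "down")
  up <- which(table$direction == "up")
  if (length(up) < 4L) stop("need >= 4 upregulated proteins for quartile grouping")
  m <- length(up)
  ord <- order(fc[up], method = "radix")   # stable ascending sort
  prov <- integer(m)
  prov[ord] <- ceiling(4 * seq_len(m) / m)
  # boundary ties: every copy of a tied value takes the lowest group seen
  grp <- stats::ave(prov, fc[up], FUN = min)
  table$quantile_group <- NA_character_
  table$quantile_group[up] <- paste0("Q", grp)
  table
}
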