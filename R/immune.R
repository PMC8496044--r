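#' Per-sample immune content score
#'
#' Summarizes overall immune infiltration as the mean across-sample
#' z-score of a list of immune-specific genes: each immune gene found in
#' the matrix is standardized across samples (population sd), and the
#' sample's score is the mean of those standardized values.  Genes
#' constant across samples carry no information and are dropped with a
#' warning.  Scores have cohort mean ~0 by construction.
#'
#' An alternative `"sumlog2"` mode returns the plain per-sample sum of the
#' immune genes' log2 values (no standardization), for users who want an
#' absolute-abundance flavour.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param immune_genes character vector of immune-specific gene symbols.
#' @param mode `"zmean"` (default) or `"sumlog2"`.
#' @return named numeric vector of per-sample scores.
#' @export
immune_content_score <- function(expr, immune_genes, mode = c("zmean", "sumlog2")) {
  mode <- match.arg(mode)
  validate_expression(expr)
  immune_genes <- unique(normalize_symbols(immune_genes))
  found <- intersect(immune_genes, rownames(expr))
  if (length(found) == 0L) {
    stop("no immune genes found in the expression matrix; first missing: ",
         paste(utils::head(immune_genes, 10), collapse = ", "))
  }
  if (length(found) < length(immune_genes) / 2) {
    warning(sprintf("only %d of %d immune genes found in the matrix",
                    length(found), length(immune_genes)))
  }
  sub <- expr[found, , drop = FALSE]
  if (mode == "sumlog2") return(colSums(sub))
  n <- ncol(sub)
  mu <- rowMeans(sub)
  sdp <- apply(sub, 1, stats::sd) * sqrt((n - 1) / n)   # population sd
  keep <- sdp > 0
  if (!any(keep)) {
    stop("all immune genes are constant across samples; content score undefined")
  }
  if (!all(keep)) {
    warning(sum(!keep), " constant immune gene(s) dropped from content score")
  }
  z <- (sub[keep, , drop = FALSE] - mu[keep]) / sdp[keep]
  colMeans(z)
}

#' Deconvolve one sample into cell-type fractions
#'
#' Regresses a sample's expression on the columns of a signature matrix
#' over their shared genes.  Before fitting, the sample vector and the
#' signature columns are centered over the shared genes and each side is
#' scaled by a single global standard deviation, which makes the fit
#' invariant to affine changes of units while preserving the relative
#' weight of each cell type.  Two solvers:
#' \describe{
#'   \item{nnls}{non-negative least squares (deterministic default).}
#'   \item{nu_svr}{linear nu-support-vector regression over a grid of nu
#'     values, keeping the fit with the lowest reconstruction RMSE;
#'     negative coefficients are clipped to 0.}
#' }
#' Fractions are the (clipped) coefficients renormalized to sum to 1;
#' RMSE is measured in the z-scored shared-gene space with the
#' pre-normalization coefficients.
#'
#' @param sample_expr named numeric vector of one sample's (log2) values.
#' @param signature genes x cell-types non-negative matrix.
#' @param method `"nnls"` or `"nu_svr"`.
#' @param nu_grid nu values tried for `"nu_svr"`.
#' @return a `DeconvolutionResult`: list with `fractions` (non-negative,
#'   sum 1), `rmse`, `method`, `nu_selected` (NA for nnls).
#' @export
deconvolve <- function(sample_expr, signature, method = c("nnls", "nu_svr"),
                       nu_grid = c(0.25, 0.5, 0.75)) {
  method <- match.arg(method)
  validate_signature(signature)
  if (is.null(names(sample_expr))) stop("sample_expr must be a named vector")
  names(sample_expr) <- normalize_symbols(names(sample_expr))
  shared <- intersect(rownames(signature), names(sample_expr))
  need <- max(10L, 2L * ncol(signature))
  if (length(shared) < need) {
    stop(sprintf("only %d shared gene(s) between sample and signature; need >= %d",
                 length(shared), need))
  }
  X <- signature[shared, , drop = FALSE]
  y <- sample_expr[shared]
  if (qr(X)$rank < ncol(X)) {
    warning("signature is rank-deficient over the shared genes; ",
            "fractions of collinear cell types are not identifiable")
  }
  # center each column and the sample over the shared genes, then scale
  # each side by a single global sd; the common scale keeps noiseless
  # mixtures exactly recoverable (per-column sds would distort fractions)
  Xc <- sweep(X, 2, colMeans(X))
  sX <- stats::sd(as.vector(Xc))
  Xz <- if (sX > 0) Xc / sX else Xc
  yc <- y - mean(y)
  sy <- stats::sd(yc)
  yz <- if (sy > 0) yc / sy else yc

  nu_selected <- NA_real_
  if (method == "nnls") {
    coef <- pracma::lsqnonneg(Xz, yz)$x
  } else {
    best <- NULL
    for (nu in nu_grid) {
      fit <- e1071::svm(x = Xz, y = yz, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE)
      w <- drop(t(fit$coefs) %*% Xz[fit$index, , drop = FALSE])
      w[w < 0] <- 0
      rmse_nu <- sqrt(mean((yz - drop(Xz %*% w))^2))
      if (is.null(best) || rmse_nu < best$rmse) {
        best <- list(w = w, rmse = rmse_nu, nu = nu)
      }
    }
    coef <- best$w
    nu_selected <- best$nu
  }
  rmse <- sqrt(mean((yz - drop(Xz %*% coef))^2))
  total <- sum(coef)
  fractions <- if (total > 0) coef / total else rep(1 / ncol(X), ncol(X))
  names(fractions) <- colnames(signature)
  structure(list(fractions = fractions, rmse = rmse, method = method,
                 nu_selected = nu_selected),
            class = "DeconvolutionResult")
}

#' @export
print.DeconvolutionResult <- function(x, ...) {
  cat(sprintf("Deconvolution (%s%s), rmse = %.4g:\n", x$method,
              if (!is.na(x$nu_selected)) sprintf(", nu = %g", x$nu_selected) else "",
              x$rmse))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Assemble the per-sample immune feature matrix
#'
#' Concatenates, per sample: the immune content score, the NES of each
#' immune pathway (via [score_cohort()]), and the deconvolved cell-type
#' fractions.  Feature kinds are tagged so downstream consumers can treat
#' blocks differently.  Constant feature columns are flagged with a
#' warning because their correlations are undefined downstream.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param immune_genes immune-specific gene list (NULL to skip the score).
#' @param immune_sets `GeneSetCollection` of immune pathways (NULL to skip).
#' @param signature genes x cell-types matrix (NULL to skip deconvolution).
#' @param method deconvolution solver, see [deconvolve()].
#' @param n_perm,weight,min_size,max_size,seed enrichment parameters passed
#'   to [score_cohort()] for the immune pathway block.
#' @return an `ImmuneFeatures` object: list with `values` (samples x
#'   features matrix), `kinds` (one of "content_score", "pathway",
#'   "cell_fraction" per feature) and `deconvolution` (per-sample results
#'   or NULL).
#' @export
build_immune_features <- function(expr, immune_genes = NULL,
                                  immune_sets = NULL, signature = NULL,
                                  method = "nnls", n_perm = 1000L,
                                  weight = 1, min_size = 5L, max_size = 500L,
                                  seed = 1L) {
  validate_expression(expr)
  samples <- colnames(expr)
  blocks <- list(); kinds <- character(0)
  if (!is.null(immune_genes)) {
    ics <- immune_content_score(expr, immune_genes)
    blocks$content <- matrix(ics[samples], ncol = 1,
                             dimnames = list(samples, "immune_content_score"))
    kinds <- c(kinds, "content_score")
  }
  if (!is.null(immune_sets) && length(immune_sets) > 0) {
    pa <- score_cohort(expr, immune_sets, weight = weight, n_perm = n_perm,
                       min_size = min_size, max_size = max_size, seed = seed)
    blocks$pathway <- pa$nes[samples, , drop = FALSE]
    kinds <- c(kinds, rep("pathway", ncol(pa$nes)))
  }
  decon <- NULL
  if (!is.null(signature)) {
    decon <- lapply(samples, function(s) {
      deconvolve(expr[, s], signature, method = method)
    })
    names(decon) <- samples
    frac <- t(vapply(decon, function(d) d$fractions,
                     numeric(ncol(signature))))
    rownames(frac) <- samples
    blocks$fractions <- frac
    kinds <- c(kinds, rep("cell_fraction", ncol(frac)))
  }
  if (length(blocks) == 0L) stop("no immune feature block requested")
  values <- do.call(cbind, unname(blocks))
  const <- apply(values, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const, na.rm = TRUE)) {
    warning("constant immune feature(s): ",
            paste(colnames(values)[which(const)], collapse = ", "))
  }
  structure(list(values = values,
                 kinds = stats::setNames(kinds, colnames(values)),
                 deconvolution = decon),
            class = "ImmuneFeatures")
}

#' @export
print.ImmuneFeatures <- function(x, ...) {
  cat(sprintf("ImmuneFeatures: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$kinds)), table(x$kinds)),
                    collapse = ", ")))
  invisible(x)
}

#' Write an immune feature matrix as TSV
#'
#' Adds a second header row tagging each feature's kind.
#'
#' @param features an `ImmuneFeatures` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_immune_features <- function(features, path) {
  stopifnot(inherits(features, "ImmuneFeatures"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(features$values)), collapse = "\t"), con)
  writeLines(paste(c("#kind", unname(features$kinds)), collapse = "\t"), con)
  utils::write.table(
    data.frame(rownames(features$values), features$values, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
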