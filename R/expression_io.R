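#' Read a delimited expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' symbols; values are assumed log2-transformed abundance (e.g.
#' log2(TPM+1)).  Duplicate gene symbols are collapsed by keeping the row
#' with the highest mean (a deterministic, common convention); any
#' non-numeric or missing cell is an error naming its position.
#'
#' @param path path to the TSV/CSV file.
#' @param delimiter field separator; `"\t"` (default) or `","`.
#' @return numeric matrix, genes (upper-cased rownames) x samples.
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression file has no sample columns: ", path)
  if (nrow(df) < 1L) stop("expression file has no gene rows: ", path)
  genes <- normalize_symbols(df[[1]])
  if (any(!nzchar(genes))) {
    stop("missing gene symbol at data row(s): ",
         paste(which(!nzchar(genes)), collapse = ", "))
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                  dimnames = dimnames(body)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric or missing value '%s' at gene '%s', sample '%s'",
      body[bad[1, 1], bad[1, 2]], genes[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  rownames(vals) <- genes
  if (anyDuplicated(colnames(vals))) {
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(vals)[duplicated(colnames(vals))]),
               collapse = ", "))
  }
  vals <- collapse_duplicate_genes(vals)
  validate_expression(vals)
  vals
}

# Keep, for each duplicated symbol, the row with the highest mean.
collapse_duplicate_genes <- function(vals) {
  if (!anyDuplicated(rownames(vals))) return(vals)
  dup_syms <- unique(rownames(vals)[duplicated(rownames(vals))])
  message(sprintf("collapsing %d duplicated gene symbol(s) by max-mean rule: %s",
                  length(dup_syms), paste(utils::head(dup_syms, 5), collapse = ", ")))
  means <- rowMeans(vals)
  ord <- order(rownames(vals), -means)  # stable: highest mean first per symbol
  vals <- vals[ord, , drop = FALSE]
  vals <- vals[!duplicated(rownames(vals)), , drop = FALSE]
  vals
}

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric matrix, unique non-empty gene
#' rownames and sample colnames, all values finite.
#'
#' @param expr candidate matrix.
#' @return `expr`, invisibly, or an error.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || any(!nzchar(rownames(expr)))) {
    stop("expression matrix must have non-empty gene rownames")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene symbols in expression matrix")
  if (is.null(colnames(expr)) || anyDuplicated(colnames(expr))) {
    stop("expression matrix must have unique sample colnames")
  }
  if (any(!is.finite(expr))) stop("expression matrix contains non-finite values")
  invisible(expr)
}

#' Read a signature matrix for deconvolution
#'
#' Same layout as an expression matrix (genes x cell types), values must
#' be non-negative, at least two cell types, no all-zero column.
#'
#' @inheritParams read_expression
#' @return numeric matrix, genes x cell types.
#' @export
read_signature <- function(path, delimiter = "\t") {
  sig <- read_expression(path, delimiter)
  validate_signature(sig)
  sig
}

#' Validate a signature matrix
#' @param sig candidate genes x cell-types matrix.
#' @return `sig`, invisibly, or an error.
#' @export
validate_signature <- function(sig) {
  validate_expression(sig)
  if (ncol(sig) < 2L) stop("signature matrix needs at least 2 cell types")
  if (any(sig < 0)) stop("signature matrix must be non-negative")
  if (any(colSums(sig) == 0)) {
    stop("signature column(s) all zero: ",
         paste(colnames(sig)[colSums(sig) == 0], collapse = ", "))
  }
  invisible(sig)
}

#' Write a labelled numeric matrix as TSV
#'
#' First column carries the rownames under `id_label`; round-trips through
#' [read_expression()].
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_label header for the rowname column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_label = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
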