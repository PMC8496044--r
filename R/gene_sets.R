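#' Gene-set collections
#'
#' A `GeneSetCollection` is a lightweight container for named gene sets:
#' a named list of unique upper-cased gene symbols plus per-set free-text
#' descriptions and a provenance label.  It is the in-memory form of a GMT
#' file and the unit the enrichment engine consumes.
#'
#' @param sets named list of character vectors (member gene symbols).
#' @param descriptions character vector of per-set descriptions, recycled
#'   to `length(sets)`; defaults to empty strings.
#' @param source_label single string recording where the collection came
#'   from (file path, "synthetic", ...).
#' @return an object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source_label = "") {
  if (!is.list(sets) || length(sets) == 0L) {
    stop("'sets' must be a non-empty named list of gene vectors")
  }
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every gene set must have a non-empty name")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) {
    g <- normalize_symbols(g)
    g <- g[nzchar(g)]
    unique(g)
  })
  if (any(lengths(sets) == 0L)) {
    stop("gene set(s) with no members: ",
         paste(nm[lengths(sets) == 0L], collapse = ", "))
  }
  names(sets) <- nm
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- nm
  structure(
    list(sets = sets, descriptions = descriptions,
         source_label = as.character(source_label)[1]),
    class = "GeneSetCollection"
  )
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
names.GeneSetCollection <- function(x) names(x$sets)

#' @export
`[.GeneSetCollection` <- function(x, i) {
  gene_set_collection(x$sets[i], x$descriptions[i], x$source_label)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection of %d sets (source: %s)\n",
              length(x), if (nzchar(x$source_label)) x$source_label else "?"))
  sz <- lengths(x$sets)
  cat(sprintf("  set sizes: min %d / median %g / max %d\n",
              min(sz), stats::median(sz), max(sz)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is the standard tab-separated carrier for gene sets: one set per
#' line as `name<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate member
#' symbols within a line are removed with a warning; line order is
#' preserved; duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- c(fields[1:2], fields[-(1:2)][nzchar(fields[-(1:2)])])
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields", i, path))
    }
    genes <- normalize_symbols(fields[-(1:2)])
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicate member symbol(s) removed",
                      i, fields[1], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    nm[i] <- fields[1]
    desc[i] <- fields[2]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(sets) <- nm
  gene_set_collection(sets, desc, source_label = path)
}

#' Write a GMT gene-set file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, f))` reproduces `x`
#' exactly (names, order, members).  Tabs inside descriptions would break
#' the format and are replaced by spaces with a warning.
#'
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  desc <- collection$descriptions
  if (any(grepl("\t", desc, fixed = TRUE))) {
    warning("tab character(s) in set description replaced by spaces")
    desc <- gsub("\t", " ", desc, fixed = TRUE)
  }
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], desc[i], collection$sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path path to the list file.
#' @return character vector of unique upper-cased symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  genes <- unique(normalize_symbols(lines[nzchar(lines)]))
  if (length(genes) == 0L) stop("gene list is empty: ", path)
  genes
}

#' Restrict gene sets to measured genes and filter by size
#'
#' Each set's members are intersected with the rows of the expression
#' matrix; sets whose intersected size falls outside `[min_size, max_size]`
#' are dropped with a message.  The defaults 5-500 follow GSEA community
#' convention.
#'
#' @param collection a `GeneSetCollection`.
#' @param expr expression matrix (genes in rownames) or a character vector
#'   of gene symbols (the universe).
#' @param min_size,max_size inclusive bounds on intersected set size.
#' @return the filtered `GeneSetCollection`.
#' @export
filter_gene_sets <- function(collection, expr, min_size = 5L, max_size = 500L) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (min_size < 1L) stop("min_size must be >= 1")
  if (max_size < min_size) stop("max_size must be >= min_size")
  universe <- if (is.character(expr)) normalize_symbols(expr)
              else normalize_symbols(rownames(expr))
  sets <- lapply(collection$sets, function(g) g[g %in% universe])
  sz <- lengths(sets)
  keep <- sz >= min_size & sz <= max_size
  if (!all(keep)) {
    message(sprintf("filter_gene_sets: dropped %d set(s): %s",
                    sum(!keep),
                    paste(sprintf("%s (n=%d)", names(sets)[!keep], sz[!keep]),
                          collapse = ", ")))
  }
  if (!any(keep)) {
    stop("all gene sets dropped after intersection/size filtering; ",
         "relax min_size/max_size or check gene symbols")
  }
  gene_set_collection(sets[keep], collection$descriptions[keep],
                      collection$source_label)
}

#' Packaged synthetic DDR pathway collection
#'
#' A 27-pathway DNA damage response collection covering the five canonical
#' repair pathways (MMR, BER, NER, HR, NHEJ), double-strand-break
#' sub-processes (including homologous DNA pairing and strand exchange),
#' damage signalling and tolerance.  Member lists are curated from widely
#' known pathway genes and are a documented synthetic stand-in, not the
#' KEGG/Reactome source files; replace with your own GMT for real analyses.
#'
#' @return a `GeneSetCollection` of 27 sets.
#' @export
ddr_pathways <- function() {
  read_gmt(system.file("extdata", "ddr_pathways_synthetic.gmt",
                       package = "ddrimmune", mustWork = TRUE))
}

#' Packaged synthetic immune pathway collection
#'
#' Small hallmark-style immune gene sets (interferon response, inflammation,
#' cytotoxicity, antigen presentation, ...) used for the immune side of the
#' correlation matrix.  Synthetic stand-in; user-replaceable.
#'
#' @return a `GeneSetCollection`.
#' @export
immune_pathways <- function() {
  read_gmt(system.file("extdata", "immune_pathways_synthetic.gmt",
                       package = "ddrimmune", mustWork = TRUE))
}

#' Packaged synthetic immune-specific gene list
#'
#' Canonical immune lineage and effector genes used for the immune content
#' score.  Synthetic stand-in for a literature-derived list; user-replaceable.
#'
#' @return character vector of gene symbols.
#' @export
immune_gene_list <- function() {
  read_gene_list(system.file("extdata", "immune_genes_synthetic.txt",
                             package = "ddrimmune", mustWork = TRUE))
}
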