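#' Derive a stage seed from the root seed
#'
#' All randomness in a pipeline run flows from one root seed; each stage
#' reseeds with `root + a fixed per-stage offset` so stages can be rerun
#' in isolation and still reproduce the full run's results.
#'
#' @param root integer root seed.
#' @param stage one of `"simulate"`, `"score"`, `"immune"`.
#' @return integer seed.
#' @export
stage_seed <- function(root, stage = c("simulate", "score", "immune")) {
  stage <- match.arg(stage)
  offset <- c(simulate = 0L, score = 101L, immune = 202L)[[stage]]
  as.integer((as.integer(root) + offset) %% .Machine$integer.max)
}

#' Validate a pipeline run configuration
#'
#' Accepts a JSON file path or a plain list.  Checks that every referenced
#' input exists and every parameter is in range, fills defaults, and
#' reports *all* violations at once rather than the first.
#'
#' @param config path to a JSON config file, or a named list with keys
#'   `expression`, `ddr_gmt` (paths, required), optional `immune_gmt`,
#'   `immune_genes`, `signature` (paths), `outdir`, `seed`, and enrichment
#'   / deconvolution / clustering parameters (`weight`, `n_perm`,
#'   `min_size`, `max_size`, `deconv_method`, `distance`, `linkage`).
#' @return a validated `RunConfig` list with defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(immune_gmt = NULL, immune_genes = NULL, signature = NULL,
                   outdir = "ddrimmune_run", seed = 1L, weight = 1,
                   n_perm = 1000L, min_size = 5L, max_size = 500L,
                   deconv_method = "nnls", distance = "euclidean",
                   linkage = "average")
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[k] <- defaults[k]
  }
  problems <- character(0)
  for (k in c("expression", "ddr_gmt")) {
    if (is.null(config[[k]])) {
      problems <- c(problems, sprintf("missing required path '%s'", k))
    }
  }
  for (k in c("expression", "ddr_gmt", "immune_gmt", "immune_genes",
              "signature")) {
    p <- config[[k]]
    if (!is.null(p) && !file.exists(p)) {
      problems <- c(problems, sprintf("'%s' path does not exist: %s", k, p))
    }
  }
  if (!is.null(config$n_perm) && config$n_perm < 1) {
    problems <- c(problems, "n_perm must be >= 1")
  }
  if (!is.null(config$min_size) &&
      (config$min_size < 1 || config$max_size < config$min_size)) {
    problems <- c(problems, "need 1 <= min_size <= max_size")
  }
  if (!config$deconv_method %in% c("nnls", "nu_svr")) {
    problems <- c(problems, "deconv_method must be 'nnls' or 'nu_svr'")
  }
  if (length(problems) > 0) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(config, class = "RunConfig")
}

#' Run the full profiling and correlation pipeline
#'
#' End to end: load inputs, score the DDR collection per sample
#' ([score_cohort()]), assemble immune features
#' ([build_immune_features()]), correlate DDR pathway activity against
#' the immune features and against itself ([spearman_matrix()]), cluster
#' the activity matrix, and write all tables plus a run manifest under
#' `config$outdir`.  Identical (inputs, config, seed) give identical
#' outputs; the manifest is written on failure too, recording the failing
#' stage.
#'
#' @param config a `RunConfig` (or anything [validate_config()] accepts).
#' @return invisibly, a list with `activity` (`PathwayActivity`),
#'   `immune` (`ImmuneFeatures`), `ddr_immune` and `ddr_ddr`
#'   (`CorrelationMatrix`), `clustering`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("ddrimmune")),
                   input_checksums = vapply(
                     Filter(Negate(is.null),
                            config[c("expression", "ddr_gmt", "immune_gmt",
                                     "immune_genes", "signature")]),
                     function(p) unname(tools::md5sum(p)), character(1)),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), warnings = character(0), status = "running")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  stage <- function(name, code) {
    ts <- Sys.time()
    out <- withCallingHandlers(
      tryCatch(code, error = function(e) {
        manifest$status <<- paste0("failed at stage '", name, "': ",
                                   conditionMessage(e))
        flush_manifest()
        stop(e)
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), ts, units = "secs")))
    out
  }

  inputs <- stage("load", {
    list(expr = read_expression(config$expression),
         ddr = read_gmt(config$ddr_gmt),
         immune_sets = if (!is.null(config$immune_gmt)) read_gmt(config$immune_gmt),
         immune_genes = if (!is.null(config$immune_genes)) read_gene_list(config$immune_genes),
         signature = if (!is.null(config$signature)) read_signature(config$signature))
  })

  activity <- stage("score", {
    score_cohort(inputs$expr, inputs$ddr, weight = config$weight,
                 n_perm = config$n_perm, min_size = config$min_size,
                 max_size = config$max_size,
                 seed = stage_seed(config$seed, "score"))
  })
  stage("write_activity", {
    write_matrix_tsv(activity$nes, file.path(config$outdir, "ddr_nes.tsv"),
                     id_label = "sample")
    utils::write.table(activity$results,
                       file.path(config$outdir, "ddr_enrichment_long.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  immune <- stage("immune", {
    build_immune_features(inputs$expr, immune_genes = inputs$immune_genes,
                          immune_sets = inputs$immune_sets,
                          signature = inputs$signature,
                          method = config$deconv_method,
                          n_perm = config$n_perm, weight = config$weight,
                          min_size = config$min_size,
                          max_size = config$max_size,
                          seed = stage_seed(config$seed, "immune"))
  })
  stage("write_immune", {
    write_immune_features(immune, file.path(config$outdir, "immune_features.tsv"))
  })

  cors <- stage("correlate", {
    A <- activity$nes
    keep <- apply(A, 1, function(r) !anyNA(r))
    list(ddr_immune = spearman_matrix(A[keep, , drop = FALSE],
                                      immune$values[keep, , drop = FALSE]),
         ddr_ddr = spearman_matrix(A[keep, , drop = FALSE]))
  })
  stage("write_correlations", {
    for (nm in names(cors)) {
      cm <- cors[[nm]]
      write_matrix_tsv(cm$rho, file.path(config$outdir, paste0(nm, "_rho.tsv")),
                       id_label = "pathway")
      write_matrix_tsv(cm$p, file.path(config$outdir, paste0(nm, "_p.tsv")),
                       id_label = "pathway")
      write_matrix_tsv(cm$q, file.path(config$outdir, paste0(nm, "_q.tsv")),
                       id_label = "pathway")
      utils::write.table(cm$long,
                         file.path(config$outdir, paste0(nm, "_long.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })

  clustering <- stage("cluster", {
    cl <- cluster_matrix(activity$nes, axis = "both",
                         distance = config$distance, linkage = config$linkage)
    jsonlite::write_json(
      list(row_order = cl$row_order, col_order = cl$col_order,
           rows = rownames(activity$nes)[cl$row_order],
           columns = colnames(activity$nes)[cl$col_order],
           distance = config$distance, linkage = config$linkage),
      file.path(config$outdir, "clustering.json"),
      auto_unbox = TRUE, digits = NA)
    cl
  })

  manifest$status <- "ok"
  manifest$decisions <- list(
    dropped_sets = setdiff(names(inputs$ddr), colnames(activity$nes)),
    degenerate_samples = activity$degenerate_samples,
    fdr = activity$params$fdr,
    correlation_fdr = cors$ddr_immune$fdr)
  flush_manifest()
  invisible(list(activity = activity, immune = immune,
                 ddr_immune = cors$ddr_immune, ddr_ddr = cors$ddr_ddr,
                 clustering = clustering, manifest = manifest))
}
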