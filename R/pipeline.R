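#' Assemble a pipeline configuration
#'
#' Collects paths and thresholds for [run_pipeline()]. Can be built
#' directly or loaded from YAML with [read_pipeline_config()].
#'
#' @param catalog Path to the dataset catalog CSV (see [read_catalog()]).
#' @param data_dir Directory holding `<dataset_id>_matrix.tsv` and
#'   `<dataset_id>_labels.csv` per catalog entry (the layout
#'   [write_simulation()] produces).
#' @param gmt Path to a GMT gene-set collection, or `NULL` to skip the
#'   enrichment stages.
#' @param relations Path to a relations CSV, or `NULL` to skip the
#'   relation-network stages.
#' @param genes Optional path to a one-column gene list restricting the
#'   panel; default: every gene regulating `downstream` in the relation
#'   table, falling back to all measured genes.
#' @param alpha Per-gene significance threshold for the mega table.
#' @param adjust Multiplicity adjustment for the mega table
#'   (`"none"`/`"BH"`/`"bonferroni"`).
#' @param fdr_q Unused by the enrichment test itself; retained in the
#'   manifest for provenance.
#' @param ggi_threshold Enrichment cutoff for the gene-gene network.
#' @param ggi_on `"p"` or `"q"`: which column the cutoff applies to.
#' @param model `"auto"` (the Q vs df switch), `"fixed"`, or `"random"`.
#' @param mlr_mode `"univariate"` or `"joint"`.
#' @param tau2_method `"DL"` or `"REML"`.
#' @param upstream,downstream Disease node names for the relation network.
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed matters when simulation precedes it).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(catalog, data_dir, gmt = NULL, relations = NULL,
                            genes = NULL, alpha = 0.05, adjust = "none",
                            fdr_q = 0.001, ggi_threshold = 0.001,
                            ggi_on = "p", model = "auto",
                            mlr_mode = "univariate", tau2_method = "DL",
                            upstream = "AD", downstream = "MDD", seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, ggi_threshold > 0, ggi_threshold < 1)
  structure(list(catalog = catalog, data_dir = data_dir, gmt = gmt,
                 relations = relations, genes = genes, alpha = alpha,
                 adjust = adjust, fdr_q = fdr_q,
                 ggi_threshold = ggi_threshold, ggi_on = ggi_on,
                 model = model, mlr_mode = mlr_mode,
                 tau2_method = tau2_method, upstream = upstream,
                 downstream = downstream, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

.stage <- function(name, expr) {
  message(sprintf("[megaDE] stage %s", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full mega-analysis workflow
#'
#' Executes catalog filtering, per-study effect computation, mega-analysis
#' combination, study-level covariate regression, literature + expression
#' direction classification, gene-set enrichment, and gene-gene network
#' assembly, writing every stage's table under `out_dir` together with a
#' run manifest. Given identical inputs and configuration the outputs are
#' byte-identical across reruns.
#'
#' Outputs: `effects.tsv`, `mega_table.tsv`, `covariates.tsv`,
#' `verdicts.tsv` (literature and expression verdicts stacked),
#' `enrichment.tsv`, `ggi_edges.tsv`, `ggi.graphml`,
#' `relations.graphml`, `manifest.json`. Enrichment/relation outputs are
#' only produced when the corresponding inputs are configured.
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly; the loaded tables are
#'   attached as the attribute `"results"`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  catalog <- .stage("catalog", {
    filter_dataset_catalog(read_catalog(config$catalog))
  })
  if (nrow(catalog) == 0L) stop("no dataset passes the inclusion criteria")

  datasets <- .stage("load", {
    lapply(catalog$dataset_id, function(id) {
      read_expression_matrix(
        file.path(config$data_dir, paste0(id, "_matrix.tsv")),
        file.path(config$data_dir, paste0(id, "_labels.csv")),
        dataset_id = id)
    })
  })

  relations <- NULL
  mdd_map <- NULL
  if (!is.null(config$relations)) {
    relations <- .stage("relations", read_relations(config$relations))
    mdd_map <- signed_regulators(relations, config$downstream)
  }

  panel <- .stage("panel", {
    measured <- sort(unique(unlist(lapply(datasets,
                                          function(d) rownames(d$matrix)))))
    if (!is.null(config$genes)) {
      intersect(readLines(config$genes, warn = FALSE), measured)
    } else if (!is.null(mdd_map) &&
               length(intersect(mdd_map$entity, measured))) {
      sort(intersect(mdd_map$entity, measured))
    } else measured
  })
  if (length(panel) == 0L) stop("gene panel is empty")

  effects <- .stage("effects", effects_table(datasets, panel))
  write_effects(effects, file.path(out_dir, "effects.tsv"))

  mega <- .stage("mega", {
    tbl <- mega_table(datasets, panel, alpha = config$alpha,
                      adjust = config$adjust, method = config$tau2_method)
    if (config$model == "fixed") {
      tbl$model <- "fixed"; tbl$random_model <- 0L
    } else if (config$model == "random") {
      tbl$model <- "random"; tbl$random_model <- 1L
    }
    tbl
  })
  write_mega_table(mega, file.path(out_dir, "mega_table.tsv"))

  covars <- .stage("mlr", {
    covariate_table(effects[effects$variance > 0, , drop = FALSE],
                    catalog, mode = config$mlr_mode)
  })
  utils::write.table(covars, file.path(out_dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  results <- list(catalog = catalog, effects = effects, mega = mega,
                  covariates = covars)

  if (!is.null(relations)) {
    verdicts <- .stage("classify", {
      lit <- intersect_regulators(
        signed_targets(relations, config$upstream), mdd_map)
      expr <- expression_verdicts(mega, mdd_map)
      rbind(lit, expr)
    })
    write_verdicts(verdicts, file.path(out_dir, "verdicts.tsv"))
    write_relations_graphml(verdicts, file.path(out_dir, "relations.graphml"),
                            upstream = config$upstream,
                            downstream = config$downstream)
    results$verdicts <- verdicts
  }

  if (!is.null(config$gmt)) {
    enr <- .stage("pea", {
      query <- mega$gene[mega$significant]
      collection <- read_gmt(config$gmt)
      background <- unique(c(unlist(lapply(collection, `[[`, "members"),
                                    use.names = FALSE), panel))
      fisher_enrichment(query, collection, background)
    })
    write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))
    ggi <- .stage("ggi", build_ggi(enr, threshold = config$ggi_threshold,
                                   on = config$ggi_on))
    write_ggi(ggi, file.path(out_dir, "ggi_edges.tsv"),
              file.path(out_dir, "ggi.graphml"))
    results$enrichment <- enr
    results$ggi <- ggi
  }

  .stage("manifest", {
    manifest <- list(
      config = unclass(config),
      package = "megaDE",
      package_version = as.character(utils::packageVersion("megaDE")),
      r_version = R.version.string,
      n_datasets = nrow(catalog),
      n_genes = length(panel))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  })

  out <- out_dir
  attr(out, "results") <- results
  invisible(out)
}
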