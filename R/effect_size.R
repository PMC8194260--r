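#' Per-study effect size of one gene
#'
#' The effect size is the log2 fold change (LFC): the difference of group
#' means on the log2 scale, case minus control. Its sampling variance is
#' the two-sample (Welch-style) variance of a difference of means,
#' `s2_case/n_case + s2_control/n_control`, with unbiased sample variances
#' — the quantity the inverse-variance weights of [mega_analyze()] need.
#'
#' Missing values are ignored; each group must retain at least two
#' non-missing samples for the variance to be estimable. A gene absent
#' from the dataset, or with a degenerate group, yields `NULL` (the gene
#' is simply not measurable in that study and is skipped upstream).
#'
#' @param ds An [expression_dataset()].
#' @param gene Gene identifier (a row of the dataset).
#' @return A one-row data.frame (`dataset_id`, `gene`, `lfc`, `variance`,
#'   `n_case`, `n_control`), or `NULL` if the gene is not measurable.
#'   A zero variance (no within-group spread) is returned as-is; the
#'   combination step refuses such degenerate weights.
#' @export
study_effect <- function(ds, gene) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!gene %in% rownames(ds$matrix)) return(NULL)
  x <- ds$matrix[gene, ]
  ca <- x[ds$sample_groups == "case"]
  co <- x[ds$sample_groups == "control"]
  ca <- ca[!is.na(ca)]
  co <- co[!is.na(co)]
  if (length(ca) < 2L || length(co) < 2L) return(NULL)
  data.frame(dataset_id = ds$dataset_id, gene = gene,
             lfc = mean(ca) - mean(co),
             variance = stats::var(ca) / length(ca) +
               stats::var(co) / length(co),
             n_case = length(ca), n_control = length(co),
             stringsAsFactors = FALSE)
}

#' Collect one gene's effects across studies
#'
#' One row per dataset in which the gene is measurable (present, with at
#' least two non-missing samples per group); datasets are visited in input
#' order, so the result may have fewer rows than there are datasets.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param gene Gene identifier.
#' @return A data.frame of per-study effects (possibly zero rows).
#' @export
effects_for_gene <- function(datasets, gene) {
  rows <- lapply(datasets, study_effect, gene = gene)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(dataset_id = character(), gene = character(),
                      lfc = numeric(), variance = numeric(),
                      n_case = integer(), n_control = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Per-study effect table for a gene panel
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param genes Character vector of gene identifiers; defaults to the
#'   union of all dataset rows.
#' @return Long data.frame, one row per (gene, contributing study).
#' @export
effects_table <- function(datasets, genes = NULL) {
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(datasets, function(d) rownames(d$matrix)))))
  do.call(rbind, lapply(genes, function(g) effects_for_gene(datasets, g)))
}

#' Write a per-study effect table as TSV
#' @param effects Data.frame from [effects_table()].
#' @param path Output path.
#' @return `effects`, invisibly.
#' @export
write_effects <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(effects)
}
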