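#' Construct an expression dataset
#'
#' Bundles one study's log2 expression matrix with per-sample case/control
#' labels and study-level metadata. This is the unit of input for the
#' mega-analysis: effect sizes are computed per dataset and then combined.
#'
#' @param dataset_id Character scalar identifying the study (e.g. a GEO
#'   series accession).
#' @param matrix Numeric matrix, genes in rows (rownames = gene or probe
#'   identifiers), samples in columns (colnames = sample identifiers),
#'   values on the log2 scale. `NA` marks missing measurements.
#' @param sample_groups Character vector, one entry per column of `matrix`,
#'   each `"case"` or `"control"`. Names, if present, must match the
#'   column names.
#' @param meta A [dataset_meta()] object, or `NULL`.
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, matrix, sample_groups, meta = NULL) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)) || anyNA(rownames(matrix)))
    stop("`matrix` must have row names (gene/probe identifiers)")
  if (is.null(colnames(matrix)))
    stop("`matrix` must have column names (sample identifiers)")
  if (length(sample_groups) != ncol(matrix))
    stop("`sample_groups` must have one label per sample column")
  if (!is.null(names(sample_groups))) {
    if (!setequal(names(sample_groups), colnames(matrix)))
      stop("names of `sample_groups` do not match the matrix columns")
    sample_groups <- sample_groups[colnames(matrix)]
  }
  bad <- setdiff(unique(sample_groups), c("case", "control"))
  if (length(bad))
    stop("sample group labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  if (any(!is.finite(matrix) & !is.na(matrix)))
    stop("matrix values must be finite or NA")
  structure(
    list(dataset_id = dataset_id,
         matrix = matrix,
         sample_groups = stats::setNames(as.character(sample_groups),
                                         colnames(matrix)),
         meta = meta),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d genes x %d samples (%d case / %d control)\n",
              x$dataset_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$sample_groups == "case"), sum(x$sample_groups == "control")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Genes of an expression dataset
#' @param ds An `expression_dataset`.
#' @return Character vector of row identifiers.
#' @export
genes <- function(ds) rownames(ds$matrix)

#' Study-level metadata record
#'
#' One row of the dataset catalog: the sample counts, country of origin and
#' study age used as covariates in [covariate_regression()], plus the
#' fields tested by [filter_dataset_catalog()].
#'
#' @param dataset_id Study identifier.
#' @param n_control,n_case Non-negative sample counts.
#' @param country Country of origin.
#' @param study_age Age of the study in years (>= 0).
#' @param organism Organism name, e.g. `"Homo sapiens"`.
#' @param platform Array platform identifier.
#' @param data_type Dataset type string.
#' @param comparison Comparison design string.
#' @param downloadable Logical: is the raw data retrievable.
#'
#' @return A one-row `data.frame` of class `dataset_meta`.
#' @export
dataset_meta <- function(dataset_id, n_control, n_case, country = NA_character_,
                         study_age = NA_real_, organism = "Homo sapiens",
                         platform = NA_character_,
                         data_type = "microarray expression profiling",
                         comparison = "AD vs healthy controls",
                         downloadable = TRUE) {
  stopifnot(n_control >= 0, n_case >= 0)
  if (!is.na(study_age) && study_age < 0) stop("`study_age` must be >= 0")
  structure(
    data.frame(dataset_id = dataset_id, n_control = as.integer(n_control),
               n_case = as.integer(n_case), country = country,
               study_age = as.numeric(study_age), organism = organism,
               platform = platform, data_type = data_type,
               comparison = comparison, downloadable = as.logical(downloadable),
               stringsAsFactors = FALSE),
    class = c("dataset_meta", "data.frame")
  )
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix with its case/control labels
#'
#' Reads a delimited text matrix (genes/probes in rows, first column the
#' row identifier, header row the sample identifiers) together with a
#' two-column labels file mapping every sample to `"case"` or `"control"`.
#' If the matrix appears to be on a linear intensity scale (maximum value
#' above `linear_threshold`) it is transformed by `log2(x + 1)`; log2-scale
#' matrices are left untouched. Row order is preserved.
#'
#' @param path Path to the matrix file (TSV or CSV by extension).
#' @param labels_path Path to a two-column CSV/TSV (`sample_id`, `group`).
#' @param dataset_id Identifier for the dataset; defaults to the matrix
#'   file name without extension.
#' @param meta Optional [dataset_meta()] to attach.
#' @param linear_threshold Values above this trigger the log2 transform
#'   (default 30: log2 microarray data rarely exceeds ~20).
#'
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, labels_path, dataset_id = NULL,
                                   meta = NULL, linear_threshold = 30) {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, sep = .delim_for(path), header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("matrix file must have an id column plus samples")
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("", "NA", "na", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at row %d (gene %s), column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  rownames(num) <- ids

  lab <- utils::read.table(labels_path, sep = .delim_for(labels_path),
                           header = TRUE, colClasses = "character",
                           check.names = FALSE)
  if (ncol(lab) < 2L) stop("labels file must have columns sample_id, group")
  groups <- stats::setNames(tolower(trimws(lab[[2L]])), trimws(lab[[1L]]))
  missing <- setdiff(colnames(num), names(groups))
  if (length(missing))
    stop("sample(s) present in matrix but absent from labels: ",
         paste(missing, collapse = ", "))
  groups <- groups[colnames(num)]

  mx <- suppressWarnings(max(num, na.rm = TRUE))
  if (is.finite(mx) && mx > linear_threshold) num <- log2(num + 1)

  expression_dataset(dataset_id, num, groups, meta)
}

#' Write an expression dataset back to matrix + labels files
#'
#' Inverse of [read_expression_matrix()]: the written pair reads back to a
#' value-identical dataset (values are written in full precision).
#'
#' @param ds An `expression_dataset`.
#' @param path Matrix output path (TSV or CSV by extension).
#' @param labels_path Labels output path.
#' @return `ds`, invisibly.
#' @export
write_expression_matrix <- function(ds, path, labels_path) {
  sep <- .delim_for(path)
  df <- data.frame(gene = rownames(ds$matrix),
                   format(ds$matrix, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = names(ds$sample_groups),
                    group = unname(ds$sample_groups))
  utils::write.table(lab, labels_path, sep = .delim_for(labels_path),
                     quote = FALSE, row.names = FALSE)
  invisible(ds)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Array platforms measure probes, not genes; before cross-study
#' combination every dataset must carry one row per gene. Probes missing
#' from `probe_map` are dropped.
#'
#' @param ds An `expression_dataset` whose rows are probes.
#' @param probe_map Two-column data.frame (`probe`, `gene`) or a named
#'   character vector (`names` = probes, values = genes).
#' @param method `"max_mean"` keeps, per gene, the probe with the highest
#'   mean expression (ties broken lexicographically by probe id);
#'   `"average"` takes the per-sample mean across the gene's probes.
#'
#' @return An `expression_dataset` with one row per mapped gene, gene rows
#'   ordered by gene id.
#' @export
collapse_probes <- function(ds, probe_map, method = c("max_mean", "average")) {
  method <- match.arg(method)
  if (is.data.frame(probe_map)) {
    map <- stats::setNames(as.character(probe_map[[2L]]),
                           as.character(probe_map[[1L]]))
  } else {
    map <- probe_map
  }
  probes <- intersect(rownames(ds$matrix), names(map))
  if (length(probes) == 0L)
    stop("no probe in the dataset is covered by `probe_map`")
  sub <- ds$matrix[probes, , drop = FALSE]
  gene_of <- map[probes]
  out_genes <- sort(unique(unname(gene_of)))
  collapsed <- matrix(NA_real_, length(out_genes), ncol(sub),
                      dimnames = list(out_genes, colnames(sub)))
  for (g in out_genes) {
    rows <- sort(probes[gene_of == g])   # lexicographic, fixes ties
    if (method == "average") {
      collapsed[g, ] <- colMeans(sub[rows, , drop = FALSE], na.rm = TRUE)
    } else {
      means <- rowMeans(sub[rows, , drop = FALSE], na.rm = TRUE)
      keep <- rows[which.max(means)]     # first max = lexicographically least
      collapsed[g, ] <- sub[keep, ]
    }
  }
  collapsed[is.nan(collapsed)] <- NA_real_
  expression_dataset(ds$dataset_id, collapsed, ds$sample_groups, ds$meta)
}

.norm_str <- function(x) tolower(gsub("\\s+", " ", trimws(as.character(x))))

#' Apply the dataset inclusion criteria to a catalog
#'
#' Retains, in input order, catalog entries that satisfy all four
#' inclusion criteria: human organism, microarray expression profiling,
#' a disease-versus-healthy-controls comparison, and downloadable data.
#' Matching is case- and whitespace-insensitive. The filter is idempotent.
#'
#' @param catalog A data.frame with columns `organism`, `data_type`,
#'   `comparison`, `downloadable` (e.g. rows built by [dataset_meta()] or
#'   read by [read_catalog()]).
#' @param organism,data_type,comparison Required values.
#' @return The retained rows, in input order.
#' @export
filter_dataset_catalog <- function(catalog,
                                   organism = "Homo sapiens",
                                   data_type = "microarray expression profiling",
                                   comparison = "AD vs healthy controls") {
  need <- c("organism", "data_type", "comparison", "downloadable")
  miss <- setdiff(need, names(catalog))
  if (length(miss)) stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  dl <- catalog$downloadable
  if (!is.logical(dl)) dl <- .norm_str(dl) %in% c("true", "yes", "1")
  keep <- .norm_str(catalog$organism) == .norm_str(organism) &
    .norm_str(catalog$data_type) == .norm_str(data_type) &
    .norm_str(catalog$comparison) == .norm_str(comparison) &
    dl
  catalog[which(keep), , drop = FALSE]
}

#' Read a dataset catalog CSV
#'
#' @param path CSV with columns `dataset_id`, `n_control`, `n_case`,
#'   `country`, `study_age`, `organism`, `platform`, `data_type`,
#'   `comparison`, `downloadable`.
#' @return A data.frame.
#' @export
read_catalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("downloadable" %in% names(cat) && !is.logical(cat$downloadable))
    cat$downloadable <- .norm_str(cat$downloadable) %in% c("true", "yes", "1")
  cat
}

#' Write a dataset catalog CSV
#' @param catalog Data.frame of catalog rows.
#' @param path Output path.
#' @return `catalog`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE, quote = TRUE)
  invisible(catalog)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, `set_id TAB description TAB
#' member ...`. Duplicate members within a line are deduplicated.
#'
#' @param path Path to a GMT file.
#' @return A list of gene sets, each a list with elements `set_id`,
#'   `name` (the description field) and `members` (character vector).
#'   The list is named by `set_id`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(list(), character()))
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); at least 3 required", i,
                   length(f)))
    sets[[i]] <- list(set_id = f[1L], name = f[2L],
                      members = unique(f[-(1:2)]))
  }
  stats::setNames(sets, vapply(sets, `[[`, "", "set_id"))
}

#' Write a GMT gene-set collection
#' @param collection List of gene sets as returned by [read_gmt()], or a
#'   named list of character vectors.
#' @param path Output path.
#' @return `collection`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  collection <- .as_collection(collection)
  lines <- vapply(collection, function(s)
    paste(c(s$set_id, s$name, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(collection)
}

# Coerce a named list of member vectors into the gene-set list structure.
.as_collection <- function(collection) {
  if (length(collection) == 0L) return(collection)
  if (is.list(collection[[1L]]) && !is.null(collection[[1L]]$members))
    return(collection)
  if (is.null(names(collection)))
    stop("a plain list collection must be named by set id")
  out <- lapply(names(collection), function(id)
    list(set_id = id, name = id, members = unique(as.character(collection[[id]]))))
  stats::setNames(out, names(collection))
}

.POLARITY_TOKENS <- c(positive = 1L, negative = -1L, unknown = 0L)

#' Read a signed relation table
#'
#' Reads a CSV of directed literature-curated relations
#' (`source`, `source_type`, `target`, `polarity`, `n_refs`[, `evidence`]).
#' Polarity tokens `positive`/`negative`/`unknown` map to `+1`/`-1`/`0`.
#' Unknown columns are carried through untouched.
#'
#' @param path Path to the relations CSV.
#' @return A data.frame with integer `polarity` in `{-1, 0, 1}`.
#' @export
read_relations <- function(path) {
  rel <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("source", "source_type", "target", "polarity", "n_refs")
  miss <- setdiff(need, names(rel))
  if (length(miss)) stop("relations file lacks column(s): ",
                         paste(miss, collapse = ", "))
  tok <- .norm_str(rel$polarity)
  bad <- setdiff(unique(tok), names(.POLARITY_TOKENS))
  if (length(bad))
    stop("unknown polarity token(s): ", paste(bad, collapse = ", "))
  rel$polarity <- unname(.POLARITY_TOKENS[tok])
  rel$n_refs <- as.integer(rel$n_refs)
  if (any(rel$n_refs < 0, na.rm = TRUE)) stop("n_refs must be >= 0")
  rel
}

#' Write a signed relation table
#'
#' Inverse of [read_relations()]: integer polarities are written back as
#' `positive`/`negative`/`unknown` tokens.
#'
#' @param relations Data.frame with integer `polarity`.
#' @param path Output path.
#' @return `relations`, invisibly.
#' @export
write_relations <- function(relations, path) {
  out <- relations
  out$polarity <- names(.POLARITY_TOKENS)[match(relations$polarity,
                                                .POLARITY_TOKENS)]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(relations)
}
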