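#' Fisher-exact gene-set over-representation
#'
#' For each set in the collection, tests whether the query list overlaps
#' the set more than expected by chance, using the upper-tail
#' hypergeometric probability `P(X >= k)` of drawing `n` query genes from
#' a background of `N` containing `K` set members. This one-sided Fisher
#' exact test is the classic over-representation statistic. Benjamini-
#' Hochberg q-values over the collection are attached.
#'
#' The background defaults to the union of all collection members and the
#' query; when supplied explicitly, the query must be contained in it and
#' every set is intersected with it.
#'
#' @param query Character vector of query gene identifiers.
#' @param collection Gene-set collection ([read_gmt()] output, or a named
#'   list of member vectors).
#' @param background Optional character vector: the gene universe.
#' @return Data.frame sorted by ascending `p` (ties by `set_id`) with
#'   columns `set_id`, `name`, `k`, `K`, `n`, `N`, `p`, `q`, and a list
#'   column `overlap` holding the overlapping genes.
#' @export
fisher_enrichment <- function(query, collection, background = NULL) {
  collection <- .as_collection(collection)
  query <- unique(as.character(query))
  if (is.null(background)) {
    background <- unique(c(unlist(lapply(collection, `[[`, "members"),
                                  use.names = FALSE), query))
  } else {
    background <- unique(as.character(background))
    out_of_bg <- setdiff(query, background)
    if (length(out_of_bg))
      stop("query gene(s) outside the background: ",
           paste(out_of_bg, collapse = ", "))
  }
  if (length(background) == 0L) stop("background is empty")
  N <- length(background)
  n <- length(intersect(query, background))

  rows <- lapply(collection, function(s) {
    members <- intersect(s$members, background)
    ov <- sort(intersect(query, members))
    K <- length(members)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = s$set_id, name = s$name, k = k, K = K, n = n, N = N,
               p = p, stringsAsFactors = FALSE,
               overlap = I(list(ov)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_id = character(), name = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p = numeric(), q = numeric(),
                      overlap = I(list()), stringsAsFactors = FALSE))
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set_id", "name", "k", "K", "n", "N", "p", "q", "overlap")]
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted values `q(i) = min_{j >= i} (m * p(j) / j)` over the p-values
#' sorted ascending, capped at 1 and returned in input order. Delegates to
#' the stock step-up implementation after validating the input range.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return Numeric vector of q-values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("all p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Shared-pathway gene-gene interaction network
#'
#' Two genes are connected when they co-occur in the overlap of at least
#' one enriched set; the edge weight counts how many sets passing the
#' threshold the pair shares. Edges are canonical (`gene_a < gene_b`, no
#' self-edges) and the edge list is deterministic under permutation of the
#' input rows.
#'
#' @param results Data.frame from [fisher_enrichment()] (needs the
#'   `overlap` list column).
#' @param threshold Cutoff applied to the `on` column; sets with value
#'   strictly below it are retained. Default 0.001.
#' @param on `"p"` (raw p-value, default) or `"q"` (BH-adjusted).
#' @return Data.frame with columns `gene_a`, `gene_b`, `shared`, sorted by
#'   `gene_a` then `gene_b`. Zero rows when no pair co-occurs.
#' @export
build_ggi <- function(results, threshold = 0.001, on = c("p", "q")) {
  on <- match.arg(on)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      shared = integer(), stringsAsFactors = FALSE)
  if (nrow(results) == 0L) return(empty)
  passing <- results[results[[on]] < threshold, , drop = FALSE]
  pairs <- list()
  for (ov in passing$overlap) {
    g <- sort(unique(ov))
    if (length(g) < 2L) next
    idx <- utils::combn(g, 2L)
    pairs[[length(pairs) + 1L]] <-
      data.frame(gene_a = idx[1L, ], gene_b = idx[2L, ],
                 stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L) return(empty)
  all_pairs <- do.call(rbind, pairs)
  agg <- stats::aggregate(list(shared = rep(1L, nrow(all_pairs))),
                          all_pairs[, c("gene_a", "gene_b")], sum)
  agg <- agg[order(agg$gene_a, agg$gene_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write an enrichment table as TSV
#'
#' The `overlap` list column is serialized as a semicolon-joined string.
#'
#' @param results Data.frame from [fisher_enrichment()].
#' @param path Output path.
#' @return `results`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  out <- results
  out$overlap <- vapply(results$overlap, paste, "", collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(results)
}

#' Write a gene-gene interaction network
#'
#' Emits the edge list as TSV and/or the graph as GraphML (undirected,
#' with a `shared` edge attribute).
#'
#' @param edges Data.frame from [build_ggi()].
#' @param path Edge-list TSV path, or `NULL` to skip.
#' @param graphml_path GraphML path, or `NULL` to skip.
#' @return `edges`, invisibly.
#' @export
write_ggi <- function(edges, path = NULL, graphml_path = NULL) {
  if (!is.null(path))
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edges)
}
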