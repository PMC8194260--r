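#' Drop relations without polarity
#'
#' Literature-curated relations whose direction of regulation is unknown
#' (polarity 0) carry no sign information and are removed before network
#' assembly. Order is preserved; the filter is idempotent.
#'
#' @param relations Data.frame with an integer `polarity` column in
#'   `{-1, 0, 1}` ([read_relations()]).
#' @return The signed rows, in input order.
#' @export
filter_polarity <- function(relations) {
  stopifnot("polarity" %in% names(relations))
  relations[relations$polarity != 0L, , drop = FALSE]
}

# Entity matching is case-insensitive after whitespace normalization.
.norm_entity <- function(x) tolower(gsub("\\s+", " ", trimws(as.character(x))))

# Collapse a (entity, sign[, type, n_refs]) table to one signed entry per
# entity. Conflicting signs are an error unless resolve = "majority",
# which takes the sign with the larger total reference count.
.signed_map <- function(entity, sign, entity_type = NULL, n_refs = NULL,
                        resolve = c("error", "majority")) {
  resolve <- match.arg(resolve)
  key <- .norm_entity(entity)
  if (is.null(n_refs)) n_refs <- rep(1L, length(entity))
  if (is.null(entity_type)) entity_type <- rep(NA_character_, length(entity))
  out <- list()
  for (k in unique(key)) {
    i <- which(key == k)
    signs <- unique(sign[i])
    if (length(signs) > 1L) {
      if (resolve == "error")
        stop("conflicting polarities for entity: ", entity[i[1L]])
      tot <- tapply(n_refs[i], sign[i], sum)
      if (length(unique(tot)) == 1L && length(tot) > 1L)
        stop("conflicting polarities with tied reference counts for entity: ",
             entity[i[1L]])
      s <- as.integer(names(tot)[which.max(tot)])
    } else s <- signs
    out[[k]] <- data.frame(entity = entity[i[1L]], key = k, sign = s,
                           entity_type = entity_type[i[1L]],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Signed targets of a source entity
#'
#' Extracts from a relation table the entities a given source (e.g. a
#' disease) regulates, with the regulation sign. Unsigned relations are
#' dropped first.
#'
#' @param relations Relation table ([read_relations()]).
#' @param source Source entity identifier (matched case-insensitively).
#' @param resolve Conflict handling for entities with contradictory signs:
#'   `"error"` (default) or `"majority"` by total reference count.
#' @return Data.frame with columns `entity`, `key` (normalized id),
#'   `sign`, `entity_type` (NA: a relation records its source's type, not
#'   its target's).
#' @export
signed_targets <- function(relations, source, resolve = c("error", "majority")) {
  rel <- filter_polarity(relations)
  rel <- rel[.norm_entity(rel$source) == .norm_entity(source), , drop = FALSE]
  if (nrow(rel) == 0L)
    return(data.frame(entity = character(), key = character(),
                      sign = integer(), entity_type = character(),
                      stringsAsFactors = FALSE))
  .signed_map(rel$target, rel$polarity, n_refs = rel$n_refs,
              resolve = resolve)
}

#' Signed regulators of a target entity
#'
#' Extracts the entities that regulate a given target (e.g. a disease),
#' with sign and entity type.
#'
#' @inheritParams signed_targets
#' @param target Target entity identifier.
#' @return As [signed_targets()], with `entity_type` taken from the
#'   relation's `source_type`.
#' @export
signed_regulators <- function(relations, target,
                              resolve = c("error", "majority")) {
  rel <- filter_polarity(relations)
  rel <- rel[.norm_entity(rel$target) == .norm_entity(target), , drop = FALSE]
  if (nrow(rel) == 0L)
    return(data.frame(entity = character(), key = character(),
                      sign = integer(), entity_type = character(),
                      stringsAsFactors = FALSE))
  .signed_map(rel$source, rel$polarity, entity_type = rel$source_type,
              n_refs = rel$n_refs, resolve = resolve)
}

#' Intersect disease-driven targets with disease regulators
#'
#' The entities that one disease (AD) regulates and that in turn regulate
#' a second disease (MDD) form the bridge of the signed two-disease
#' network. Each shared entity receives a direction by sign product: when
#' the effect of AD on the entity and the effect of the entity on MDD
#' have the same sign, the AD-driven change favors MDD; opposite signs
#' oppose it.
#'
#' @param ad_targets Signed map of the first disease's targets
#'   ([signed_targets()] output, or a data.frame with `entity` and `sign`).
#' @param mdd_regulators Signed map of the second disease's regulators
#'   ([signed_regulators()] output).
#' @return Verdict data.frame ordered by entity id: `entity`,
#'   `entity_type`, `ad_sign`, `mdd_sign`, `direction`
#'   (`"favors_MDD"`/`"opposes_MDD"`), `source` = `"literature"`.
#' @export
intersect_regulators <- function(ad_targets, mdd_regulators) {
  ad <- .ensure_map(ad_targets)
  md <- .ensure_map(mdd_regulators)
  common <- intersect(ad$key, md$key)
  ai <- match(common, ad$key)
  mi <- match(common, md$key)
  type <- ifelse(is.na(md$entity_type[mi]), ad$entity_type[ai],
                 md$entity_type[mi])
  out <- data.frame(entity = md$entity[mi],
                    entity_type = type,
                    ad_sign = ad$sign[ai],
                    mdd_sign = md$sign[mi],
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$ad_sign * out$mdd_sign == 1L,
                          "favors_MDD", "opposes_MDD")
  out$source <- rep("literature", nrow(out))
  out <- out[order(out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.ensure_map <- function(m) {
  stopifnot(is.data.frame(m), all(c("entity", "sign") %in% names(m)))
  if (!all(m$sign %in% c(-1L, 1L)))
    stop("signed maps must have sign in {-1, +1}")
  if (is.null(m$key)) m$key <- .norm_entity(m$entity)
  if (anyDuplicated(m$key)) {
    dup <- unique(m$entity[duplicated(m$key)])
    stop("duplicate entity in signed map: ", paste(dup, collapse = ", "))
  }
  if (is.null(m$entity_type)) m$entity_type <- NA_character_
  m
}

#' Direction of an expression change relative to a downstream disease
#'
#' A gene with a significant expression change in the upstream disease
#' favors the downstream disease when the sign of the change agrees with
#' the gene's regulatory sign on that disease: an up-regulated disease
#' promoter, or a down-regulated disease inhibitor, both favor it.
#'
#' @param lfc Numeric vector of combined log2 fold changes (nonzero).
#' @param mdd_sign Integer vector in `{-1, +1}`: each gene's regulatory
#'   sign on the downstream disease.
#' @return Character vector, `"favors_MDD"`/`"opposes_MDD"`; an exactly
#'   zero `lfc` has no direction and yields `NA` with a warning.
#' @export
classify_expression_direction <- function(lfc, mdd_sign) {
  stopifnot(length(lfc) == length(mdd_sign))
  if (!all(mdd_sign %in% c(-1L, 1L)))
    stop("`mdd_sign` must be -1 or +1")
  out <- ifelse(sign(lfc) * mdd_sign == 1, "favors_MDD", "opposes_MDD")
  if (any(lfc == 0)) {
    warning("zero log2 fold change has undefined direction; returning NA")
    out[lfc == 0] <- NA_character_
  }
  out
}

#' Expression-based verdicts for significant genes
#'
#' Joins a mega-analysis table with a signed regulator map: every
#' significant gene with a known regulatory sign on the downstream
#' disease is classified by [classify_expression_direction()] on its
#' combined effect.
#'
#' @param mega Data.frame from [mega_table()] (needs `gene`, `effect`,
#'   `significant`).
#' @param mdd_regulators Signed map ([signed_regulators()]).
#' @return Verdict data.frame (`entity`, `entity_type`, `ad_sign` = sign
#'   of the combined effect, `mdd_sign`, `direction`, `source` =
#'   `"expression"`), ordered by entity id.
#' @export
expression_verdicts <- function(mega, mdd_regulators) {
  md <- .ensure_map(mdd_regulators)
  sig <- mega[mega$significant & mega$effect != 0, , drop = FALSE]
  i <- match(.norm_entity(sig$gene), md$key)
  keep <- !is.na(i)
  sig <- sig[keep, , drop = FALSE]
  i <- i[keep]
  out <- data.frame(entity = sig$gene,
                    entity_type = ifelse(is.na(md$entity_type[i]), "gene",
                                         md$entity_type[i]),
                    ad_sign = as.integer(sign(sig$effect)),
                    mdd_sign = md$sign[i],
                    stringsAsFactors = FALSE)
  out$direction <- classify_expression_direction(sig$effect, md$sign[i])
  out$source <- "expression"
  out <- out[order(out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write verdicts as TSV
#' @param verdicts Data.frame from [intersect_regulators()] or
#'   [expression_verdicts()].
#' @param path Output path.
#' @return `verdicts`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(verdicts)
}

#' Write the signed two-disease network as GraphML
#'
#' Emits the bipartite-style directed graph AD -> entity -> MDD with
#' signed edges (`sign` attribute) and node attributes `entity_type` and
#' `direction`.
#'
#' @param verdicts Verdict data.frame.
#' @param path GraphML output path.
#' @param upstream,downstream Names for the two disease nodes.
#' @return `verdicts`, invisibly.
#' @export
write_relations_graphml <- function(verdicts, path, upstream = "AD",
                                    downstream = "MDD") {
  edges <- rbind(
    data.frame(from = upstream, to = verdicts$entity,
               sign = verdicts$ad_sign, stringsAsFactors = FALSE),
    data.frame(from = verdicts$entity, to = downstream,
               sign = verdicts$mdd_sign, stringsAsFactors = FALSE))
  nodes <- data.frame(
    name = c(upstream, verdicts$entity, downstream),
    entity_type = c("disease", verdicts$entity_type, "disease"),
    direction = c(NA_character_, verdicts$direction, NA_character_),
    stringsAsFactors = FALSE)
  # an entity may carry both a literature and an expression verdict
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(verdicts)
}
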