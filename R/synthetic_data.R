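#' Simulate multi-study case/control expression data
#'
#' Generates `n_studies` independent case/control studies under the
#' statistical model the mega-analysis assumes: gene `g` in study `i` has
#' a study-level true effect `theta_gi = true_lfc_g + delta_gi` with
#' `delta_gi ~ N(0, tau2)` (between-study heterogeneity), and samples are
#' drawn as `N(baseline + group * theta_gi, sigma^2)` on the log2 scale.
#' Ground truth (`theta`, `true_lfc`) is returned alongside the data so
#' every downstream estimate can be checked.
#'
#' Default sample sizes and study ages follow the nine-study case/control
#' design of the motivating application (controls 5,10,9,7,8,21,18,22,5;
#' cases 12,10,9,5,25,12,28,30,24; ages 15,15,12,10,10,7,3,3,1 years),
#' recycled for other study counts; countries cycle through a fixed list
#' of four. Defaults are scalars-or-vectors and recycled across studies.
#'
#' @param n_genes Number of genes.
#' @param n_studies Number of studies.
#' @param true_lfc Per-gene true log2 fold change (scalar or length
#'   `n_genes`).
#' @param tau2 Between-study variance of the per-study effects (>= 0).
#' @param sigma Per-sample noise SD on the log2 scale (> 0); default 1, a
#'   typical residual spread for log2 array intensities.
#' @param baseline Mean log2 expression of controls.
#' @param n_case,n_control Per-study group sizes (scalar or length
#'   `n_studies`); `NULL` uses the nine-study defaults above.
#' @param covariate_effects Optional named numeric vector with names in
#'   `c("n_sample", "study_age")`: each study's effects are shifted by
#'   `slope * covariate_i` (applied to all genes), planting a study-level
#'   covariate dependence for [covariate_regression()] to detect.
#' @param seed Optional integer seed.
#' @param gene_ids Optional gene identifiers (default `G0001`, ...).
#'
#' @return A list: `datasets` (list of [expression_dataset()]), `theta`
#'   (genes x studies matrix of realized study effects), `true_lfc`
#'   (named vector), `catalog` (data.frame of study metadata).
#' @export
simulate_studies <- function(n_genes = 203, n_studies = 9, true_lfc = 0,
                             tau2 = 0, sigma = 1, baseline = 8,
                             n_case = NULL, n_control = NULL,
                             covariate_effects = NULL, seed = NULL,
                             gene_ids = NULL) {
  stopifnot(n_genes >= 1, n_studies >= 1, tau2 >= 0, sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_control)) n_control <- c(5, 10, 9, 7, 8, 21, 18, 22, 5)
  if (is.null(n_case)) n_case <- c(12, 10, 9, 5, 25, 12, 28, 30, 24)
  n_control <- rep_len(n_control, n_studies)
  n_case <- rep_len(n_case, n_studies)
  if (any(n_control < 2) || any(n_case < 2))
    stop("each group needs at least 2 samples for variances to exist")
  study_age <- rep_len(c(15, 15, 12, 10, 10, 7, 3, 3, 1), n_studies)
  country <- rep_len(c("United States", "Sweden", "Germany", "China"),
                     n_studies)
  if (is.null(gene_ids))
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
  true_lfc <- stats::setNames(rep_len(true_lfc, n_genes), gene_ids)

  theta <- true_lfc +
    matrix(stats::rnorm(n_genes * n_studies, 0, sqrt(tau2)),
           n_genes, n_studies)
  dimnames(theta) <- list(gene_ids, sprintf("study%02d", seq_len(n_studies)))
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), c("n_sample", "study_age"))
    if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
    shift <- rep(0, n_studies)
    if ("n_sample" %in% names(covariate_effects))
      shift <- shift + covariate_effects[["n_sample"]] * (n_case + n_control)
    if ("study_age" %in% names(covariate_effects))
      shift <- shift + covariate_effects[["study_age"]] * study_age
    theta <- sweep(theta, 2L, shift, `+`)
  }

  datasets <- vector("list", n_studies)
  catalog <- NULL
  for (i in seq_len(n_studies)) {
    id <- sprintf("SIM%03d", i)
    nc <- n_case[i]; nk <- n_control[i]
    ctrl <- matrix(stats::rnorm(n_genes * nk, baseline, sigma), n_genes, nk)
    case <- baseline + theta[, i] +
      matrix(stats::rnorm(n_genes * nc, 0, sigma), n_genes, nc)
    m <- cbind(ctrl, case)
    dimnames(m) <- list(gene_ids,
                        c(sprintf("%s_ctl%02d", id, seq_len(nk)),
                          sprintf("%s_case%02d", id, seq_len(nc))))
    groups <- c(rep("control", nk), rep("case", nc))
    meta <- dataset_meta(id, n_control = nk, n_case = nc,
                         country = country[i], study_age = study_age[i])
    datasets[[i]] <- expression_dataset(id, m, groups, meta)
    catalog <- rbind(catalog, as.data.frame(meta))
  }
  list(datasets = datasets, theta = theta, true_lfc = true_lfc,
       catalog = catalog)
}

#' Simulate a signed relation table with planted overlap
#'
#' Builds a random two-disease relation table in which a known subset of
#' entities is regulated by the upstream disease AND regulates the
#' downstream disease (the planted overlap), with a controlled fraction
#' of the overlap favoring the downstream disease (sign product +1).
#' Remaining entities appear on one side only. Each relation's polarity
#' is independently erased (set to unknown) with probability
#' `p_polarity_missing`; the returned truth is the bookkeeping of what
#' survives the polarity filter, i.e. exactly what
#' [filter_polarity()] + [intersect_regulators()] should recover.
#'
#' Defaults plant an overlap of 18 entities of which 15 favor the
#' downstream disease, typed as 7 genes, 7 small molecules, 3 functional
#' classes and 1 cell (the proportions are kept for other overlap sizes).
#'
#' @param n_entities Total number of entities (>= `n_overlap`).
#' @param n_overlap Number of entities planted on both sides.
#' @param p_favor Fraction of the overlap with sign product +1; the
#'   planted favoring count is `round(p_favor * n_overlap)`.
#' @param p_polarity_missing Per-relation probability of an unknown
#'   polarity.
#' @param seed Optional integer seed.
#' @param entity_ids Optional entity identifiers (default `ENT001`, ...),
#'   e.g. gene ids shared with an expression simulation.
#' @param upstream,downstream The two disease node names.
#'
#' @return A list: `relations` (data.frame in [read_relations()] form),
#'   `truth` (list with `n_overlap`, `n_favor`, `n_oppose`, and the
#'   per-entity `entities` data.frame of planted signs surviving the
#'   polarity filter).
#' @export
simulate_relations <- function(n_entities = 50, n_overlap = 18,
                               p_favor = 15 / 18, p_polarity_missing = 0,
                               seed = NULL, entity_ids = NULL,
                               upstream = "AD", downstream = "MDD") {
  stopifnot(n_entities >= n_overlap, n_overlap >= 0,
            p_favor >= 0, p_favor <= 1,
            p_polarity_missing >= 0, p_polarity_missing <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(entity_ids))
    entity_ids <- sprintf("ENT%03d", seq_len(n_entities))
  entity_ids <- rep_len(entity_ids, n_entities)

  overlap <- sort(sample(entity_ids, n_overlap))
  rest <- setdiff(entity_ids, overlap)
  side <- sample(c(TRUE, FALSE), length(rest), replace = TRUE)
  ad_only <- rest[side]
  mdd_only <- rest[!side]

  types <- .overlap_types(n_overlap)
  n_favor <- round(p_favor * n_overlap)
  entity_favor <- stats::setNames(rep(FALSE, n_overlap), overlap)
  if (n_favor > 0) entity_favor[sample(overlap, n_favor)] <- TRUE

  mdd_sign <- sample(c(-1L, 1L), n_overlap, replace = TRUE)
  ad_sign <- ifelse(entity_favor, mdd_sign, -mdd_sign)

  rel <- rbind(
    data.frame(source = upstream, source_type = "disease", target = overlap,
               polarity = ad_sign, stringsAsFactors = FALSE),
    data.frame(source = overlap, source_type = types, target = downstream,
               polarity = mdd_sign, stringsAsFactors = FALSE),
    if (length(ad_only))
      data.frame(source = upstream, source_type = "disease", target = ad_only,
                 polarity = sample(c(-1L, 1L), length(ad_only), TRUE),
                 stringsAsFactors = FALSE),
    if (length(mdd_only))
      data.frame(source = mdd_only,
                 source_type = .overlap_types(length(mdd_only)),
                 target = downstream,
                 polarity = sample(c(-1L, 1L), length(mdd_only), TRUE),
                 stringsAsFactors = FALSE))
  rel$n_refs <- stats::rpois(nrow(rel), 5) + 1L
  erased <- stats::runif(nrow(rel)) < p_polarity_missing
  rel$polarity[erased] <- 0L

  # truth = planted structure surviving the polarity filter
  ad_ok <- rel$polarity != 0L & rel$source == upstream & rel$target %in% overlap
  mdd_ok <- rel$polarity != 0L & rel$target == downstream &
    rel$source %in% overlap
  both <- intersect(rel$target[ad_ok], rel$source[mdd_ok])
  surv <- overlap %in% both
  truth_entities <- data.frame(entity = overlap, entity_type = types,
                               ad_sign = ad_sign, mdd_sign = mdd_sign,
                               favors = entity_favor,
                               surviving = surv, stringsAsFactors = FALSE)
  list(relations = rel,
       truth = list(n_overlap = sum(surv),
                    n_favor = sum(entity_favor & surv),
                    n_oppose = sum(!entity_favor & surv),
                    entities = truth_entities))
}

# Entity types in the field's proportions 7:7:3:1 (largest-remainder split).
.overlap_types <- function(n) {
  if (n == 0L) return(character())
  prop <- c(gene = 7, `small molecule` = 7, `functional class` = 3, cell = 1) / 18
  counts <- floor(prop * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- prop * n - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  rep(names(counts), counts)
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Generates random gene sets over a synthetic gene universe; the first
#' `planted_sets` sets are enriched for the planted query (each query
#' gene is included with probability `planted_frac`), the rest are drawn
#' uniformly. The truth records which set ids were planted.
#'
#' @param n_sets Number of sets.
#' @param set_size_range Integer range of set sizes.
#' @param planted_query Character vector of query genes to plant.
#' @param planted_sets Number of sets to enrich (<= `n_sets`).
#' @param universe Gene universe; default `universe_size` synthetic ids
#'   plus the planted query.
#' @param universe_size Size of the default universe.
#' @param planted_frac Inclusion probability of each query gene in a
#'   planted set.
#' @param seed Optional integer seed.
#' @return A list: `collection` (as [read_gmt()] returns), `truth`
#'   (character vector of planted set ids), `universe`.
#' @export
simulate_genesets <- function(n_sets = 50, set_size_range = c(10, 100),
                              planted_query = character(), planted_sets = 0,
                              universe = NULL, universe_size = 2000,
                              planted_frac = 0.8, seed = NULL) {
  stopifnot(planted_sets <= n_sets, planted_sets >= 0,
            set_size_range[1] >= 1, set_size_range[2] >= set_size_range[1])
  if (!is.null(seed)) set.seed(seed)
  if (is.null(universe))
    universe <- unique(c(sprintf("U%05d", seq_len(universe_size)),
                         planted_query))
  sizes <- sample(set_size_range[1]:set_size_range[2], n_sets, replace = TRUE)
  ids <- sprintf("SET%03d", seq_len(n_sets))
  collection <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= planted_sets && length(planted_query)) {
      core <- planted_query[stats::runif(length(planted_query)) < planted_frac]
      fill <- sample(setdiff(universe, core),
                     max(0, sizes[i] - length(core)))
      members <- unique(c(core, fill))
    } else {
      members <- sample(universe, min(sizes[i], length(universe)))
    }
    collection[[i]] <- list(set_id = ids[i], name = sprintf("synthetic set %d", i),
                            members = members)
  }
  list(collection = stats::setNames(collection, ids),
       truth = ids[seq_len(planted_sets)],
       universe = universe)
}

#' Write a simulated multi-study dataset to disk
#'
#' Emits, under `dir`, one `<id>_matrix.tsv` + `<id>_labels.csv` pair per
#' study, a `catalog.csv`, and the ground truth (`truth_theta.tsv`,
#' `true_lfc.tsv`) — the exact formats the package readers consume.
#'
#' @param sim Result of [simulate_studies()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in sim$datasets)
    write_expression_matrix(ds,
                            file.path(dir, paste0(ds$dataset_id, "_matrix.tsv")),
                            file.path(dir, paste0(ds$dataset_id, "_labels.csv")))
  write_catalog(sim$catalog, file.path(dir, "catalog.csv"))
  th <- data.frame(gene = rownames(sim$theta), sim$theta,
                   check.names = FALSE)
  utils::write.table(th, file.path(dir, "truth_theta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(sim$true_lfc),
                                true_lfc = sim$true_lfc),
                     file.path(dir, "true_lfc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
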