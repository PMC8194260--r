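#' Regress per-study effect sizes on study-level covariates
#'
#' Asks whether a gene's per-study log2 fold changes track study-level
#' properties: total sample size, country of origin, and study age.
#' In `"univariate"` mode (the default) each covariate is tested in its
#' own simple regression of `lfc` on that covariate — the slope p-value
#' for the numeric covariates, the overall F-test p-value for the country
#' factor. `"joint"` mode fits all three covariates together and reports
#' marginal F-tests, but requires at least one residual degree of freedom
#' (with three predictors and a factor this needs many studies; univariate
#' mode is the estimable choice for small study counts, which is why it is
#' the default).
#'
#' A covariate that is constant across the contributing studies is not
#' estimable and is reported as `NA`.
#'
#' @param effects Data.frame of one gene's per-study effects
#'   ([effects_for_gene()]); column `dataset_id` links to the metadata.
#' @param metas Data.frame of study metadata with columns `dataset_id`,
#'   `n_case`, `n_control`, `country`, `study_age` (e.g. a catalog).
#' @param mode `"univariate"` (default) or `"joint"`.
#' @return One-row data.frame: `gene`, `p_nsample`, `p_country`,
#'   `p_study_age`, `mode`.
#' @export
covariate_regression <- function(effects, metas,
                                 mode = c("univariate", "joint")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(effects), is.data.frame(metas))
  d <- merge(effects, metas[, c("dataset_id", "n_case", "n_control",
                                "country", "study_age")],
             by = "dataset_id", sort = FALSE)
  if (nrow(d) < nrow(effects))
    stop("metadata missing for dataset(s): ",
         paste(setdiff(effects$dataset_id, metas$dataset_id), collapse = ", "))
  # merge suffixes with .y when the effects table also carries the counts
  d$n_sample <- if (!is.null(d$n_case.y)) d$n_case.y + d$n_control.y
                else d$n_case + d$n_control
  d$country <- factor(d$country)
  gene <- if ("gene" %in% names(effects)) effects$gene[[1L]] else NA_character_

  if (nrow(d) < 3L)
    stop("covariate regression requires at least 3 studies")

  if (mode == "univariate") {
    p_n <- .uni_p(d$lfc, d$n_sample)
    p_c <- .uni_p(d$lfc, d$country)
    p_a <- .uni_p(d$lfc, d$study_age)
  } else {
    keep <- c(n_sample = .varies(d$n_sample), country = .varies(d$country),
              study_age = .varies(d$study_age))
    terms <- names(keep)[keep]
    if (length(terms) == 0L) stop("no covariate varies across studies")
    fit <- stats::lm(stats::reformulate(terms, response = "lfc"), data = d)
    if (stats::df.residual(fit) < 1L)
      stop("joint mode has no residual degrees of freedom with ", nrow(d),
           " studies; use mode = 'univariate'")
    dr <- stats::drop1(fit, test = "F")
    pick <- function(t) if (t %in% rownames(dr)) dr[t, "Pr(>F)"] else NA_real_
    p_n <- pick("n_sample"); p_c <- pick("country"); p_a <- pick("study_age")
  }
  data.frame(gene = gene, p_nsample = p_n, p_country = p_c, p_study_age = p_a,
             mode = mode, stringsAsFactors = FALSE)
}

.varies <- function(x) length(unique(x[!is.na(x)])) > 1L

# Simple-regression p-value of lfc on one covariate; overall F for factors.
.uni_p <- function(lfc, x) {
  if (!.varies(x)) return(NA_real_)
  fit <- stats::lm(lfc ~ x)
  if (stats::df.residual(fit) < 1L) return(NA_real_)  # saturated fit
  if (is.factor(x)) {
    a <- stats::anova(fit)
    a[1L, "Pr(>F)"]
  } else {
    stats::coef(summary(fit))["x", "Pr(>|t|)"]
  }
}

#' Covariate regression for a gene panel
#'
#' Runs [covariate_regression()] per gene over the per-study effect table.
#'
#' @param effects Long per-study effect table ([effects_table()]).
#' @param metas Study metadata data.frame (see [covariate_regression()]).
#' @param mode Passed through.
#' @param min_studies Genes with fewer contributing studies are skipped.
#' @return Data.frame, one row per gene, ordered by gene id.
#' @export
covariate_table <- function(effects, metas, mode = c("univariate", "joint"),
                            min_studies = 3L) {
  mode <- match.arg(mode)
  rows <- lapply(split(effects, effects$gene), function(e) {
    if (nrow(e) < min_studies) return(NULL)
    covariate_regression(e, metas, mode = mode)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(gene = character(), p_nsample = numeric(),
                      p_country = numeric(), p_study_age = numeric(),
                      mode = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$gene), , drop = FALSE]
}
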