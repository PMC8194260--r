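#' Fixed-effect (inverse-variance) combination
#'
#' Combines per-study effect estimates with weights `w_i = 1/v_i`:
#' `effect = sum(w_i * theta_i) / sum(w_i)`, `se = 1/sqrt(sum(w_i))`, and a
#' two-sided normal p-value for `effect/se`.
#'
#' @param effect Numeric vector of per-study effect estimates, or a
#'   data.frame with columns `lfc` and `variance` (as produced by
#'   [effects_for_gene()]).
#' @param variance Numeric vector of per-study sampling variances
#'   (ignored when `effect` is a data.frame). All must be > 0.
#' @return A list with `effect`, `se`, `p`.
#' @export
fixed_effect_combine <- function(effect, variance = NULL) {
  th <- .theta_v(effect, variance)
  w <- 1 / th$v
  est <- sum(w * th$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(effect = est, se = se, p = .z_p(est / se))
}

# Accept (vector, vector) or an effects data.frame; validate variances.
.theta_v <- function(effect, variance) {
  if (is.data.frame(effect)) {
    theta <- effect$lfc
    variance <- effect$variance
  } else {
    theta <- effect
  }
  if (length(theta) < 1L) stop("at least one effect is required")
  if (length(variance) != length(theta))
    stop("`effect` and `variance` lengths differ")
  if (any(!is.finite(theta))) stop("effects must be finite")
  if (any(!is.finite(variance) | variance <= 0))
    stop("all variances must be positive and finite")
  list(theta = theta, v = variance)
}

.z_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i * (theta_i - mu_F)^2)` with fixed-effect weights, `df = k - 1`,
#' and the heterogeneity percentage `ISq = 100 * (Q - df) / Q`, set to 0
#' whenever the total variance Q does not exceed its expectation df under
#' homogeneity. This floor is exactly the model-selection rule of
#' [mega_analyze()]: `ISq == 0` if and only if the fixed-effect model is
#' selected.
#'
#' @inheritParams fixed_effect_combine
#' @param fixed_effect Optional precomputed fixed-effect estimate; computed
#'   from the inputs when `NULL`.
#' @return A list with `Q`, `df`, `ISq`.
#' @export
heterogeneity <- function(effect, variance = NULL, fixed_effect = NULL) {
  th <- .theta_v(effect, variance)
  if (length(th$theta) < 2L) stop("heterogeneity requires at least 2 effects")
  w <- 1 / th$v
  if (is.null(fixed_effect)) fixed_effect <- sum(w * th$theta) / sum(w)
  Q <- sum(w * (th$theta - fixed_effect)^2)
  df <- length(th$theta) - 1L
  ISq <- if (Q > df) 100 * (Q - df) / Q else 0
  list(Q = Q, df = df, ISq = ISq)
}

#' Heterogeneity p-value
#'
#' Upper-tail chi-square probability of observing total variance `Q` when
#' all variation is within-study (homogeneity): `P(chisq_df >= Q)`.
#'
#' @param Q Cochran's Q statistic (>= 0).
#' @param df Degrees of freedom, number of studies minus one (>= 1).
#' @return The upper-tail probability.
#' @export
q_p_value <- function(Q, df) {
  if (df < 1) stop("`df` must be >= 1")
  if (Q < 0) stop("`Q` must be >= 0")
  stats::pchisq(Q, df, lower.tail = FALSE)
}

#' Random-effects (DerSimonian-Laird) combination
#'
#' Estimates the between-study variance by the method of moments,
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`, then
#' combines with weights `1/(v_i + tau2)`. With `method = "REML"` the
#' restricted-maximum-likelihood fixed-point iteration replaces the
#' moment estimator. When `Q <= df`, `tau2 = 0` (under DL) and the result
#' coincides with [fixed_effect_combine()].
#'
#' @inheritParams fixed_effect_combine
#' @param method `"DL"` (default) or `"REML"`.
#' @return A list with `effect`, `se`, `p`, `tau2`.
#' @export
random_effects_combine <- function(effect, variance = NULL,
                                   method = c("DL", "REML")) {
  method <- match.arg(method)
  th <- .theta_v(effect, variance)
  if (length(th$theta) < 2L)
    stop("random-effects combination requires at least 2 effects")
  tau2 <- if (method == "DL") .tau2_dl(th$theta, th$v) else
    .tau2_reml(th$theta, th$v)
  w <- 1 / (th$v + tau2)
  est <- sum(w * th$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(effect = est, se = se, p = .z_p(est / se), tau2 = tau2)
}

.tau2_dl <- function(theta, v) {
  w <- 1 / v
  mu <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - mu)^2)
  df <- length(theta) - 1
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - df) / C)
}

# Standard REML fixed-point iteration for the between-study variance.
.tau2_reml <- function(theta, v, tol = 1e-10, max_iter = 200L) {
  tau2 <- .tau2_dl(theta, v)
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    mu <- sum(w * theta) / sum(w)
    new <- sum(w^2 * ((theta - mu)^2 - v)) / sum(w^2) + 1 / sum(w)
    new <- max(0, new)
    if (abs(new - tau2) < tol) return(new)
    tau2 <- new
  }
  tau2
}

#' Mega-analysis of one gene
#'
#' Combines one gene's per-study log2 fold changes. The fixed-effect
#' estimate and Cochran's Q are computed first; if the total variance Q is
#' at most its homogeneity expectation df, the fixed-effect model is
#' reported (ISq = 0, tau2 = 0), otherwise the random-effects model is.
#'
#' The 95% confidence interval uses the normal critical value under the
#' fixed model and the t(k-1) critical value under the random model — a
#' small-sample allowance for tau2 being estimated from few studies.
#' P-values are two-sided normal throughout; values that underflow to zero
#' are reported as 0 and flagged in `p_underflow`.
#'
#' @param effects Data.frame of per-study effects for one gene
#'   ([effects_for_gene()]), or a numeric vector of effects with
#'   `variance` supplied. At least two studies with positive variance.
#' @inheritParams fixed_effect_combine
#' @param method tau2 estimator for the random-effects branch:
#'   `"DL"` or `"REML"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row data.frame: `gene`, `n_study`, `effect`, `se`,
#'   `p_value`, `ci_lo`, `ci_hi`, `Q`, `df`, `ISq`, `Q_p`, `tau2`,
#'   `model` ("fixed"/"random"), `random_model` (0/1), `p_underflow`.
#' @export
mega_analyze <- function(effects, variance = NULL, method = c("DL", "REML"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  th <- .theta_v(effects, variance)
  if (length(th$theta) < 2L)
    stop("mega-analysis requires effects from at least 2 studies")
  gene <- if (is.data.frame(effects) && "gene" %in% names(effects))
    effects$gene[[1L]] else NA_character_
  k <- length(th$theta)

  fx <- fixed_effect_combine(th$theta, th$v)
  het <- heterogeneity(th$theta, th$v, fixed_effect = fx$effect)
  Qp <- q_p_value(het$Q, het$df)
  alpha <- 1 - conf_level

  if (het$Q <= het$df) {
    model <- "fixed"
    res <- c(fx, tau2 = 0)
    crit <- stats::qnorm(1 - alpha / 2)
  } else {
    model <- "random"
    res <- random_effects_combine(th$theta, th$v, method = method)
    crit <- stats::qt(1 - alpha / 2, k - 1)
  }

  data.frame(gene = gene, n_study = k, effect = res$effect, se = res$se,
             p_value = res$p,
             ci_lo = res$effect - crit * res$se,
             ci_hi = res$effect + crit * res$se,
             Q = het$Q, df = het$df, ISq = het$ISq, Q_p = Qp,
             tau2 = res$tau2, model = model,
             random_model = as.integer(model == "random"),
             p_underflow = res$p == 0,
             stringsAsFactors = FALSE)
}

#' Mega-analysis across a gene panel
#'
#' Runs [mega_analyze()] for every panel gene measurable in at least two
#' studies (per-study effects with non-positive variance are discarded
#' first: a study with no within-group spread carries no usable weight).
#' Genes are ordered by ascending p-value, ties broken by gene id, and
#' flagged significant at `alpha` after the chosen multiplicity
#' adjustment.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param genes Gene panel; defaults to all genes seen in any dataset.
#' @param alpha Significance threshold (default 0.05).
#' @param adjust Multiplicity adjustment applied before thresholding:
#'   `"none"` (default), `"BH"`, or `"bonferroni"`.
#' @inheritParams mega_analyze
#' @return Data.frame, one row per combinable gene, with the
#'   [mega_analyze()] columns plus `significant`.
#' @export
mega_table <- function(datasets, genes = NULL, alpha = 0.05,
                       adjust = c("none", "BH", "bonferroni"),
                       method = c("DL", "REML"), conf_level = 0.95) {
  adjust <- match.arg(adjust)
  method <- match.arg(method)
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(datasets,
                                       function(d) rownames(d$matrix)))))
  rows <- lapply(genes, function(g) {
    eff <- effects_for_gene(datasets, g)
    eff <- eff[eff$variance > 0, , drop = FALSE]
    if (nrow(eff) < 2L) return(NULL)
    mega_analyze(eff, method = method, conf_level = conf_level)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    out <- mega_analyze(data.frame(gene = "x", lfc = c(0, 0),
                                   variance = c(1, 1)))[0, ]
    out$significant <- logical()
    return(out)
  }
  out <- do.call(rbind, rows)
  padj <- switch(adjust,
                 none = out$p_value,
                 BH = stats::p.adjust(out$p_value, "BH"),
                 bonferroni = stats::p.adjust(out$p_value, "bonferroni"))
  out$significant <- padj < alpha
  out[order(out$p_value, out$gene), , drop = FALSE]
}

#' Write a mega-analysis table as TSV
#' @param mega Data.frame from [mega_table()].
#' @param path Output path.
#' @return `mega`, invisibly.
#' @export
write_mega_table <- function(mega, path) {
  utils::write.table(mega, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mega)
}
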