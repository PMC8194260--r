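---
title: "Cross-study mega-analysis of differential expression: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study mega-analysis of differential expression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megaDE)
```

## Scope and statistical model

megaDE combines per-study differential-expression effect sizes across
independent case/control studies. The unit of evidence for gene $g$ in
study $i$ is the log2 fold change
$\theta_{gi} = \bar{y}^{case}_{gi} - \bar{y}^{ctrl}_{gi}$ with sampling
variance $v_{gi} = s^2_{case}/n_{case} + s^2_{ctrl}/n_{ctrl}$ (unbiased
sample variances; the Welch form of the variance of a difference in
means). Combination assumes the per-study estimates are approximately
normal around study-level true effects
$\theta^*_{gi} = \mu_g + \delta_{gi}$, $\delta_{gi} \sim N(0, \tau^2_g)$
— the standard two-level random-effects structure. With $\tau^2_g = 0$
this collapses to a common-effect model.

The package computes per-study effects itself (from matrices, not from
published summaries), which is what distinguishes this "mega-analysis"
usage from a summary-statistics meta-analysis; the combination step is
nonetheless the classical two-stage inverse-variance machinery, because
per-study heterogeneity statistics (Q, ISq) are part of the required
output and only a two-stage formulation defines them.

### The heterogeneity switch

For each gene, Cochran's $Q = \sum_i w_i(\theta_i - \hat\mu_F)^2$
(fixed weights $w_i = 1/v_i$) is compared directly against its
homogeneity expectation $df = k - 1$:

* $Q \le df$: the heterogeneity percentage ISq
  $= 100\,(Q - df)/Q$ is floored at exactly 0, $\tau^2 = 0$, and the
  **fixed-effect** result is reported.
* $Q > df$: the **random-effects** (DerSimonian–Laird) result is
  reported, $\tau^2 = (Q - df)/C$, $C = \sum w_i - \sum w_i^2 / \sum w_i$,
  weights $1/(v_i + \tau^2)$.

The switch, the ISq floor, and the selected-model flag are linked by
construction: `ISq == 0` exactly when the fixed model is selected, and
`tau2 = 0` under the fixed model. `Q_p` is the upper-tail
$\chi^2_{df}$ probability of $Q$.

Note the percentage conventionally written $I^2$ measures
*between*-study excess variance; the package reports it under the name
`ISq` with exactly the formula above.

### P-values, confidence intervals, and small-sample behaviour

P-values for the combined effect are two-sided normal
($2\Phi(-|\hat\mu/se|)$), the standard asymptotics of inverse-variance
combination. Confidence intervals use the normal critical value under
the fixed model but the $t_{k-1}$ critical value under the random
model. The asymmetry is deliberate: when $\tau^2$ is estimated from a
handful of studies, the plain Wald interval of the DL estimator is
known to undercover (the extra uncertainty of $\hat\tau^2$ is ignored),
and replacing $z_{0.975}$ by $t_{k-1,0.975}$ is the light-weight
version of the Hartung–Knapp/Follmann–Proschan small-sample
corrections. We do not adopt the full Hartung–Knapp rescaling for the
p-value because, interacting with the $Q \le df$ switch, it makes the
null p-value distribution visibly non-uniform (conservative in the
random branch), and calibrated p-values across a null panel are a core
requirement for a screening statistic. The package's own validation
(see `tests/testthat/test-acceptance.R`) checks both properties at the
design conditions: uniform null p-values with nominal type-I error,
and 95% CI coverage within [0.92, 0.97] under planted heterogeneity.

P-values below the smallest representable double underflow to 0; they
are reported as 0 with the `p_underflow` flag set rather than clamped,
since downstream ranking only needs the order.

$\tau^2$ can alternatively be estimated by REML
(`method = "REML"`, a fixed-point iteration initialized at the DL
value, tolerance $10^{-10}$); DL remains the default as the canonical
moment estimator for this design.

### Degenerate inputs and tie-breaks

* A gene absent from a study, or with fewer than two non-missing
  samples in either group, is simply not measurable there; the study
  is skipped, and genes measurable in fewer than two studies are
  excluded from combination ($Q$ needs $df \ge 1$).
* A study with zero within-group spread yields variance 0 — an
  infinite weight. Such rows are excluded by `mega_table()` before
  combination; `fixed_effect_combine()` itself refuses non-positive
  variances loudly.
* Output rows are ordered by ascending p-value with ties broken by
  gene id; probe-collapse ties on mean expression are broken
  lexicographically by probe id. Both make reruns byte-identical.
* Matrices whose maximum exceeds 30 are assumed linear-scale and
  transformed by $\log_2(x+1)$; log2 microarray data rarely exceeds
  ~20, so the heuristic is far from both regimes.

## Covariate regression

Per-study effect sizes can be regressed on study-level covariates:
total sample size, country of origin (factor), study age in years.
The default is **univariate** mode — one simple regression per
covariate, slope p-value (overall F for the factor). With the small
study counts typical here (often 4–9 studies contribute to a gene), a
joint 3-predictor fit has little or no residual degrees of freedom;
joint mode is available but refuses to fit when the residual df is
zero, directing the user back to univariate mode. Constant covariates
and saturated factor fits are reported as `NA` (not estimable) rather
than as fabricated p-values.

## Enrichment and networks

Over-representation uses the one-sided Fisher exact test
($P(X \ge k)$ hypergeometric upper tail), BH-adjusted across the
collection. The background universe defaults to the union of all
collection members and the query — the least presumptive choice when
no platform universe is given — and can be supplied explicitly. The
gene–gene network connects genes sharing at least one enriched set
(default cutoff: raw $p < 0.001$, applied to `p`; applying it to `q`
instead is a parameter, since reasonable pipelines differ on this).

Relation tables are reduced to a signed two-disease network in three
steps: drop unsigned relations; intersect the upstream disease's
signed targets with the downstream disease's signed regulators
(case-insensitive, whitespace-normalized entity matching, since
curated tables mix naming conventions); classify each shared entity by
sign product — same sign favors the downstream disease, opposite signs
oppose it. Conflicting signs for one entity are an error by default;
`resolve = "majority"` arbitrates by total reference count and still
errors on exact ties. The same sign-product rule classifies
significant expression changes against the regulator map.

## What the synthetic generator does and does not emulate

`simulate_studies()` draws data exactly from the model above: normal
log2 noise (SD `sigma`, default 1.0 — a typical residual spread for
log2 array intensities), between-study effects with variance `tau2`,
optional study-level covariate slopes, and study metadata (default
sample sizes follow the motivating nine-study design; countries cycle
through a fixed list of four). `simulate_relations()` and
`simulate_genesets()` plant known overlap/direction counts and
enriched sets, with exact bookkeeping of the planted truth (defaults:
overlap 18, 15 favoring, entity types in 7:7:3:1 proportions).

Because the generator *is* the model, passing calibration tests shows
the estimator chain is correct and well-calibrated **under the model's
assumptions** — it does not show robustness to what real microarray
data adds: probe-level artifacts, batch and platform effects,
non-normal and heteroskedastic noise, correlated genes, mixed tissue
sources, or imbalanced lesional/nonlesional sampling. Probe collapse
is provided (`max_mean`/`average`), but upstream normalization (RMA
and relatives) is assumed done.

## Validation problem sizes

The packaged checks use: 120 random small instances ($k \le 5$) for
exact formula equivalence against independently re-derived oracles
(tolerance $10^{-12}$ relative, with `metafor` as an additional
cross-check); 1000-gene panels at 9 studies of 10+10 samples for null
calibration (KS uniformity, type-I error) and for planted-effect
recovery (LFC 1.0, $\tau^2 = 0.2$: bias and CI coverage); 300-gene
panels per $\tau^2 \in \{0, 0.1, 0.5\}$ for the model-selection curve;
exhaustive enumeration up to $N = 12$ for the hypergeometric oracle;
and planted networks/collections recovered exactly. These sizes give
Monte-Carlo error well inside the tested bands while keeping the whole
suite under a minute.

## Known limitations

* One-stage pooled mixed-model fitting (all samples in one model) is
  out of scope; the engine is two-stage by design.
* No moderated/shrunken variance estimators (limma-style); with very
  few samples per group the per-study variances are noisy, which the
  $t_{k-1}$ interval only partly absorbs.
* No GO-DAG-aware enrichment (term ancestry is ignored; sets are
  independent lists).
* The catalog filter implements fixed inclusion criteria
  (human, microarray, disease-vs-healthy, downloadable); it does not
  query any repository.
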