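# megaDE

Cross-study **mega-analysis of differential gene expression**: combine
per-study case/control log2 fold changes across independent expression
datasets under fixed-effect and random-effects models, with a
heterogeneity-driven switch between the two, and carry the results
through study-level covariate regression, gene-set over-representation
analysis, and signed regulator-network assembly.

The package is aimed at analyses that ask how one disease (for example
atopic dermatitis) perturbs the upstream regulators of a second disease
(for example major depressive disorder): expression changes are
estimated per study from the original matrices, combined across
studies, and then classified by whether they act with or against the
regulators' known effect on the downstream disease.

## The model

For gene *g* in study *i*, the effect size is the log2 fold change
(case minus control mean on the log2 scale), with sampling variance

    theta_i = mean(log2 case) - mean(log2 control)
    v_i     = s2_case/n_case + s2_control/n_control

The fixed-effect combination uses inverse-variance weights
`w_i = 1/v_i`:

    mu_F = sum(w_i * theta_i) / sum(w_i),   se_F = sum(w_i)^(-1/2)

Heterogeneity is measured by Cochran's statistic and its percentage
form:

    Q   = sum(w_i * (theta_i - mu_F)^2),    df = k - 1
    ISq = 100 * (Q - df) / Q,   floored at 0 when Q <= df

**Model switch:** when the total variance `Q` is at most its
homogeneity expectation `df`, the fixed-effect model is reported;
otherwise the DerSimonian–Laird random-effects model is used, with

    tau2 = max(0, (Q - df) / C),  C = sum(w) - sum(w^2)/sum(w)

and weights `1/(v_i + tau2)`. `Q_p`, the upper-tail chi-square
probability of `Q`, quantifies the evidence that the observed variance
exceeds the within-study component.

Enrichment of a gene list against a collection of gene sets uses the
one-sided Fisher exact (hypergeometric) test with Benjamini–Hochberg
FDR control, and two genes are linked in the gene–gene interaction
(GGI) network when they share at least one enriched set — the edge
weight counts the shared sets. Literature-style relation tables are
reduced to a signed two-disease network: unsigned relations are
discarded, entities regulated by the upstream disease and regulating
the downstream one are intersected, and each is classified
`favors`/`opposes` by the product of its two signs.

## Worked example

Simulate nine studies of 10 cases + 10 controls, a 203-gene panel with
five genes truly perturbed (LFC = 1) and between-study heterogeneity
`tau2 = 0.2`, then combine:

```r
library(megaDE)
sim <- simulate_studies(n_genes = 203, n_studies = 9,
                        n_case = 10, n_control = 10,
                        true_lfc = c(rep(1, 5), rep(0, 198)),
                        tau2 = 0.2, sigma = 1, seed = 42)
tab <- mega_table(sim$datasets, alpha = 0.05, adjust = "bonferroni")
head(tab, 3)
```

```
   gene n_study effect    se  p_value     Q df  ISq      Q_p   tau2  model significant
  G0004       9  0.825 0.182 5.83e-06 11.24  8 28.8 0.188704 0.0843 random        TRUE
  G0005       9  0.804 0.205 9.05e-05 16.92  8 52.7 0.030968 0.1958 random        TRUE
  G0111       9 -0.570 0.149 1.35e-04  7.20  8  0.0 0.515383 0.0000  fixed        TRUE
```

Reading a row: `G0004` is measured in all 9 studies; its combined LFC
is 0.83 (true value 1). `Q = 11.2` exceeds `df = 8`, so 28.8% of the
total variance is attributed to between-study spread (`ISq`), the
random-effects model is selected and `tau2 = 0.084` estimated. Of the
three genes passing the Bonferroni threshold, two are truly perturbed
and one (`G0111`) is a null gene that slipped through — a reminder
that family-wise control bounds, but does not eliminate, false
positives. Study-level covariates are then probed per gene:

```r
covariate_regression(effects_for_gene(sim$datasets, "G0001"), sim$catalog)
```

```
   gene p_nsample p_country p_study_age       mode
  G0001        NA     0.519       0.215 univariate
```

`p_nsample` is `NA` because every simulated study here has the same
sample size — a constant covariate is not estimable, and the package
says so rather than inventing a p-value.

The full workflow (catalog filter → effects → mega table → covariate
regression → direction classification → enrichment → GGI network) runs
from one configuration via `run_pipeline()`, or from the shell through
the thin CLI in `inst/cli/mega.R` (subcommands `simulate`, `effects`,
`mega`, `mlr`, `classify`, `pea`, `ggi`, `run`).

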