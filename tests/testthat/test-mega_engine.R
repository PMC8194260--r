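test_that("fixed-effect combination matches hand-derived values", {
  one <- fixed_effect_combine(1.2, 0.04)
  expect_equal(one$effect, 1.2)
  expect_equal(one$se, 0.2)

  sym <- fixed_effect_combine(c(1, 2), c(0.3, 0.3))
  expect_equal(sym$effect, 1.5)

  # w = (10, 5): effect = (5 + 5)/15, se = 15^(-1/2)
  der <- fixed_effect_combine(c(0.5, 1.0), c(0.1, 0.2))
  expect_equal(der$effect, 2 / 3, tolerance = 1e-12)
  expect_equal(der$se, 15^-0.5, tolerance = 1e-12)

  expect_error(fixed_effect_combine(c(1, 2), c(0.1, 0)), "positive")
})

test_that("heterogeneity implements the printed ISq formula with its floor", {
  # identical effects: no excess variance at all
  het0 <- heterogeneity(c(1, 1, 1), c(0.2, 0.5, 1))
  expect_equal(het0$Q, 0)
  expect_equal(het0$ISq, 0)

  set.seed(7)
  seen_floor <- seen_pos <- FALSE
  for (i in 1:200) {
    inst <- random_instance()
    het <- heterogeneity(inst$theta, inst$v)
    ref <- oracle_het(inst$theta, inst$v)
    expect_equal(het$Q, ref$Q, tolerance = 1e-12)
    expect_equal(het$df, length(inst$theta) - 1)
    if (het$Q <= het$df) {
      expect_identical(het$ISq, 0)       # Q <= df: floored exactly at 0
      seen_floor <- TRUE
    } else {
      expect_equal(het$ISq, 100 * (het$Q - het$df) / het$Q, tolerance = 1e-12)
      seen_pos <- TRUE
    }
  }
  expect_true(seen_floor && seen_pos)
  expect_error(heterogeneity(1, 0.1), "at least 2")
})

test_that("heterogeneity p-value is the chi-square upper tail", {
  expect_equal(q_p_value(0, 3), 1)
  expect_equal(q_p_value(1, 1), 0.3173105, tolerance = 1e-6)
  expect_equal(q_p_value(9.488, 4), 0.05, tolerance = 1e-3)
  expect_error(q_p_value(1, 0), "df")
})

test_that("DerSimonian-Laird combination matches the hand-worked example", {
  # theta = (0, 2), v = (0.5, 0.5): Q = 4, df = 1, C = 2, tau2 = 1.5
  re <- random_effects_combine(c(0, 2), c(0.5, 0.5))
  expect_equal(re$tau2, 1.5, tolerance = 1e-12)
  expect_equal(re$effect, 1, tolerance = 1e-12)
  expect_equal(re$se, 1, tolerance = 1e-12)

  # equal variances: plain mean regardless of tau2
  re2 <- random_effects_combine(c(0.2, 0.9, 1.3), rep(0.4, 3))
  expect_equal(re2$effect, mean(c(0.2, 0.9, 1.3)), tolerance = 1e-12)

  # homogeneous effects (Q <= df): tau2 = 0, identical to fixed
  th <- c(1.0, 1.01, 0.99); v <- c(0.5, 0.5, 0.5)
  re3 <- random_effects_combine(th, v)
  fx <- fixed_effect_combine(th, v)
  expect_identical(re3$tau2, 0)
  expect_identical(re3$effect, fx$effect)
  expect_identical(re3$se, fx$se)
})

test_that("fixed and DL estimates agree with metafor on random instances", {
  set.seed(13)
  for (i in 1:25) {
    inst <- random_instance()
    fe <- metafor::rma(yi = inst$theta, vi = inst$v, method = "FE")
    fx <- fixed_effect_combine(inst$theta, inst$v)
    expect_equal(fx$effect, as.numeric(fe$beta), tolerance = 1e-10)
    expect_equal(fx$se, fe$se, tolerance = 1e-10)

    dl <- metafor::rma(yi = inst$theta, vi = inst$v, method = "DL")
    re <- random_effects_combine(inst$theta, inst$v)
    expect_equal(re$tau2, dl$tau2, tolerance = 1e-8)
    expect_equal(re$effect, as.numeric(dl$beta), tolerance = 1e-8)
  }
})

test_that("REML tau2 agrees with metafor's REML", {
  set.seed(29)
  for (i in 1:10) {
    k <- sample(4:8, 1)
    theta <- rnorm(k, 1, 1.5); v <- runif(k, 0.1, 1)
    rm <- metafor::rma(yi = theta, vi = v, method = "REML",
                       control = list(tol = 1e-10))
    re <- random_effects_combine(theta, v, method = "REML")
    expect_equal(re$tau2, rm$tau2, tolerance = 1e-5)
    expect_equal(re$effect, as.numeric(rm$beta), tolerance = 1e-6)
  }
})

test_that("model selection follows the Q vs df rule exactly", {
  set.seed(17)
  for (i in 1:100) {
    inst <- random_instance()
    eff <- data.frame(gene = "g", lfc = inst$theta, variance = inst$v)
    res <- mega_analyze(eff)
    het <- oracle_het(inst$theta, inst$v)
    expect_identical(res$model == "fixed", het$Q <= het$df)
    expect_identical(res$ISq == 0, res$model == "fixed")
    if (res$model == "fixed") {
      expect_identical(res$tau2, 0)
      ref <- oracle_fixed(inst$theta, inst$v)
    } else {
      ref <- oracle_dl(inst$theta, inst$v)
    }
    expect_equal(res$effect, ref$effect, tolerance = 1e-12)
    expect_equal(res$se, ref$se, tolerance = 1e-12)
    expect_equal(res$p_value, ref$p, tolerance = 1e-12)
    expect_equal(res$Q_p, pchisq(het$Q, het$df, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(res$n_study, length(inst$theta))
    expect_equal(res$df, res$n_study - 1)
  }
})

test_that("homogeneous panels go fixed, strongly heterogeneous go random", {
  sim_h <- simulate_studies(n_genes = 60, n_case = 10, n_control = 10,
                            true_lfc = 0.5, tau2 = 0, sigma = 1, seed = 91)
  tab_h <- mega_table(sim_h$datasets)
  # under homogeneity Q ~ chisq(8): P(Q <= 8) ~ 0.57
  expect_gt(mean(tab_h$model == "fixed"), 0.35)

  sim_r <- simulate_studies(n_genes = 60, n_case = 10, n_control = 10,
                            true_lfc = 0.5, tau2 = 2, sigma = 1, seed = 92)
  tab_r <- mega_table(sim_r$datasets)
  expect_gt(mean(tab_r$model == "random"), 0.9)
})

test_that("mega_table drops single-study genes and orders deterministically", {
  d1 <- tiny_dataset("A"); d2 <- tiny_dataset("B")
  m <- rbind(solo = c(5, 6, 4, 4))
  colnames(m) <- paste0("x", 1:4)
  d3 <- expression_dataset("C", m, c("case", "case", "control", "control"))

  tab <- mega_table(list(d1, d2, d3))
  expect_false("solo" %in% tab$gene)      # measurable in one study only
  expect_false("g2" %in% tab$gene)        # zero variance everywhere
  expect_true(all(diff(tab$p_value) >= 0))

  # identical duplicated inputs give identical rows, tie broken by gene id
  m2 <- rbind(aa = c(5, 7, 4, 4.5), bb = c(5, 7, 4, 4.5))
  colnames(m2) <- paste0("s", 1:4)
  dd <- lapply(c("D1", "D2"), function(id)
    expression_dataset(id, m2, c("case", "case", "control", "control")))
  tab2 <- mega_table(dd)
  expect_equal(tab2$gene, c("aa", "bb"))
  expect_equal(tab2$effect[1], tab2$effect[2])
  expect_equal(tab2$p_value[1], tab2$p_value[2])
})

test_that("adding a study at the combined effect never inflates the se", {
  set.seed(23)
  for (i in 1:200) {
    inst <- random_instance(sample(3:6, 1))
    before <- mega_analyze(data.frame(gene = "g", lfc = inst$theta,
                                      variance = inst$v))
    after <- mega_analyze(data.frame(
      gene = "g", lfc = c(inst$theta, before$effect),
      variance = c(inst$v, runif(1, 0.05, 2))))
    expect_lte(after$se, before$se + 1e-12)
  }
})
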