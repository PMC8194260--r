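mk_rel <- function(source, type, target, pol, refs = 1L) {
  data.frame(source = source, source_type = type, target = target,
             polarity = as.integer(pol), n_refs = as.integer(refs),
             stringsAsFactors = FALSE)
}

test_that("polarity filter drops unsigned relations, preserving order", {
  rel <- mk_rel(c("a", "b", "c"), "gene", "MDD", c(1, 0, -1))
  kept <- filter_polarity(rel)
  expect_equal(kept$source, c("a", "c"))
  expect_identical(filter_polarity(kept), kept)

  none <- filter_polarity(mk_rel(c("a", "b"), "gene", "MDD", c(0, 0)))
  expect_equal(nrow(none), 0L)

  set.seed(71)
  pol <- c(rep(0L, 4), sample(c(-1L, 1L), 6, TRUE))[sample(10)]
  mixed <- mk_rel(sprintf("e%02d", 1:10), "gene", "MDD", pol)
  expect_equal(nrow(filter_polarity(mixed)), 6L)
})

test_that("regulator intersection classifies by sign product", {
  ad <- data.frame(entity = c("a", "b", "c"), sign = c(1L, 1L, -1L))
  mdd <- data.frame(entity = c("b", "c", "d"), sign = c(1L, -1L, 1L))
  v <- intersect_regulators(ad, mdd)
  expect_equal(v$entity, c("b", "c"))
  expect_equal(v$direction, c("favors_MDD", "favors_MDD"))

  # mismatched signs oppose
  v2 <- intersect_regulators(data.frame(entity = "x", sign = 1L),
                             data.frame(entity = "x", sign = -1L))
  expect_equal(v2$direction, "opposes_MDD")

  # result is never larger than either map
  expect_lte(nrow(v), min(nrow(ad), nrow(mdd)))
})

test_that("negating both signs leaves every direction unchanged", {
  set.seed(73)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    ids <- sprintf("e%02d", seq_len(n))
    ad <- data.frame(entity = ids, sign = sample(c(-1L, 1L), n, TRUE))
    mdd <- data.frame(entity = sample(ids), sign = sample(c(-1L, 1L), n, TRUE))
    a <- intersect_regulators(ad, mdd)
    ad2 <- ad; mdd2 <- mdd
    ad2$sign <- -ad2$sign; mdd2$sign <- -mdd2$sign
    b <- intersect_regulators(ad2, mdd2)
    expect_equal(b$direction, a$direction)
  }
})

test_that("entities match case-insensitively after whitespace normalization", {
  rel <- rbind(mk_rel("AD", "disease", "Vitamin  D3", -1),
               mk_rel("vitamin d3", "small molecule", "MDD", -1))
  v <- intersect_regulators(signed_targets(rel, "ad"),
                            signed_regulators(rel, "mdd"))
  expect_equal(nrow(v), 1L)
  expect_equal(v$direction, "favors_MDD")
  expect_equal(v$entity_type, "small molecule")
})

test_that("conflicting polarities error by default, majority resolves", {
  rel <- rbind(mk_rel("AD", "disease", "tnf", 1, refs = 10),
               mk_rel("AD", "disease", "TNF", -1, refs = 2))
  expect_error(signed_targets(rel, "AD"), "tnf")
  maj <- signed_targets(rel, "AD", resolve = "majority")
  expect_equal(maj$sign, 1L)

  tie <- rbind(mk_rel("AD", "disease", "tnf", 1, refs = 5),
               mk_rel("AD", "disease", "TNF", -1, refs = 5))
  expect_error(signed_targets(tie, "AD", resolve = "majority"), "tied")
})

test_that("expression direction follows sign(lfc) x regulator sign", {
  # down-regulated inhibitor favors the downstream disease
  expect_equal(classify_expression_direction(-1.07, -1L), "favors_MDD")
  # up-regulated gene with mismatched regulator sign opposes
  expect_equal(classify_expression_direction(2.765, -1L), "opposes_MDD")
  expect_equal(classify_expression_direction(1, 1L), "favors_MDD")
  expect_warning(out <- classify_expression_direction(c(0, 1), c(1L, 1L)),
                 "undefined")
  expect_identical(out, c(NA, "favors_MDD"))
  expect_error(classify_expression_direction(1, 2L), "sign")
})

test_that("a planted relation table is recovered entity-for-entity", {
  sim <- simulate_relations(n_entities = 50, n_overlap = 18,
                            p_favor = 15 / 18, p_polarity_missing = 0,
                            seed = 79)
  expect_equal(sim$truth$n_overlap, 18L)
  expect_equal(sim$truth$n_favor, 15L)
  # paper-like type proportions at overlap 18: 7 genes, 7 small molecules,
  # 3 functional classes, 1 cell
  tt <- table(sim$truth$entities$entity_type)
  expect_equal(as.vector(tt[c("gene", "small molecule", "functional class",
                              "cell")]), c(7, 7, 3, 1))

  v <- intersect_regulators(signed_targets(sim$relations, "AD"),
                            signed_regulators(sim$relations, "MDD"))
  expect_equal(nrow(v), 18L)
  expect_equal(sum(v$direction == "favors_MDD"), 15L)
  expect_equal(v$entity, sort(sim$truth$entities$entity))
})

test_that("fully unsigned tables leave an empty network", {
  sim <- simulate_relations(n_entities = 20, n_overlap = 5,
                            p_polarity_missing = 1, seed = 83)
  expect_equal(nrow(filter_polarity(sim$relations)), 0L)
  expect_equal(sim$truth$n_overlap, 0L)
  v <- intersect_regulators(signed_targets(sim$relations, "AD"),
                            signed_regulators(sim$relations, "MDD"))
  expect_equal(nrow(v), 0L)
})
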