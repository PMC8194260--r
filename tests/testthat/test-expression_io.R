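test_that("matrix + labels round-trip through disk is value-identical", {
  ds <- tiny_dataset()
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".csv")
  write_expression_matrix(ds, mp, lp)
  back <- read_expression_matrix(mp, lp, dataset_id = "DS1")
  expect_equal(back$matrix, ds$matrix, tolerance = 0)
  expect_identical(back$sample_groups, ds$sample_groups)
  expect_identical(genes(back), genes(ds))
})

test_that("linear-scale matrices are detected and log2(x+1)-transformed", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "gA\t40000\t20000\t100\t200",
               "gB\t5\t6\t7\t8"), mp)
  writeLines(c("sample_id,group", "s1,case", "s2,case",
               "s3,control", "s4,control"), lp)
  ds <- read_expression_matrix(mp, lp)
  expect_equal(ds$matrix["gA", "s1"], log2(40001))
  expect_equal(max(ds$matrix), log2(40001), tolerance = 1e-12)

  # already on log2 scale (max 15.3): untouched
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "gA\t15.3\t12\t10\t9",
               "gB\t5\t6\t7\t8"), mp)
  ds2 <- read_expression_matrix(mp, lp)
  expect_equal(ds2$matrix["gA", "s1"], 15.3)
})

test_that("reader errors name the offending sample or cell", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene\ts1\ts2\ts3\ts4", "gA\t1\t2\t3\t4"), mp)
  writeLines(c("sample_id,group", "s1,case", "s2,case", "s3,control"), lp)
  expect_error(read_expression_matrix(mp, lp), "s4")

  writeLines(c("sample_id,group", "s1,case", "s2,case",
               "s3,control", "s4,control"), lp)
  writeLines(c("gene\ts1\ts2\ts3\ts4", "gA\t1\toops\t3\t4"), mp)
  expect_error(read_expression_matrix(mp, lp), "oops.*gA.*s2")
})

test_that("probe collapse honours method and lexicographic tie-break", {
  m <- rbind(p1 = c(4, 6), p2 = c(6, 8), p3 = c(2, 4), p9 = c(1, 1))
  colnames(m) <- c("s1", "s2")
  ds <- expression_dataset("D", m, c("case", "control"))
  map <- data.frame(probe = c("p1", "p2", "p3"), gene = c("G", "G", "H"))

  # max_mean keeps the higher-mean probe (p2, mean 7 vs p1, mean 5)
  mm <- collapse_probes(ds, map, "max_mean")
  expect_equal(mm$matrix["G", ], c(s1 = 6, s2 = 8))
  # unmapped probe p9 dropped
  expect_setequal(genes(mm), c("G", "H"))

  # average takes the per-sample mean: (4,6) & (6,8) -> (5,7)
  av <- collapse_probes(ds, map, "average")
  expect_equal(av$matrix["G", ], c(s1 = 5, s2 = 7))

  # equal means: lexicographically first probe wins
  m2 <- rbind(pB = c(1, 3), pA = c(3, 1))
  colnames(m2) <- c("s1", "s2")
  ds2 <- expression_dataset("D", m2, c("case", "control"))
  tie <- collapse_probes(ds2, data.frame(probe = c("pA", "pB"),
                                         gene = c("G", "G")), "max_mean")
  expect_equal(tie$matrix["G", ], c(s1 = 3, s2 = 1))

  expect_error(collapse_probes(ds, data.frame(probe = "zz", gene = "G")),
               "no probe")
})

test_that("average collapse preserves the mean of member-probe column sums", {
  set.seed(5)
  m <- matrix(rnorm(30, 8), 6, 5,
              dimnames = list(paste0("p", 1:6), paste0("s", 1:5)))
  ds <- expression_dataset("D", m, c("case", "case", "case",
                                     "control", "control"))
  map <- data.frame(probe = paste0("p", 1:6),
                    gene = rep(c("G1", "G2"), each = 3))
  av <- collapse_probes(ds, map, "average")
  expect_equal(unname(av$matrix["G1", ]),
               unname(colMeans(m[1:3, ])), tolerance = 1e-12)
  expect_equal(nrow(av$matrix), 2L)
})

test_that("catalog filter applies all four inclusion criteria, idempotently", {
  base <- do.call(rbind, lapply(1:9, function(i)
    dataset_meta(paste0("GSE", i), 5, 5, country = "United States",
                 study_age = i)))
  expect_equal(nrow(filter_dataset_catalog(base)), 9L)

  mouse <- dataset_meta("GSEm", 3, 3, organism = "Mus musculus")
  nodl <- dataset_meta("GSEd", 3, 3, downloadable = FALSE)
  rnaseq <- dataset_meta("GSEr", 3, 3, data_type = "RNA-seq")
  other <- dataset_meta("GSEo", 3, 3, comparison = "psoriasis vs controls")
  cat <- rbind(base, mouse, nodl, rnaseq, other)
  kept <- filter_dataset_catalog(cat)
  expect_equal(kept$dataset_id, base$dataset_id)
  expect_identical(filter_dataset_catalog(kept), kept)
})

test_that("GMT reading deduplicates members and reports bad lines", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tA\tB\tA", p)
  gs <- read_gmt(p)
  expect_length(gs, 1L)
  expect_setequal(gs[["S1"]]$members, c("A", "B"))

  writeLines(character(), p)
  expect_length(read_gmt(p), 0L)

  lines <- vapply(1:38, function(i)
    paste(c(sprintf("S%02d", i), "d", paste0("g", 1:4)), collapse = "\t"), "")
  writeLines(lines, p)
  expect_length(read_gmt(p), 38L)

  writeLines(c("S1\tdesc\tA", "S2\tonly-two-fields"), p)
  expect_error(read_gmt(p), "line 2")
})

test_that("relation tables map polarity tokens and round-trip", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,source_type,target,polarity,n_refs",
               "TNF,gene,MDD,positive,12",
               "vitamin D3,small molecule,MDD,negative,5",
               "AD,disease,IL6,unknown,2"), p)
  rel <- read_relations(p)
  expect_equal(rel$polarity, c(1L, -1L, 0L))

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_relations(rel, p2)
  expect_equal(read_relations(p2), rel)

  writeLines(c("source,source_type,target,polarity,n_refs",
               "TNF,gene,MDD,upwards,1"), p)
  expect_error(read_relations(p), "upwards")
})
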