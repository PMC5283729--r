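test_that("readDataset parses a toy table, keeps missing cells, rejects duplicates", {
  tf <- tempfile(fileext = ".tsv")
  write_toy_tsv(tf)
  d <- readDataset(tf, orientation = "samples", meta_cols = "group")
  expect_s4_class(d, "MetaboSet")
  expect_equal(dim(intensities(d)), c(3L, 4L))
  expect_equal(sort(rownames(intensities(d))), c("f1", "f2", "f3"))
  expect_equal(sampleInfo(d)$group, c("a", "a", "b", "b"))

  write_toy_tsv(tf, empty_cell = TRUE)
  d2 <- readDataset(tf, orientation = "samples", meta_cols = "group")
  expect_equal(sum(is.na(intensities(d2))), 1L)

  write_toy_tsv(tf, dup_sample = TRUE)
  expect_error(readDataset(tf, orientation = "samples", meta_cols = "group"),
               "s1")
})

test_that("readDataset names the offending cell for non-numeric intensities", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tgroup\tf1\tf2",
               "s1\ta\t1\t2", "s2\ta\toops\t4",
               "s3\tb\t3\t6", "s4\tb\t4\t8"), tf)
  expect_error(readDataset(tf, orientation = "samples", meta_cols = "group"),
               "s2.*f1|f1.*s2")
})

test_that("features-as-rows orientation with a separate metadata table works", {
  tf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2\ts3\ts4",
               "f1\t1\t2\t3\t4", "f2\t2\t4\t6\t8"), tf)
  writeLines(c("sample\tgroup", "s1\ta", "s2\ta", "s3\tb", "s4\tb"), mf)
  d <- readDataset(tf, orientation = "features", sample_meta_path = mf)
  expect_equal(dim(intensities(d)), c(2L, 4L))
  expect_equal(sampleInfo(d)$group, c("a", "a", "b", "b"))
})

test_that("minimum-value imputation is off by default and halves the feature minimum", {
  tf <- tempfile(fileext = ".tsv")
  write_toy_tsv(tf, empty_cell = TRUE)
  d0 <- readDataset(tf, orientation = "samples", meta_cols = "group")
  expect_true(anyNA(intensities(d0)))
  d1 <- readDataset(tf, orientation = "samples", meta_cols = "group",
                    impute_min = TRUE)
  m <- intensities(d1)
  expect_false(anyNA(m))
  expect_equal(m["f1", "s1"], min(2, 3, 4) / 2)
})

test_that("stats tables and edge lists round-trip through text files", {
  st <- data.frame(entity_id = paste0("c", 1:5), entity_type = "compound",
                   statistic = c(-2.1, 0.5, 3.14159265358979, -0.001, 10),
                   p = c(0.01, 0.2, 0.5, 0.99, 1e-8),
                   pFDR = c(0.05, 0.25, 0.5, 0.99, 5e-8),
                   log2FC = c(-2, 0.1, 1.5, 0, 7), stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  writeTable(st, tf)
  back <- readStatsTable(tf)
  expect_equal(back$entity_id, st$entity_id)
  for (col in c("statistic", "p", "pFDR", "log2FC"))
    expect_equal(back[[col]], st[[col]], tolerance = 1e-12)

  net <- WeightedNetwork(
    data.frame(id = c("a", "b", "c", "d"), node_type = "compound"),
    data.frame(source = c("a", "a", "b"), target = c("b", "c", "d"),
               weight = c(0.9, -0.8, 0.75), kind = "pearson"))
  nf <- tempfile(fileext = ".tsv")
  writeTable(net, nf)
  expect_length(readLines(nf), 4L)  # header + 3 edges
  back <- readNetwork(nf)
  expect_equal(networkEdges(back)$weight, networkEdges(net)$weight,
               tolerance = 1e-12)
  expect_equal(networkEdges(back)$source, networkEdges(net)$source)

  empty <- WeightedNetwork(data.frame(id = "a", node_type = "compound"))
  ef <- tempfile(fileext = ".tsv")
  writeTable(empty, ef)
  expect_length(readLines(ef), 1L)  # header only
})

test_that("datasets round-trip through writeDataset/readDataset", {
  sim <- simulateIntensityDataset(n_features = 10, n_per_group = 5, seed = 3,
                                  missing_rate = 0.05)
  tf <- tempfile(fileext = ".tsv")
  writeDataset(sim$dataset, tf)
  meta <- colnames(sampleInfo(sim$dataset))
  back <- readDataset(tf, orientation = "samples", meta_cols = meta)
  expect_equal(intensities(back), intensities(sim$dataset), tolerance = 1e-12)
  expect_equal(sampleInfo(back)$group, sampleInfo(sim$dataset)$group)
  expect_equal(nrow(validateDataset(back)), 0L)
})

test_that("MetaboSet construction enforces structural invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("f1", "f1"), c("s1", "s2")))
  expect_error(MetaboSet(m), "duplicated feature ids")
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(MetaboSet(m2, data.frame(sample_type = c("qc", "weird"))),
               "sample_type")
  expect_error(
    MetaboSet(m2, data.frame(batch = c("b1", "b1"), injection_order = c(1, 1))),
    "injection_order")
})

test_that("validateDataset reports content-level violations without throwing", {
  d <- toy_dataset()
  expect_equal(nrow(validateDataset(d)), 0L)

  m <- intensities(d); m[1, 1] <- -5
  dneg <- MetaboSet(m, data.frame(group = sampleInfo(d)$group))
  rep <- validateDataset(dneg)
  expect_equal(nrow(rep), 1L)
  expect_match(rep$message, "negative")

  done <- toy_dataset(group = rep("a", 4))
  rep2 <- validateDataset(done, designSpec("two_independent", "group"))
  expect_true(any(rep2$severity == "warning" & grepl("level", rep2$message)))
})

test_that("GMT files round-trip annotation sets", {
  sets <- list(annotationSet("P1", "glycolysis", c("c1", "c2", "c3")),
               annotationSet("P2", "tca cycle", c("c2", "c4")))
  names(sets) <- c("P1", "P2")
  tf <- tempfile(fileext = ".gmt")
  writeGMT(sets, tf)
  back <- readGMT(tf)
  expect_equal(names(back), c("P1", "P2"))
  expect_equal(back$P1$members, sets$P1$members)
  expect_equal(back$P2$term_name, "tca cycle")
  expect_error(annotationSet("empty", members = character()), "no members")
})
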