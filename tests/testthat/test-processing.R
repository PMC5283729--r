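test_that("value transforms are exact on hand-computable inputs", {
  m <- matrix(c(1, 2, 4, 8), 1, dimnames = list("f1", paste0("s", 1:4)))
  d <- MetaboSet(m)
  expect_equal(unname(intensities(transformValues(d, "log2"))[1, ]),
               c(0, 1, 2, 3))
  m2 <- matrix(c(4, 9), 1, dimnames = list("f1", c("s1", "s2")))
  expect_equal(unname(intensities(transformValues(MetaboSet(m2), "power",
                                                  exponent = 0.5))[1, ]),
               c(2, 3))
  m3 <- matrix(c(0, 1), 1, dimnames = list("f1", c("s1", "s2")))
  expect_error(transformValues(MetaboSet(m3), "log2"), "f1.*s1|s1.*f1")
  # missing cells stay missing
  m[1, 2] <- NA
  expect_true(is.na(intensities(transformValues(MetaboSet(m), "log10"))[1, 2]))
})

test_that("sum normalization matches hand arithmetic and equalizes totals", {
  m <- matrix(c(2, 4,
                8, 16), 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  d <- normalizeSamples(MetaboSet(m), "sum")
  # totals 10 and 20, median 15: sample 1 [2,8] -> [3,12]
  expect_equal(unname(intensities(d)[, "s1"]), c(3, 12))
  expect_equal(unname(intensities(d)[, "s2"]), c(3, 12))
  tot <- colSums(intensities(d))
  expect_lt(diff(range(tot)) / mean(tot), 1e-9)
})

test_that("metadata normalization with equal weights is the identity", {
  d <- toy_dataset()
  d2 <- MetaboSet(intensities(d), cbind(sampleInfo(d), mass = rep(2.5, 4)))
  out <- normalizeSamples(d2, "metadata", meta_col = "mass")
  expect_equal(intensities(out), intensities(d2))
  bad <- MetaboSet(intensities(d), cbind(sampleInfo(d), mass = c(2, 2, 0, 2)))
  expect_error(normalizeSamples(bad, "metadata", meta_col = "mass"), "positive")
})

test_that("batch-median normalization divides by reference medians per feature", {
  m <- matrix(c(2, 2, 2, 4, 6,
                10, 10, 10, 5, 15), 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), paste0("s", 1:5)))
  meta <- data.frame(batch = "b1",
                     sample_type = c("qc", "qc", "qc", "biological", "biological"))
  out <- normalizeSamples(MetaboSet(m, meta), "batch_median")
  # reference medians: f1 = 2, f2 = 10
  expect_equal(unname(intensities(out)["f1", ]), m["f1", ] / 2,
               ignore_attr = TRUE)
  expect_equal(unname(intensities(out)["f2", ]), m["f2", ] / 10,
               ignore_attr = TRUE)
  # identity when reference medians are all 1
  m1 <- matrix(c(1, 1, 1, 3, 7), 1, dimnames = list("f1", paste0("s", 1:5)))
  out1 <- normalizeSamples(MetaboSet(m1, meta), "batch_median")
  expect_equal(intensities(out1), m1)
  # no reference samples in a batch is an error naming the batch
  meta2 <- meta; meta2$sample_type <- "biological"
  expect_error(normalizeSamples(MetaboSet(m, meta2), "batch_median"), "b1")
})

test_that("feature scaling matches hand computations and guards constants", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("f1", paste0("s", 1:3)))
  expect_equal(unname(intensities(scaleFeatures(MetaboSet(m), "auto"))[1, ]),
               c(-1, 0, 1))
  expect_equal(unname(intensities(scaleFeatures(MetaboSet(m), "range"))[1, ]),
               c(-0.5, 0, 0.5))
  sdv <- sd(c(1, 2, 3))
  expect_equal(unname(intensities(scaleFeatures(MetaboSet(m), "pareto"))[1, ]),
               (c(1, 2, 3) - 2) / sqrt(sdv))
  mc <- matrix(c(5, 5, 5), 1, dimnames = list("f1", paste0("s", 1:3)))
  expect_warning(out <- scaleFeatures(MetaboSet(mc), "pareto"), "constant")
  expect_equal(unname(intensities(out)[1, ]), c(0, 0, 0))
})

test_that("auto-scaled features have mean 0 and sd 1; pareto mean 0; permutation equivariance", {
  set.seed(21)
  m <- matrix(rlnorm(200), 20, 10,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  d <- MetaboSet(m)
  a <- intensities(scaleFeatures(d, "auto"))
  expect_lt(max(abs(rowMeans(a))), 1e-10)
  expect_lt(max(abs(apply(a, 1, sd) - 1)), 1e-10)
  p <- intensities(scaleFeatures(d, "pareto"))
  expect_lt(max(abs(rowMeans(p))), 1e-10)
  # feature/sample reordering commutes with scaling
  perm_f <- sample(20); perm_s <- sample(10)
  a_perm <- intensities(scaleFeatures(d[perm_f, perm_s], "auto"))
  expect_equal(a_perm, a[perm_f, perm_s])
  # and with sum normalization
  s1 <- intensities(normalizeSamples(d, "sum"))
  s2 <- intensities(normalizeSamples(d[perm_f, perm_s], "sum"))
  expect_equal(s2, s1[perm_f, perm_s])
})

test_that("PCA overview recovers structure and satisfies its algebra", {
  # two perfectly correlated features: one component explains everything
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8), 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  pc <- pcaOverview(MetaboSet(m), n_components = 2)
  expect_equal(pc$explained[1], 1.0, tolerance = 1e-12)

  set.seed(4)
  m2 <- matrix(rnorm(60), 6, 10,
               dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  pc2 <- pcaOverview(MetaboSet(m2), n_components = 6)
  g <- crossprod(pc2$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  recon <- pc2$scores %*% t(pc2$loadings)
  centered <- t(m2) - matrix(pc2$center, 10, 6, byrow = TRUE)
  expect_lt(max(abs(recon - centered)), 1e-8)

  m2[1, 1] <- NA
  expect_error(pcaOverview(MetaboSet(m2)), "missing")
})
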