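test_that("correlation networks threshold on |r| with signed weights", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(f1 = x, f2 = 2 * x, f3 = -x + 10, f4 = c(2, 9, 1, 8, 3, 7))
  colnames(m) <- paste0("s", 1:6)
  net <- correlationNetwork(MetaboSet(m), "pearson", threshold = 0.7)
  ed <- networkEdges(net)
  key <- paste(pmin(ed$source, ed$target), pmax(ed$source, ed$target))
  expect_true("f1 f2" %in% key)
  expect_equal(ed$weight[key == "f1 f2"], 1)
  expect_true("f1 f3" %in% key)              # |r| = 1 for the negative pair
  expect_equal(ed$weight[key == "f1 f3"], -1)
  expect_false(any(grepl("f4", key)))
  expect_equal(networkThreshold(net), 0.7)
})

test_that("constant features are excluded and edge count is monotone in threshold", {
  set.seed(61)
  m <- matrix(rnorm(80), 8, 10,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:10)))
  m[8, ] <- 3
  expect_warning(net <- correlationNetwork(MetaboSet(m), threshold = 0),
                 "constant")
  expect_false("f8" %in% networkNodes(net)$id)
  counts <- vapply(c(0, 0.3, 0.6, 0.9), function(th)
    nrow(networkEdges(correlationNetwork(MetaboSet(m[1:7, ]), threshold = th))),
    0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(62)
  m <- matrix(rlnorm(50), 5, 10,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:10)))
  m2 <- m; m2[1, ] <- exp(m2[1, ])
  n1 <- correlationNetwork(MetaboSet(m), "spearman", threshold = 0.2)
  n2 <- correlationNetwork(MetaboSet(m2), "spearman", threshold = 0.2)
  expect_equal(networkEdges(n1), networkEdges(n2))
})

test_that("partial correlation matches its closed form for 3 variables", {
  set.seed(63)
  n <- 200
  z <- rnorm(n)
  m <- rbind(X = z + rnorm(n, 0, 0.8),
             Y = z + rnorm(n, 0, 0.8),
             Z = rnorm(n))
  colnames(m) <- paste0("s", 1:n)
  R <- cor(t(m))
  pxy_oracle <- (R["X", "Y"] - R["X", "Z"] * R["Y", "Z"]) /
    sqrt((1 - R["X", "Z"]^2) * (1 - R["Y", "Z"]^2))
  net <- partialCorrelationNetwork(MetaboSet(m), threshold = 0,
                                   shrinkage = 0)
  ed <- networkEdges(net)
  got <- ed$weight[(ed$source == "X" & ed$target == "Y") |
                   (ed$source == "Y" & ed$target == "X")]
  expect_equal(got, pxy_oracle, tolerance = 1e-10)
})

test_that("with 2 features the partial correlation equals the marginal one", {
  set.seed(64)
  m <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("f1", "f2"), paste0("s", 1:20)))
  pc <- networkEdges(partialCorrelationNetwork(MetaboSet(m), threshold = 0,
                                               shrinkage = 0))$weight
  expect_equal(pc, cor(m[1, ], m[2, ]), tolerance = 1e-12)
})

test_that("conditioning removes the indirect X-Z association in a Markov chain", {
  set.seed(65)
  n <- 2000
  x <- rnorm(n); y <- x + rnorm(n, 0, 0.6); z <- y + rnorm(n, 0, 0.6)
  m <- rbind(X = x, Y = y, Z = z); colnames(m) <- paste0("s", 1:n)
  d <- MetaboSet(m)
  marg <- cor(x, z)
  expect_gt(abs(marg), 0.5)
  net <- partialCorrelationNetwork(d, threshold = 0, shrinkage = "auto")
  ed <- networkEdges(net)
  pXZ <- ed$weight[(ed$source == "X" & ed$target == "Z") |
                   (ed$source == "Z" & ed$target == "X")]
  expect_lt(abs(pXZ), 0.1)
})

test_that("a singular unshrunk matrix errors with advice; shrinkage handles it", {
  set.seed(66)
  m <- matrix(rnorm(5 * 20), 20, 5)   # 20 features, 5 samples: singular
  rownames(m) <- paste0("f", 1:20); colnames(m) <- paste0("s", 1:5)
  d <- MetaboSet(m)
  expect_error(partialCorrelationNetwork(d, shrinkage = 0), "shrinkage")
  net <- partialCorrelationNetwork(d, shrinkage = "auto")
  expect_s4_class(net, "WeightedNetwork")
  expect_true(attr(net, "shrinkage") > 0)
})

test_that("Tanimoto similarity matches hand counts", {
  a <- fingerprint("a", c(1, 2, 3)); b <- fingerprint("b", c(2, 3, 4))
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, fingerprint("c", c(1, 2, 3))), 1)
  expect_equal(tanimoto(a, fingerprint("d", c(7, 8))), 0)
  net <- tanimotoNetwork(list(a, b, fingerprint("c", c(1, 2, 3)),
                              fingerprint("d", c(7, 8))), threshold = 0.7)
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 1L)   # only the identical pair passes 0.7
  expect_equal(ed$weight, 1)
  expect_error(tanimoto(a, fingerprint("e", 1, length = 10)), "bit length")
})

test_that("fingerprint tables read from TSV and all-zero prints are excluded", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("id\tbits", "c1\t1,2,3", "c2\t2,3,4"), tf)
  fps <- readFingerprints(tf)
  expect_equal(tanimoto(fps$c1, fps$c2), 0.5)
  fps$c3 <- structure(list(id = "c3", positions = integer(), length = 881L),
                      class = "Fingerprint")
  expect_warning(net <- tanimotoNetwork(fps, threshold = 0.4), "all-zero")
  expect_false("c3" %in% networkNodes(net)$id)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(67)
  fps <- randomFingerprints(6, length = 100, density = 0.3, seed = 67)
  ids <- names(fps)
  k <- length(fps)
  Tm <- outer(seq_len(k), seq_len(k),
              Vectorize(function(i, j) tanimoto(fps[[i]], fps[[j]])))
  expect_equal(Tm, t(Tm))
  expect_equal(diag(Tm), rep(1, k))
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  R <- cor(t(m))
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 6))
})
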