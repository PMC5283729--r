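test_that("Welch t matches its hand-evaluated formula and degenerate cases", {
  r <- twoGroupTest(c(1, 2, 3), c(2, 4, 6), "welch")
  # mean diff -2; se = sqrt(1/3 + 4/3); df by Satterthwaite
  expect_equal(r$statistic, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(r$df, (5 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2),
               tolerance = 1e-12)
  expect_equal(r$mean_diff, -2)
  expect_equal(r$log2FC, log2(2 / 4))

  x <- c(5, 6, 7)
  same <- twoGroupTest(x, x, "welch")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  r2 <- twoGroupTest(c(1, 1, 1), c(2, 2, 2), "welch")
  expect_equal(r2$p, 0)
  expect_true(r2$degenerate)
})

test_that("Welch equals Student's statistic under equal sizes and variances", {
  set.seed(31)
  x <- rnorm(12); y <- rnorm(12)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)  # force equal variance
  w <- twoGroupTest(x, y, "welch"); s <- twoGroupTest(x, y, "student")
  expect_equal(w$statistic, s$statistic, tolerance = 1e-12)
  expect_equal(s$df, 22)
  expect_lt(w$df, s$df + 1e-9)
})

test_that("Mann-Whitney exact p matches full enumeration for small samples", {
  # canonical extreme case: one tail 1/20, doubled
  r <- twoGroupTest(c(1, 2, 3), c(4, 5, 6), "mannwhitney")
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  set.seed(32)
  for (i in 1:8) {
    nx <- sample(3:4, 1); ny <- sample(3:4, 1)
    x <- round(rnorm(nx), 4); y <- round(rnorm(ny), 4)
    r <- twoGroupTest(x, y, "mannwhitney")
    expect_equal(r$p, mw_exact_oracle(x, y), tolerance = 1e-12,
                 info = paste("case", i))
  }
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(33)
  x <- rlnorm(15); y <- rlnorm(18) * 1.5
  p1 <- twoGroupTest(x, y, "mannwhitney")$p
  p2 <- twoGroupTest(exp(x), exp(y), "mannwhitney")$p
  p3 <- twoGroupTest(log(x), log(y), "mannwhitney")$p
  expect_equal(p1, p2); expect_equal(p1, p3)
})

test_that("paired tests operate on within-subject differences", {
  set.seed(34)
  x <- rnorm(10, 1); y <- rnorm(10)
  r <- twoGroupTest(x, y, "welch", paired = TRUE)
  tt <- t.test(x - y, mu = 0)
  expect_equal(r$statistic, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)
  rw <- twoGroupTest(x, y, "mannwhitney", paired = TRUE)
  ww <- wilcox.test(x - y, mu = 0, exact = TRUE)
  expect_equal(rw$p, ww$p.value)
})

test_that("multi-group tests match hand formulas and base-R references", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  r <- multiGroupTest(g, "kruskal")
  # rank means 1.5 / 3.5 / 5.5, no ties:
  # H = 12/(N(N+1)) * sum(n_i (rbar_i - (N+1)/2)^2)
  H <- 12 / (6 * 7) * 2 * ((1.5 - 3.5)^2 + 0 + (5.5 - 3.5)^2)
  expect_equal(r$statistic, H, tolerance = 1e-12)

  same <- multiGroupTest(list(c(1, 1), c(1, 1), c(1, 1)), "anova")
  expect_equal(same$statistic, 0); expect_equal(same$p, 1)

  # Welch ANOVA converges to classical ANOVA when group variances and sizes
  # are equal (the heteroscedasticity correction vanishes as n grows)
  for (n in c(20, 2000)) {
    set.seed(n)
    gs <- lapply(1:3, function(i) { v <- rnorm(n); (v - mean(v)) / sd(v) + i / 4 })
    w <- multiGroupTest(gs, "welch_anova"); a <- multiGroupTest(gs, "anova")
    rel <- abs(w$statistic - a$statistic) / a$statistic
    if (n == 20) expect_lt(rel, 0.05) else expect_lt(rel, 1e-3)
  }
  expect_error(multiGroupTest(list(c(1, 2)), "anova"), "2 groups")
})

test_that("repeated-measures ANOVA applies Greenhouse-Geisser correction", {
  # 2 conditions: sphericity trivially holds, epsilon = 1 exactly
  set.seed(36)
  b2 <- matrix(rnorm(16), 8, 2)
  r2 <- repeatedTest(b2, "repeated_anova")
  expect_equal(r2$epsilon, 1)
  # equivalent to a paired t test: F = t^2
  tt <- t.test(b2[, 1] - b2[, 2])
  expect_equal(r2$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-9)

  b3 <- matrix(rnorm(30), 10, 3)
  r3 <- repeatedTest(b3, "repeated_anova")
  expect_true(r3$epsilon > 0.5 && r3$epsilon <= 1)
  # with a real condition effect (F > 1) the correction is conservative
  b3e <- b3 + matrix(rep(c(0, 1, 2), each = 10), 10, 3)
  r3e <- repeatedTest(b3e, "repeated_anova")
  expect_gt(r3e$statistic, 1)
  expect_gte(r3e$p, r3e$p_uncorrected)

  # rows constant per subject: identical condition means, no condition effect
  flat <- matrix(rep(c(1, 2, 3), each = 3), 3, 3, byrow = TRUE)
  expect_equal(repeatedTest(flat, "repeated_anova")$statistic, 0)
  expect_equal(repeatedTest(flat, "repeated_anova")$p, 1)

  miss <- b3; miss[2, 1] <- NA; rownames(miss) <- paste0("sub", 1:10)
  expect_error(repeatedTest(miss, "repeated_anova"), "sub2")
})

test_that("Friedman statistic matches its rank formula on a perfect ordering", {
  b <- matrix(c(1, 2, 3,
                4, 5, 6,
                7, 8, 9), 3, byrow = TRUE)  # ranks (1,2,3) per subject
  r <- repeatedTest(b, "friedman")
  expect_equal(r$statistic, 6, tolerance = 1e-12)
})

test_that("post hoc procedures match hand values and degenerate cases", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  for (meth in c("games_howell", "tukey", "dunn_bonferroni"))
    expect_true(all(postHoc(same, meth)$p_adj == 1), info = meth)

  dn <- postHoc(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)), "dunn_bonferroni")
  z13 <- dn$statistic[dn$group1 == "a" & dn$group2 == "c"]
  expect_equal(abs(z13), 4 / sqrt(3.5), tolerance = 1e-12)

  # Games-Howell approximates Tukey under balanced homoscedastic sampling
  set.seed(37)
  gr <- lapply(1:3, function(i) rnorm(50))
  gh <- postHoc(gr, "games_howell"); tk <- postHoc(gr, "tukey")
  expect_lt(max(abs(gh$p_adj - tk$p_adj)), 0.05)
  expect_equal(order(gh$p_adj), order(tk$p_adj))

  expect_error(postHoc(list(1:3, 4:6), "games_howell"), "3 groups")

  # paired variants work on blocks and clip at 1
  set.seed(38)
  blocks <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("t1", "t2", "t3")))
  pb <- postHoc(blocks, "pairwise_bonferroni")
  expect_equal(nrow(pb), 3L)
  expect_true(all(pb$p_adj >= 0 & pb$p_adj <= 1))
  t12 <- t.test(blocks[, 1] - blocks[, 2])
  expect_equal(pb$statistic[1], unname(t12$statistic))
  expect_equal(pb$p_adj[1], min(1, 3 * t12$p.value))
  wb <- postHoc(blocks, "wilcoxon_bonferroni")
  expect_true(all(wb$p_adj >= 0 & wb$p_adj <= 1))
})

test_that("BH adjustment is the step-up procedure and dominates Bonferroni", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.37), 0.37)
  set.seed(39)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjustBH(p[perm]), adjustBH(p)[perm])
  expect_true(all(adjustBH(p) <= pmin(1, p * 50) + 1e-12))
  # monotone in the rank of p
  expect_true(all(diff(adjustBH(sort(p))) >= -1e-12))
  expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bootstrap p-values are seeded, calibrated under the null, and guarded", {
  x <- c(1.2, 0.8, 1.5, 2.0, 0.9); y <- c(1.1, 1.4, 0.7, 1.8, 1.3)
  b1 <- bootstrapPvalue(x, y, B = 500, seed = 10)
  b2 <- bootstrapPvalue(x, y, B = 500, seed = 10)
  expect_identical(b1$p, b2$p)
  expect_error(bootstrapPvalue(x, y, B = 10, seed = 1), "at least 100")
  # identical pooled distributions: p should be large (within MC error of 1
  # for identical x = y, where the observed statistic is 0)
  bnull <- bootstrapPvalue(x, x, B = 500, seed = 11)
  expect_gte(bnull$p, 1 - 3 * sqrt(0.5 * 0.5 / 500))
})
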