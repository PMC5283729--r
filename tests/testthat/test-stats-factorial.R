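test_that("a balanced 2x2 ANOVA matches an explicit OLS projection oracle", {
  set.seed(41)
  A <- factor(rep(c("a1", "a2"), each = 12))
  B <- factor(rep(rep(c("b1", "b2"), each = 6), 2))
  y <- rnorm(24) + (A == "a2") * 0.8 + (B == "b2") * 0.5 +
    (A == "a2" & B == "b2") * 1.2
  r <- factorialTest(y, A, B, "twoway_independent")

  # independent oracle: orthogonal projections in the balanced case
  cm <- tapply(y, list(A, B), mean)
  ga <- rowMeans(cm); gb <- colMeans(cm); g <- mean(cm)
  n_cell <- 6
  ssA <- 2 * n_cell * sum((ga - g)^2)
  ssB <- 2 * n_cell * sum((gb - g)^2)
  ssAB <- n_cell * sum((cm - outer(ga, gb, "+") + g)^2)
  sse <- sum((y - cm[cbind(A, B)])^2)
  df2 <- 24 - 4
  expect_equal(r$anova$SS, c(ssA, ssB, ssAB), tolerance = 1e-9)
  expect_equal(r$anova$statistic,
               c(ssA, ssB, ssAB) / (sse / df2), tolerance = 1e-9)
  expect_equal(r$anova$p,
               pf(c(ssA, ssB, ssAB) / (sse / df2), 1, df2, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("exactly additive data have zero interaction sum of squares", {
  A <- factor(rep(1:3, each = 8))
  B <- factor(rep(rep(1:2, each = 4), 3))
  ai <- c(1, 4, 9)[as.integer(A)]
  bj <- c(0, 5)[as.integer(B)]
  noise <- rep(c(-1, 1), 12)  # within-cell spread, cell means exactly additive
  y <- ai + bj + noise
  r <- factorialTest(y, A, B, "twoway_independent")
  expect_lt(r$anova$SS[r$anova$effect == "A:B"], 1e-9)
})

test_that("equal cell means give zero F for every effect", {
  A <- factor(rep(1:2, each = 4)); B <- factor(rep(rep(1:2, each = 2), 2))
  y <- rep(c(-1, 1), 4)  # every cell is {-1, 1}: all cell means 0
  r <- factorialTest(y, A, B, "twoway_independent")
  expect_equal(r$anova$statistic, c(0, 0, 0))
  rr <- factorialTest(y, A, B, "twoway_independent", robust = TRUE, trim = 0)
  expect_equal(rr$anova$statistic, c(0, 0, 0))
})

test_that("empty factorial cells are rejected", {
  A <- factor(c(1, 1, 2, 2)); B <- factor(c(1, 1, 1, 1))
  expect_error(factorialTest(rnorm(4), A, B, "twoway_independent"),
               "levels|empty cell")
  A <- factor(c(1, 1, 1, 2, 2, 2)); B <- factor(c(1, 2, 1, 1, 1, 1))
  expect_error(factorialTest(rnorm(6), A, B, "twoway_independent"),
               "empty cell")
})

test_that("the robust Welch-James test reduces to Welch ANOVA at zero trim", {
  set.seed(42)
  y <- rnorm(30) + rep(c(0, 0.5, 1), each = 10)
  fac <- factor(rep(1:3, each = 10))
  cells <- split(y, fac)
  tm <- vapply(cells, mean, 0)
  dv <- vapply(cells, function(v) var(v) / length(v), 0)
  h <- lengths(cells)
  wj <- metabolokit:::.welch_james_stat(tm, dv, h,
                                        metabolokit:::.diff_contrasts(3))
  ot <- oneway.test(y ~ fac)
  expect_equal(wj$statistic, unname(ot$statistic), tolerance = 1e-10)
  expect_equal(wj$df2, unname(ot$parameter[2]), tolerance = 1e-10)
  expect_equal(wj$p, ot$p.value, tolerance = 1e-10)
})

test_that("the robust factorial test tolerates heavy-tailed contamination", {
  set.seed(43)
  A <- factor(rep(c("a1", "a2"), each = 20))
  B <- factor(rep(rep(c("b1", "b2"), each = 10), 2))
  y <- rnorm(40) + (A == "a2" & B == "b2") * 3
  out <- sample(40, 4)
  y[out] <- y[out] + rnorm(4, 0, 30)  # gross outliers
  rr <- factorialTest(y, A, B, "twoway_independent", robust = TRUE)
  expect_true(all(is.finite(rr$anova$statistic)))
  expect_true(all(rr$anova$p >= 0 & rr$anova$p <= 1))
})

test_that("paired and mixed two-way designs use subject error strata", {
  set.seed(44)
  nsub <- 12
  subject <- factor(rep(paste0("s", 1:nsub), each = 4))
  A <- factor(rep(rep(c("a1", "a2"), each = 2), nsub))
  B <- factor(rep(c("b1", "b2"), 2 * nsub))
  subj_eff <- rnorm(nsub, 0, 2)[as.integer(sub("s", "", subject))]
  y <- subj_eff + (A == "a2") * 1 + rnorm(4 * nsub, 0, 0.5)
  rp <- factorialTest(y, A, B, "twoway_paired", subject = subject)
  expect_equal(rp$anova$effect, c("A", "B", "A:B"))
  expect_true(all(rp$anova$p >= 0 & rp$anova$p <= 1))
  expect_lt(rp$anova$p[1], 0.01)    # strong within-subject A effect
  expect_gt(rp$anova$p[3], 0.001)   # no interaction simulated

  # mixed: between factor G, within factor W
  G <- factor(rep(c("g1", "g2"), each = nsub))       # per subject
  subject2 <- factor(rep(paste0("s", 1:(2 * nsub)), each = 2))
  W <- factor(rep(c("w1", "w2"), 2 * nsub))
  Gl <- G[as.integer(sub("s", "", subject2))]
  y2 <- rnorm(2 * nsub, 0, 1)[as.integer(sub("s", "", subject2))] +
    (Gl == "g2") * 1.5 + (W == "w2") * 0.7 + rnorm(4 * nsub, 0, 0.4)
  rm <- factorialTest(y2, Gl, W, "twoway_mixed", subject = subject2)
  expect_true(all(rm$anova$p >= 0 & rm$anova$p <= 1))
  expect_lt(rm$anova$p[2], 0.001)  # within-subject W effect detected
})

test_that("simple main effects appear only for significant interactions", {
  set.seed(45)
  A <- factor(rep(c("a1", "a2"), each = 20))
  B <- factor(rep(rep(c("b1", "b2"), each = 10), 2))
  y_add <- rnorm(40) + (A == "a2") * 1
  r0 <- factorialTest(y_add, A, B, "twoway_independent")
  y_int <- rnorm(40) + (A == "a2" & B == "b2") * 4
  r1 <- factorialTest(y_int, A, B, "twoway_independent")
  expect_null(r0$simple_main_effects)
  sme <- r1$simple_main_effects
  expect_false(is.null(sme))
  expect_true(all(c("factor", "at", "p", "p_adj") %in% colnames(sme)))
  expect_equal(sme$p_adj, adjustBH(sme$p))
  # A differs at B = b2 but not at B = b1
  expect_lt(sme$p_adj[sme$factor == "A" & sme$at == "B=b2"], 0.01)
  expect_gt(sme$p_adj[sme$factor == "A" & sme$at == "B=b1"], 0.05)
})
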