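test_that("Fisher and Stouffer combinations match closed forms", {
  f <- combinePvalues(c(0.05, 0.05), "fisher")
  expect_equal(f$statistic, -2 * (log(0.05) + log(0.05)), tolerance = 1e-10)
  expect_equal(f$p, pchisq(-4 * log(0.05), df = 4, lower.tail = FALSE),
               tolerance = 1e-10)
  s <- combinePvalues(c(0.5, 0.5), "stouffer")
  expect_equal(s$statistic, 0, tolerance = 1e-12)
  expect_equal(s$p, 0.5, tolerance = 1e-12)
  # k = 1 identity for both methods
  expect_equal(combinePvalues(0.123, "fisher")$p, 0.123, tolerance = 1e-10)
  expect_equal(combinePvalues(0.123, "stouffer")$p, 0.123, tolerance = 1e-10)
  expect_warning(combinePvalues(c(0, 0.5), "fisher"), "clipped")
})

test_that("ORA matches exhaustive draw enumeration on small universes", {
  # N=10, K=5, n=4, k=4: 5/210
  universe <- paste0("e", 1:10)
  sets <- list(T1 = annotationSet("T1", members = universe[1:5]))
  res <- oraHypergeometric(universe[1:4], universe, sets)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p, ora_enum_oracle(10, 5, 4, 4), tolerance = 1e-12)
  set.seed(71)
  for (i in 1:6) {
    N <- sample(8:12, 1); K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    universe <- paste0("e", seq_len(N))
    sets <- list(T1 = annotationSet("T1", members = universe[seq_len(K)]))
    selected <- sample(universe, n)
    k <- sum(selected %in% universe[seq_len(K)])
    res <- oraHypergeometric(selected, universe, sets)
    expect_equal(res$p, ora_enum_oracle(N, K, n, k), tolerance = 1e-10,
                 info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
})

test_that("ORA degenerate cases and input validation behave", {
  universe <- paste0("e", 1:10)
  all_ann <- list(T1 = annotationSet("T1", members = universe))
  expect_equal(oraHypergeometric(universe[1:3], universe, all_ann)$p, 1)
  none <- list(T1 = annotationSet("T1", members = universe[6:10]))
  expect_equal(oraHypergeometric(universe[1:3], universe, none)$p, 1)
  expect_error(oraHypergeometric(c("e1", "zz"), universe, all_ann), "zz")
})

test_that("FCS set statistics are definitional and permutation p-values seeded", {
  set.seed(72)
  st <- data.frame(entity_id = paste0("e", 1:40),
                   statistic = rnorm(40), p = runif(40),
                   stringsAsFactors = FALSE)
  sets <- toy_annotation_sets(st$entity_id)
  r_mean <- fcsEnrich(st, sets, "mean", n_perm = 200, seed = 7)
  for (tid in names(sets)) {
    memb <- sets[[tid]]$members
    expect_equal(r_mean$statistic[r_mean$term_id == tid],
                 mean(st$statistic[st$entity_id %in% memb]), tolerance = 1e-12)
  }
  r2 <- fcsEnrich(st, sets, "mean", n_perm = 200, seed = 7)
  expect_identical(r_mean$p, r2$p)
  expect_true(all(r_mean$p >= 1 / 201 & r_mean$p <= 1))
  expect_error(fcsEnrich(st, sets, "mean", n_perm = 50), "at least 100")
  # sets outside the universe are dropped with a warning
  sets$gone <- annotationSet("gone", members = c("zz1", "zz2"))
  expect_warning(fcsEnrich(st, sets, "mean", n_perm = 100, seed = 1), "dropped")
})

test_that("a singleton Fisher set recovers its member's p-value rank", {
  set.seed(73)
  st <- data.frame(entity_id = paste0("e", 1:100), p = runif(100),
                   stringsAsFactors = FALSE)
  target <- st$entity_id[which.min(st$p)]
  sets <- list(S = annotationSet("S", members = target))
  r <- fcsEnrich(st, sets, "fisher", n_perm = 2000, seed = 8)
  # the member has the smallest p of 100, so the permutation p should be
  # near rank/(n+1) = 1/100 within Monte Carlo error
  rank_p <- mean(st$p <= st$p[st$entity_id == target])
  expect_lt(abs(r$p - rank_p), 3 * sqrt(rank_p * (1 - rank_p) / 2000) + 1e-3)
})

test_that("FCS is calibrated under a uniform null across 200 terms", {
  set.seed(74)
  st <- data.frame(entity_id = paste0("e", 1:300), p = runif(300),
                   statistic = rnorm(300), stringsAsFactors = FALSE)
  sets <- lapply(1:200, function(i)
    annotationSet(paste0("T", i), members = sample(st$entity_id, 10)))
  names(sets) <- paste0("T", 1:200)
  r <- fcsEnrich(st, sets, "stouffer", n_perm = 400, seed = 9)
  frac <- mean(r$p < 0.05)
  expect_lt(abs(frac - 0.05), 0.05)
})

test_that("the reporter background standardization is calibrated", {
  set.seed(75)
  st <- data.frame(entity_id = paste0("e", 1:200), p = runif(200),
                   stringsAsFactors = FALSE)
  vals <- pmin(pmax(st$p, .Machine$double.eps), 1 - 1e-16)
  names(vals) <- st$entity_id
  zstat <- function(v) sum(qnorm(1 - v)) / sqrt(length(v))
  k <- 12
  draws <- replicate(1000, zstat(vals[sample.int(200, k)]))
  mu <- mean(draws); sigma <- sd(draws)
  std <- replicate(1000, (zstat(vals[sample.int(200, k)]) - mu) / sigma)
  expect_lt(abs(mean(std)), 0.1)
  expect_lt(abs(sd(std) - 1), 0.1)
  # and the reporter statistic in fcsEnrich is this standardized Z
  sets <- list(S = annotationSet("S", members = st$entity_id[1:k]))
  r <- fcsEnrich(st, sets, "reporter", n_perm = 200, seed = 10,
                 n_background = 2000)
  direct <- zstat(vals[st$entity_id[1:k]])
  expect_lt(abs(r$statistic - (direct - mu) / sigma), 0.15)
})

test_that("multi-type ORA reduces to single-type and combines with Fisher", {
  universe <- paste0("c", 1:12)
  sets <- list(T1 = annotationSet("T1", members = universe[1:6]))
  single <- multitypeOra(list(compound = universe[1:4]),
                         list(compound = universe), sets)
  plain <- oraHypergeometric(universe[1:4], universe, sets)
  expect_equal(single$p, plain$p, tolerance = 1e-12)

  genes <- paste0("g", 1:12)
  sets2 <- list(T1 = annotationSet("T1", members = c(universe[1:6], genes[1:6])))
  two <- multitypeOra(list(compound = universe[1:4], gene = genes[1:4]),
                      list(compound = universe, gene = genes), sets2)
  pc <- oraHypergeometric(universe[1:4], universe, sets2)$p
  pg <- oraHypergeometric(genes[1:4], genes, sets2)$p
  expect_equal(two$p, combinePvalues(c(pc, pg), "fisher")$p, tolerance = 1e-10)

  # a term with members in only one type keeps that type's p
  sets3 <- list(T1 = annotationSet("T1", members = universe[1:6]),
                T2 = annotationSet("T2", members = genes[1:6]))
  mix <- multitypeOra(list(compound = universe[1:4], gene = genes[1:4]),
                      list(compound = universe, gene = genes), sets3)
  expect_equal(mix$p[mix$term_id == "T1"],
               oraHypergeometric(universe[1:4], universe, sets3["T1"])$p,
               tolerance = 1e-12)
})

test_that("term frequencies count exactly with deterministic tie ordering", {
  tf <- termFrequencies(c("b", "a", "b", "c", "b", "a"))
  expect_equal(tf$term, c("b", "a", "c"))
  expect_equal(tf$count, c(3L, 2L, 1L))
  expect_equal(nrow(termFrequencies(character())), 0L)
  ties <- termFrequencies(c("z", "y", "z", "y"))
  expect_equal(ties$term, c("y", "z"))
})
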