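#' Two-group hypothesis test
#'
#' Compares two groups with Welch's t test (default; no equal-variance
#' assumption), Student's t test, or the Mann-Whitney U test. With
#' `paired = TRUE` the test operates on within-subject differences `x - y`
#' (one-sample test against zero; the rank-based variant is the Wilcoxon
#' signed-rank test on the differences). Mann-Whitney p-values are exact
#' (full enumeration) when the combined sample size is at most 20 and there
#' are no ties, and use the normal approximation with tie correction
#' otherwise. All tests are two-sided.
#'
#' Degenerate inputs: when both groups have zero variance, equal means give
#' statistic 0 / p = 1 and unequal means give p = 0 with a
#' `degenerate = TRUE` flag.
#'
#' @param x,y numeric vectors (paired: equal length, ordered by subject).
#' @param method `"welch"`, `"student"` or `"mannwhitney"`.
#' @param paired logical.
#' @return list with `statistic`, `df` (NA for rank tests), `p`,
#'   `mean_diff`, `log2FC` (log2 of the ratio of group means; NA unless both
#'   means are positive), `method`, `paired`, `degenerate`.
#' @examples
#' twoGroupTest(c(1, 2, 3), c(2, 4, 6))$statistic   # Welch t ~ -1.549
#' @export
twoGroupTest <- function(x, y, method = c("welch", "student", "mannwhitney"),
                         paired = FALSE) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (paired) {
    .assert(length(x) == length(y),
            "paired test requires equal-length vectors (complete subject blocks)")
    keep <- complete.cases(x, y); x <- x[keep]; y <- y[keep]
    .assert(length(x) >= 2, "need at least 2 complete pairs")
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    .assert(length(x) >= 2 && length(y) >= 2, "need at least 2 observations per group")
  }
  mean_diff <- mean(x) - mean(y)
  log2fc <- if (mean(x) > 0 && mean(y) > 0) log2(mean(x) / mean(y)) else NA_real_
  base <- list(method = method, paired = paired, mean_diff = mean_diff,
               log2FC = log2fc, degenerate = FALSE)

  if (method %in% c("welch", "student")) {
    novar <- if (paired) var(x - y) == 0 else var(x) == 0 && var(y) == 0
    if (novar) {
      equal <- if (paired) mean(x - y) == 0 else mean(x) == mean(y)
      base$degenerate <- !equal
      return(c(base, list(
        statistic = if (equal) 0 else sign(mean_diff) * Inf,
        df = NA_real_, p = if (equal) 1 else 0)))
    }
    tt <- if (paired) t.test(x - y, mu = 0)
          else t.test(x, y, var.equal = (method == "student"))
    return(c(base, list(statistic = unname(tt$statistic),
                        df = unname(tt$parameter), p = tt$p.value)))
  }
  # mannwhitney
  if (paired) {
    d <- x - y
    if (all(d == 0))
      return(c(base, list(statistic = 0, df = NA_real_, p = 1)))
    exact <- length(d) <= 20 && !any(d == 0) && !anyDuplicated(abs(d))
    wt <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  } else {
    pooled <- c(x, y)
    exact <- (length(pooled) <= 20) && !anyDuplicated(pooled)
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  }
  c(base, list(statistic = unname(wt$statistic), df = NA_real_, p = wt$p.value))
}

#' Multi-group (one-way) hypothesis test
#'
#' Welch's heteroscedastic ANOVA (default), classical one-way ANOVA, or the
#' Kruskal-Wallis rank sum test (with tie correction, chi-square reference).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations; Welch additionally needs positive variance in
#'   each group).
#' @param method `"welch_anova"`, `"anova"` or `"kruskal"`.
#' @return list with `statistic`, `df1`, `df2` (NA for Kruskal-Wallis, whose
#'   `df1` is k - 1), `p`, `method`.
#' @export
multiGroupTest <- function(groups, method = c("welch_anova", "anova", "kruskal")) {
  method <- match.arg(method)
  .assert(is.list(groups) && length(groups) >= 2,
          "need a list of at least 2 groups")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  sizes <- lengths(groups)
  .assert(all(sizes >= 2), "each group needs at least 2 observations")
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), sizes))
  if (length(unique(vals)) == 1L)  # fully degenerate: no variation anywhere
    return(list(statistic = 0, df1 = length(groups) - 1L, df2 = NA_real_,
                p = 1, method = method))
  if (method == "kruskal") {
    kt <- kruskal.test(vals, fac)
    return(list(statistic = unname(kt$statistic), df1 = unname(kt$parameter),
                df2 = NA_real_, p = kt$p.value, method = method))
  }
  if (method == "welch_anova")
    .assert(all(vapply(groups, var, 0) > 0),
            "Welch ANOVA requires positive variance in every group")
  ot <- oneway.test(vals ~ fac, var.equal = (method == "anova"))
  list(statistic = unname(ot$statistic), df1 = unname(ot$parameter[1L]),
       df2 = unname(ot$parameter[2L]), p = ot$p.value, method = method)
}

#' Repeated-measures test on complete subject-by-condition blocks
#'
#' One-way repeated-measures ANOVA with Greenhouse-Geisser sphericity
#' correction, or the Friedman rank test. The Greenhouse-Geisser epsilon is
#' estimated from the sample covariance of the conditions and applied to
#' both degrees of freedom; with two conditions sphericity holds trivially
#' and epsilon is exactly 1.
#'
#' @param blocks numeric matrix, subjects in rows, conditions in columns;
#'   no missing values (incomplete blocks are an error).
#' @param method `"repeated_anova"` or `"friedman"`.
#' @return list with `statistic` (F or Friedman chi-square), `df1`, `df2`,
#'   `p` (Greenhouse-Geisser adjusted for the parametric test),
#'   `p_uncorrected`, `epsilon`, `method`.
#' @export
repeatedTest <- function(blocks, method = c("repeated_anova", "friedman")) {
  method <- match.arg(method)
  blocks <- as.matrix(blocks)
  .assert(ncol(blocks) >= 2, "need at least 2 conditions")
  .assert(nrow(blocks) >= 2, "need at least 2 subjects")
  if (anyNA(blocks)) {
    bad <- rownames(blocks) %||% as.character(seq_len(nrow(blocks)))
    bad <- bad[rowSums(is.na(blocks)) > 0]
    stop(sprintf("incomplete blocks for subject(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(blocks); k <- ncol(blocks)
  if (method == "friedman") {
    ft <- friedman.test(blocks)
    return(list(statistic = unname(ft$statistic), df1 = unname(ft$parameter),
                df2 = NA_real_, p = ft$p.value, p_uncorrected = ft$p.value,
                epsilon = NA_real_, method = method))
  }
  grand <- mean(blocks)
  cond_means <- colMeans(blocks); subj_means <- rowMeans(blocks)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- blocks - outer(subj_means, cond_means, "+") + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_cond <= .Machine$double.eps * abs(grand + 1))
    return(list(statistic = 0, df1 = df1, df2 = df2, p = 1, p_uncorrected = 1,
                epsilon = .gg_epsilon(blocks), method = method))
  if (ss_err == 0)
    return(list(statistic = Inf, df1 = df1, df2 = df2, p = 0, p_uncorrected = 0,
                epsilon = .gg_epsilon(blocks), method = method))
  Fstat <- (ss_cond / df1) / (ss_err / df2)
  eps <- .gg_epsilon(blocks)
  list(statistic = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE),
       p_uncorrected = pf(Fstat, df1, df2, lower.tail = FALSE),
       epsilon = eps, method = method)
}

# Greenhouse-Geisser epsilon from the condition covariance matrix
.gg_epsilon <- function(blocks) {
  k <- ncol(blocks)
  if (k == 2L) return(1)
  S <- cov(blocks)
  C <- .orthonormal_contrasts(k)
  M <- C %*% S %*% t(C)
  trM <- sum(diag(M))
  if (trM <= 0) return(1)
  min(1, trM^2 / ((k - 1) * sum(M^2)))
}

# (k-1) x k orthonormal contrast rows
.orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)           # k x (k-1)
  C <- t(H)
  C / sqrt(rowSums(C^2))
}

#' Pairwise post hoc comparisons
#'
#' Follow-up procedures after a significant multi-group or repeated-measures
#' test, each returning per-pair statistics with multiplicity-adjusted
#' p-values (clipped to \[0, 1\]):
#' \describe{
#'   \item{games_howell}{pairwise Welch statistics with per-pair
#'     Satterthwaite df, referred to the studentized range distribution
#'     (no equal-variance assumption).}
#'   \item{tukey}{Tukey-Kramer honest significant differences from the
#'     pooled error variance.}
#'   \item{dunn_bonferroni}{Dunn's rank-sum z tests with tie correction and
#'     Bonferroni adjustment.}
#'   \item{pairwise_bonferroni}{paired t tests between conditions with
#'     Bonferroni adjustment (repeated-measures follow-up; `groups` must be
#'     a subject-by-condition matrix).}
#'   \item{wilcoxon_bonferroni}{pairwise Wilcoxon signed-rank tests with
#'     Bonferroni adjustment (also on a blocks matrix).}
#' }
#'
#' @param groups list of >= 3 numeric group vectors, or for the paired
#'   variants a subject-by-condition matrix with >= 3 conditions.
#' @param method one of the five procedures above.
#' @return data.frame with `group1`, `group2`, `statistic`, `df`, `p_adj`.
#' @examples
#' postHoc(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)), "dunn_bonferroni")
#' @export
postHoc <- function(groups, method = c("games_howell", "tukey", "dunn_bonferroni",
                                       "pairwise_bonferroni", "wilcoxon_bonferroni")) {
  method <- match.arg(method)
  if (method %in% c("pairwise_bonferroni", "wilcoxon_bonferroni")) {
    blocks <- as.matrix(groups)
    .assert(ncol(blocks) >= 3,
            "paired post hoc needs >= 3 conditions (use twoGroupTest for 2)")
    return(.post_hoc_paired(blocks, method))
  }
  .assert(is.list(groups) && length(groups) >= 3,
          "post hoc needs >= 3 groups (use twoGroupTest for 2)")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  nm <- names(groups) %||% as.character(seq_along(groups))
  k <- length(groups)
  pairs <- combn(k, 2)
  switch(method,
         games_howell = .gh_tukey(groups, nm, pairs, pooled = FALSE),
         tukey = .gh_tukey(groups, nm, pairs, pooled = TRUE),
         dunn_bonferroni = .dunn(groups, nm, pairs))
}

.gh_tukey <- function(groups, nm, pairs, pooled) {
  k <- length(groups)
  n <- lengths(groups); m <- vapply(groups, mean, 0); v <- vapply(groups, var, 0)
  N <- sum(n)
  mse <- sum((n - 1) * v) / (N - k)
  out <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    diff <- m[i] - m[j]
    if (pooled) {
      se <- sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
      df <- N - k
    } else {
      se <- sqrt((v[i] / n[i] + v[j] / n[j]) / 2)
      df <- (v[i] / n[i] + v[j] / n[j])^2 /
        ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
      if (!is.finite(df)) df <- n[i] + n[j] - 2
    }
    if (se == 0) {
      q <- if (diff == 0) 0 else sign(diff) * Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- diff / se
      p <- ptukey(abs(q), nmeans = k, df = df, lower.tail = FALSE)
    }
    c(q, df, p)
  })
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             statistic = out[1, ], df = out[2, ],
             p_adj = pmin(1, pmax(0, out[3, ])), stringsAsFactors = FALSE)
}

.dunn <- function(groups, nm, pairs) {
  vals <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(vals)
  r <- rank(vals)
  rbar <- tapply(r, g, mean)
  ties <- table(vals)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  sig2 <- N * (N + 1) / 12 - tiecor
  n <- lengths(groups)
  mcomp <- ncol(pairs)
  out <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(sig2 * (1 / n[i] + 1 / n[j]))
    z <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p <- min(1, 2 * pnorm(-abs(z)) * mcomp)
    c(z, p)
  })
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             statistic = out[1, ], df = NA_real_, p_adj = out[2, ],
             stringsAsFactors = FALSE)
}

.post_hoc_paired <- function(blocks, method) {
  k <- ncol(blocks)
  nm <- colnames(blocks) %||% as.character(seq_len(k))
  pairs <- combn(k, 2)
  mcomp <- ncol(pairs)
  rows <- apply(pairs, 2L, function(pr) {
    a <- blocks[, pr[1]]; b <- blocks[, pr[2]]
    keep <- complete.cases(a, b); a <- a[keep]; b <- b[keep]
    res <- twoGroupTest(a, b,
                        method = if (method == "pairwise_bonferroni") "welch"
                                 else "mannwhitney",
                        paired = TRUE)
    c(res$statistic, res$df %||% NA_real_, min(1, res$p * mcomp))
  })
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             statistic = rows[1, ], df = rows[2, ], p_adj = rows[3, ],
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment. Order-preserving (monotone in
#' the rank of p) and equivariant under permutation of the input.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values in \[0, 1\], same order as input.
#' @examples
#' adjustBH(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjustBH <- function(p) {
  .assert(is.numeric(p), "p must be numeric")
  .assert(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Bootstrap two-group test
#'
#' Non-parametric significance by resampling the pooled data: both groups
#' are redrawn with replacement from the pooled values (the null of a common
#' distribution) and the absolute test statistic is compared with the
#' observed one. p = (1 + #\{|stat*| >= |observed|\}) / (B + 1).
#'
#' @param x,y numeric group vectors.
#' @param statistic function of `(x, y)` returning a scalar; default is the
#'   Welch t statistic.
#' @param B number of resamples (>= 100).
#' @param seed integer seed (required for reproducibility).
#' @return list with `p`, `observed`, `B`.
#' @export
bootstrapPvalue <- function(x, y, statistic = NULL, B = 1000, seed = 1) {
  .assert(B >= 100, "B must be at least 100 (got %d)", B)
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  statistic <- statistic %||% function(x, y) {
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    if (se == 0) 0 else (mean(x) - mean(y)) / se
  }
  obs <- statistic(x, y)
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  exceed <- .with_seed(seed, {
    sum(vapply(seq_len(B), function(b) {
      xs <- sample(pooled, n1, replace = TRUE)
      ys <- sample(pooled, n2, replace = TRUE)
      abs(statistic(xs, ys)) >= abs(obs)
    }, FALSE))
  })
  list(p = (1 + exceed) / (B + 1), observed = obs, B = B)
}
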