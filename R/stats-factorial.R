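#' Two-way factorial, repeated-measures and mixed ANOVA
#'
#' Tests the two main effects and their interaction for a two-factor layout.
#' Independent designs use ordinary least squares with Type II sums of
#' squares (via [car::Anova()]); `robust = TRUE` switches to a
#' heteroscedasticity-tolerant Welch-James (Johansen) test on 20%-trimmed
#' cell means with winsorized variances. Fully within-subject
#' (`twoway_paired`) and mixed between/within (`twoway_mixed`) designs are
#' fitted as classical univariate ANOVA with subject error strata.
#'
#' When the interaction is significant (p < 0.05, unadjusted), simple main
#' effects are computed: each factor is tested separately within every level
#' of the other factor, with Benjamini-Hochberg adjustment across the
#' resulting slice tests.
#'
#' @param values numeric response vector.
#' @param f1,f2 the two factors (coerced with `factor()`); for
#'   `twoway_mixed`, `f1` is the between-subject factor and `f2` the
#'   within-subject factor.
#' @param design `"twoway_independent"`, `"twoway_paired"` or
#'   `"twoway_mixed"`.
#' @param subject subject ids, required for paired/mixed designs.
#' @param robust logical; trimmed-means Welch-James test
#'   (independent design only).
#' @param trim trimming proportion for the robust test (default 0.2).
#' @return list with `anova` (data.frame: `effect`, `SS`, `df1`, `df2`,
#'   `statistic`, `p`; `SS` is NA for the robust and error-strata fits),
#'   `simple_main_effects` (data.frame or NULL), `method`.
#' @export
factorialTest <- function(values, f1, f2,
                          design = c("twoway_independent", "twoway_paired",
                                     "twoway_mixed"),
                          subject = NULL, robust = FALSE, trim = 0.2) {
  design <- match.arg(design)
  y <- as.numeric(values)
  A <- factor(f1); B <- factor(f2)
  keep <- complete.cases(y, A, B)
  if (!is.null(subject)) keep <- keep & !is.na(subject)
  y <- y[keep]; A <- droplevels(A[keep]); B <- droplevels(B[keep])
  subject <- if (!is.null(subject)) factor(subject[keep])
  .assert(nlevels(A) >= 2 && nlevels(B) >= 2, "each factor needs >= 2 levels")
  cells <- table(A, B)
  if (any(cells == 0))
    stop(sprintf("empty cell(s) in the factorial layout: %s",
                 paste(apply(which(cells == 0, arr.ind = TRUE), 1L, function(ix)
                   paste(levels(A)[ix[1]], levels(B)[ix[2]], sep = ":")),
                   collapse = ", ")), call. = FALSE)

  if (design == "twoway_independent") {
    tab <- if (robust) .welch_james_twoway(y, A, B, trim)
           else .ols_type2_twoway(y, A, B)
  } else {
    .assert(!is.null(subject), "paired/mixed designs require subject ids")
    tab <- .strata_anova(y, A, B, subject, design)
  }
  sme <- NULL
  p_int <- tab$p[tab$effect == "A:B"]
  if (length(p_int) == 1 && is.finite(p_int) && p_int < 0.05)
    sme <- .simple_main_effects(y, A, B, subject, design)
  list(anova = tab, simple_main_effects = sme,
       method = if (robust) "twoway_anova_robust"
                else switch(design, twoway_independent = "twoway_anova",
                            twoway_paired = "twoway_repeated_anova",
                            twoway_mixed = "mixed_anova"))
}

.ols_type2_twoway <- function(y, A, B) {
  fit <- lm(y ~ A * B)
  at <- car::Anova(fit, type = 2)
  eff <- rownames(at)
  idx <- match(c("A", "B", "A:B"), eff)
  resid_row <- match("Residuals", eff)
  df2 <- at$Df[resid_row]
  ss <- at$`Sum Sq`[idx]
  # guard the exact-fit case (zero residual variance)
  Fv <- at$F[idx]; pv <- at$`Pr(>F)`[idx]
  if (at$`Sum Sq`[resid_row] <= 1e-12 * sum(abs(y))) {
    Fv <- ifelse(ss <= 1e-9, 0, Inf)
    pv <- ifelse(ss <= 1e-9, 1, 0)
  }
  data.frame(effect = c("A", "B", "A:B"), SS = ss, df1 = at$Df[idx],
             df2 = df2, statistic = Fv, p = pv, stringsAsFactors = FALSE)
}

# Welch-James/Johansen heteroscedastic test on trimmed cell means.
# With trim = 0 and a single factor this reduces exactly to Welch's ANOVA.
.welch_james_twoway <- function(y, A, B, trim) {
  a <- nlevels(A); b <- nlevels(B)
  cells <- split(y, list(A, B), sep = "\x01")
  # order cells with A slowest, B fastest to match the Kronecker contrasts
  ord <- as.vector(outer(levels(B), levels(A),
                         function(bb, aa) paste(aa, bb, sep = "\x01")))
  cells <- cells[ord]
  tm <- vapply(cells, function(v) mean(v, trim = trim), 0)
  dv <- vapply(cells, .trimmed_mean_var, 0, trim = trim)
  h <- vapply(cells, function(v) length(v) - 2 * floor(trim * length(v)), 0)
  .assert(all(h >= 2), "a cell is too small after trimming")
  MA <- .diff_contrasts(a); MB <- .diff_contrasts(b)
  oneA <- matrix(1 / a, 1, a); oneB <- matrix(1 / b, 1, b)
  effects <- list(A = MA %x% oneB, B = oneA %x% MB, `A:B` = MA %x% MB)
  rows <- lapply(names(effects), function(nm) {
    wj <- .welch_james_stat(tm, dv, h, effects[[nm]])
    data.frame(effect = nm, SS = NA_real_, df1 = wj$df1, df2 = wj$df2,
               statistic = wj$statistic, p = wj$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# squared standard error of the trimmed mean (winsorized variance based)
.trimmed_mean_var <- function(v, trim) {
  n <- length(v)
  g <- floor(trim * n)
  h <- n - 2 * g
  s <- sort(v)
  w <- c(rep(s[g + 1], g), s[(g + 1):(n - g)], rep(s[n - g], g))
  ((n - 1) * var(w)) / (h * (h - 1))
}

.diff_contrasts <- function(k) {
  # (k-1) x k successive-difference contrast rows
  M <- matrix(0, k - 1, k)
  for (i in seq_len(k - 1)) { M[i, i] <- 1; M[i, i + 1] <- -1 }
  M
}

# Johansen (Welch-James) statistic: t = cell estimates, d = their squared
# SEs, h = effective cell sizes, C = contrast matrix for the effect.
.welch_james_stat <- function(t, d, h, C) {
  q <- nrow(C)
  V <- diag(d, nrow = length(d))
  CVC <- C %*% V %*% t(C)
  Ct <- C %*% t
  W <- drop(t(Ct) %*% solve(CVC, Ct))
  P <- V %*% t(C) %*% solve(CVC, C)
  Adiag <- diag(P)
  Aterm <- sum(Adiag^2 / (h - 1))
  denom <- q + 2 * Aterm - 6 * Aterm / (q + 2)
  Fstat <- W / denom
  df2 <- if (Aterm > 0) q * (q + 2) / (3 * Aterm) else Inf
  list(statistic = Fstat, df1 = q, df2 = df2,
       p = pf(Fstat, q, df2, lower.tail = FALSE))
}

# classical univariate ANOVA with subject error strata
.strata_anova <- function(y, A, B, subject, design) {
  df <- data.frame(y = y, A = A, B = B, subject = subject)
  if (design == "twoway_paired")
    fit <- aov(y ~ A * B + Error(subject / (A * B)), data = df)
  else
    fit <- aov(y ~ A * B + Error(subject / B), data = df)
  sm <- summary(fit)
  pull <- function(effect) {
    for (stratum in sm) {
      st <- stratum[[1L]]
      rn <- trimws(rownames(st))
      i <- match(effect, rn)
      if (!is.na(i)) {
        j <- match("Residuals", rn)
        Fv <- st$`F value`[i]; pv <- st$`Pr(>F)`[i]
        if (is.na(Fv)) {  # zero residual stratum
          Fv <- if (st$`Sum Sq`[i] <= 1e-9) 0 else Inf
          pv <- if (st$`Sum Sq`[i] <= 1e-9) 1 else 0
        }
        return(data.frame(effect = effect, SS = st$`Sum Sq`[i], df1 = st$Df[i],
                          df2 = if (!is.na(j)) st$Df[j] else NA_real_,
                          statistic = Fv, p = pv, stringsAsFactors = FALSE))
      }
    }
    data.frame(effect = effect, SS = NA_real_, df1 = NA_real_, df2 = NA_real_,
               statistic = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(c("A", "B", "A:B"), pull))
}

# slice tests of each factor within levels of the other, BH-adjusted
.simple_main_effects <- function(y, A, B, subject, design) {
  within_B <- if (design == "twoway_paired") TRUE
              else if (design == "twoway_mixed") TRUE else FALSE
  within_A <- design == "twoway_paired"
  rows <- list()
  slice_test <- function(vals, fac, subj, within) {
    fac <- droplevels(fac)
    if (nlevels(fac) < 2 || length(vals) < 4) return(NULL)
    if (within && !is.null(subj)) {
      blocks <- tapply(vals, list(factor(subj), fac), mean)
      blocks <- blocks[complete.cases(blocks), , drop = FALSE]
      if (nrow(blocks) < 2) return(NULL)
      if (ncol(blocks) == 2) {
        r <- twoGroupTest(blocks[, 1], blocks[, 2], "welch", paired = TRUE)
        c(statistic = r$statistic, df1 = 1, df2 = r$df, p = r$p)
      } else {
        r <- repeatedTest(blocks, "repeated_anova")
        c(statistic = r$statistic, df1 = r$df1, df2 = r$df2, p = r$p)
      }
    } else {
      gr <- split(vals, fac)
      if (any(lengths(gr) < 2)) return(NULL)
      if (length(gr) == 2) {
        r <- twoGroupTest(gr[[1]], gr[[2]], "welch")
        c(statistic = r$statistic, df1 = 1, df2 = r$df, p = r$p)
      } else {
        r <- multiGroupTest(gr, "welch_anova")
        c(statistic = r$statistic, df1 = r$df1, df2 = r$df2, p = r$p)
      }
    }
  }
  for (lv in levels(B)) {
    sel <- B == lv
    r <- slice_test(y[sel], A[sel], subject[sel], within_A)
    if (!is.null(r))
      rows[[length(rows) + 1L]] <- data.frame(
        factor = "A", at = paste0("B=", lv), t(r), stringsAsFactors = FALSE)
  }
  for (lv in levels(A)) {
    sel <- A == lv
    r <- slice_test(y[sel], B[sel], subject[sel], within_B)
    if (!is.null(r))
      rows[[length(rows) + 1L]] <- data.frame(
        factor = "B", at = paste0("A=", lv), t(r), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adj <- adjustBH(out$p)
  out
}
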