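#' Power analysis for the supported test families
#'
#' Entity-level power calculations based on the noncentral t and F
#' distributions. Two modes: `post_hoc` computes the achieved power of a
#' two-sided test at significance level `alpha` given the per-group sample
#' size; `a_priori` returns the smallest integer per-group sample size
#' reaching `power_target`.
#'
#' Effect sizes follow Cohen: `d` (standardized mean difference) for the
#' t families, `f` (between-group SD over within-group SD) for the one-way
#' ANOVA family.
#'
#' @param mode `"post_hoc"` or `"a_priori"`.
#' @param family `"two_sample_t"`, `"paired_t"` (equivalently one-sample on
#'   differences) or `"anova"`.
#' @param effect Cohen's d (t families) or f (ANOVA), >= 0.
#' @param alpha two-sided significance level in (0, 1).
#' @param n per-group sample size (pairs for `paired_t`); required for
#'   `post_hoc`.
#' @param power_target target power in (alpha, 1); required for `a_priori`.
#' @param k number of groups (ANOVA family only).
#' @return `post_hoc`: list with `power`, `n`; `a_priori`: list with `n`
#'   (per group) and the `power` achieved at that n.
#' @examples
#' powerAnalysis("a_priori", "two_sample_t", effect = 1, alpha = 0.05,
#'               power_target = 0.8)$n   # 17 per group
#' @export
powerAnalysis <- function(mode = c("post_hoc", "a_priori"),
                          family = c("two_sample_t", "paired_t", "anova"),
                          effect, alpha = 0.05, n = NULL, power_target = NULL,
                          k = NULL) {
  mode <- match.arg(mode)
  family <- match.arg(family)
  .assert(is.numeric(effect) && effect >= 0, "effect size must be >= 0")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  if (family == "anova") .assert(!is.null(k) && k >= 2, "ANOVA family needs k >= 2 groups")

  pw <- function(n) .power_at(family, effect, alpha, n, k)
  if (mode == "post_hoc") {
    .assert(!is.null(n) && n >= 2, "post_hoc mode needs a per-group n >= 2")
    return(list(power = pw(n), n = n))
  }
  .assert(!is.null(power_target) && power_target > 0 && power_target < 1,
          "a_priori mode needs a power target in (0, 1)")
  if (effect == 0 && power_target > alpha)
    stop("unreachable power target: effect size 0 gives power = alpha", call. = FALSE)
  n <- 2
  while (pw(n) < power_target) {
    n <- n + 1
    if (n > 1e6) stop("required sample size exceeds 1e6; check the effect size",
                      call. = FALSE)
  }
  list(n = n, power = pw(n))
}

.power_at <- function(family, effect, alpha, n, k) {
  if (family == "anova") {
    df1 <- k - 1; df2 <- k * (n - 1)
    ncp <- effect^2 * k * n
    crit <- qf(1 - alpha, df1, df2)
    return(pf(crit, df1, df2, ncp = ncp, lower.tail = FALSE))
  }
  if (family == "two_sample_t") {
    df <- 2 * (n - 1); ncp <- effect * sqrt(n / 2)
  } else {
    df <- n - 1; ncp <- effect * sqrt(n)
  }
  crit <- qt(1 - alpha / 2, df)
  pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
}
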