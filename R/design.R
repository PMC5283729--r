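#' Suggest statistical methods for a study design
#'
#' Maps each of the seven supported study designs to its hypothesis-testing
#' methods and follow-up procedures, so users are guided to an appropriate
#' analysis without navigating statistical terminology. The first-listed
#' parametric method is the default (the Welch family, robust to unequal
#' variances); the rank-based alternative is flagged non-parametric. Across
#' features, p-values are always adjusted for false discovery rate with the
#' Benjamini-Hochberg procedure.
#'
#' @param design a [DesignSpec-class] or a design name.
#' @return a list of class `"methodSuggestion"` with elements
#'   `design`, `methods` (data.frame: `method`, `label`, `parametric`,
#'   `default`), `follow_up` (data.frame: `after` = `"parametric"`,
#'   `"nonparametric"` or `"all"`, `procedure`, `label`).
#' @examples
#' suggestMethods("two_independent")
#' @export
suggestMethods <- function(design) {
  name <- if (is(design, "DesignSpec")) design@design else as.character(design)
  if (!name %in% .design_names)
    stop(sprintf("unknown design '%s'; expected one of: %s", name,
                 paste(.design_names, collapse = ", ")), call. = FALSE)
  row <- .method_table[[name]]
  structure(list(design = name, methods = row$methods, follow_up = row$follow_up),
            class = "methodSuggestion")
}

#' @export
print.methodSuggestion <- function(x, ...) {
  cat(sprintf("Suggested methods for design '%s':\n", x$design))
  for (i in seq_len(nrow(x$methods)))
    cat(sprintf("  %s%s%s\n", x$methods$label[i],
                if (x$methods$default[i]) " [default]" else "",
                if (!x$methods$parametric[i]) " [non-parametric]" else ""))
  cat("Following procedures:\n")
  for (i in seq_len(nrow(x$follow_up)))
    cat(sprintf("  (%s) %s\n", x$follow_up$after[i], x$follow_up$label[i]))
  invisible(x)
}

.mk_methods <- function(method, label, parametric) {
  data.frame(method = method, label = label, parametric = parametric,
             default = seq_along(method) == 1L, stringsAsFactors = FALSE)
}
.mk_follow <- function(after, procedure, label) {
  data.frame(after = after, procedure = procedure, label = label,
             stringsAsFactors = FALSE)
}

.bh_follow <- .mk_follow("all", "adjust_bh",
  "P-values adjusted for FDR using the Benjamini-Hochberg procedure")

.method_table <- list(
  two_independent = list(
    methods = .mk_methods(c("welch", "mannwhitney", "student"),
                          c("Welch's t test", "Mann-Whitney U test", "t test"),
                          c(TRUE, FALSE, TRUE)),
    follow_up = .bh_follow),
  two_paired = list(
    methods = .mk_methods(c("welch", "mannwhitney"),
                          c("Welch's t test on difference",
                            "Mann-Whitney U test on difference"),
                          c(TRUE, FALSE)),
    follow_up = .bh_follow),
  multi_independent = list(
    methods = .mk_methods(c("welch_anova", "kruskal", "anova"),
                          c("Welch ANOVA", "Kruskal-Wallis rank sum test", "ANOVA"),
                          c(TRUE, FALSE, TRUE)),
    follow_up = rbind(
      .mk_follow("parametric", "games_howell",
                 "Games-Howell (or Tukey) post hoc test on all pairwise group differences"),
      .mk_follow("nonparametric", "dunn_bonferroni",
                 "Pairwise comparisons using Dunn's procedure with Bonferroni adjustment"),
      .bh_follow)),
  multi_paired = list(
    methods = .mk_methods(c("repeated_anova", "friedman"),
                          c("Repeated-measures ANOVA", "Friedman test"),
                          c(TRUE, FALSE)),
    follow_up = rbind(
      .mk_follow("parametric", "greenhouse_geisser",
                 "Greenhouse-Geisser correction for violation of sphericity"),
      .mk_follow("parametric", "pairwise_bonferroni",
                 "Bonferroni post hoc test (pairwise paired comparisons)"),
      .mk_follow("nonparametric", "wilcoxon_bonferroni",
                 "Pairwise Wilcoxon signed-rank tests with Bonferroni correction"),
      .bh_follow)),
  twoway_independent = list(
    methods = .mk_methods(c("twoway_anova", "twoway_anova_robust"),
                          c("Two-way ANOVA",
                            "Two-way ANOVA with robust estimation (20% trimmed means)"),
                          c(TRUE, TRUE)),
    follow_up = rbind(
      .mk_follow("all", "simple_main_effects",
                 "Post hoc analysis on main effect level and simple main effect level"),
      .bh_follow)),
  twoway_paired = list(
    methods = .mk_methods("twoway_repeated_anova", "Two-way repeated-measures ANOVA",
                          TRUE),
    follow_up = rbind(
      .mk_follow("all", "simple_main_effects",
                 "Post hoc analysis on main effect level and simple main effect level"),
      .bh_follow)),
  twoway_mixed = list(
    methods = .mk_methods("mixed_anova", "Mixed ANOVA", TRUE),
    follow_up = rbind(
      .mk_follow("all", "simple_main_effects",
                 "Post hoc analysis on main effect level and simple main effect level"),
      .bh_follow))
)
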