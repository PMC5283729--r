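#' Feature-wise statistical testing driven by a study design
#'
#' Applies the design-appropriate hypothesis test to every feature of a
#' dataset (complete-case per feature), adjusts the per-feature p-values for
#' false discovery across features with Benjamini-Hochberg, and attaches the
#' design's follow-up post hoc tables. Only `sample_type == "biological"`
#' samples enter the tests (QC and blank injections are excluded when a
#' `sample_type` column is present).
#'
#' Features with fewer than 2 complete observations per group are kept in
#' the output with `flag = "insufficient_data"` and NA results rather than
#' silently dropped. For two-way designs the reported per-feature p-value is
#' the interaction test (the design's primary hypothesis); main-effect rows
#' are in the post hoc table.
#'
#' @param d a [MetaboSet-class]
#' @param design a [DesignSpec-class]
#' @param method optional method override (one of the codes listed by
#'   [suggestMethods()] for the design); default = the design's default.
#' @param entity_type entity type recorded in the output
#'   (default `"compound"`).
#' @return list of class `"featureTestResults"`: `table` — the per-entity
#'   statistics data.frame (`entity_id`, `entity_type`, `method`,
#'   `statistic`, `df`, `p`, `pFDR`, `mean_diff`, `log2FC`, `flag`) — and
#'   `post_hoc`, a long-format data.frame of per-feature post hoc rows
#'   (NULL when the design has none).
#' @examples
#' sim <- simulateIntensityDataset(n_features = 20, seed = 1)
#' res <- testFeatures(sim$dataset, sim$design)
#' head(res$table)
#' @export
testFeatures <- function(d, design, method = NULL, entity_type = "compound") {
  stopifnot(is(d, "MetaboSet"), is(design, "DesignSpec"))
  rep <- validateDataset(d, design)
  if (any(rep$severity == "error"))
    stop(paste(rep$message[rep$severity == "error"], collapse = "; "), call. = FALSE)
  sug <- suggestMethods(design)
  method <- method %||% sug$methods$method[sug$methods$default][1L]
  .assert(method %in% sug$methods$method || grepl("^twoway|^mixed", method),
          "method '%s' is not listed for design '%s'", method, design@design)

  si <- sampleInfo(d)
  bio <- if ("sample_type" %in% colnames(si)) si$sample_type == "biological"
         else rep(TRUE, nrow(si))
  m <- intensities(d)[, bio, drop = FALSE]
  si <- si[bio, , drop = FALSE]
  fac1 <- factor(si[[design@factors[1L]]])
  fac2 <- if (length(design@factors) > 1L) factor(si[[design@factors[2L]]])
  subj <- if (!is.na(design@subject)) factor(si[[design@subject]])

  rows <- vector("list", nrow(m))
  ph <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    fid <- rownames(m)[i]
    res <- .test_one_feature(m[i, ], design, method, fac1, fac2, subj)
    rows[[i]] <- data.frame(entity_id = fid, entity_type = entity_type,
                            method = method, statistic = res$statistic,
                            df = res$df, p = res$p,
                            mean_diff = res$mean_diff, log2FC = res$log2FC,
                            flag = res$flag, stringsAsFactors = FALSE)
    if (!is.null(res$post_hoc) && nrow(res$post_hoc))
      ph[[i]] <- cbind(entity_id = fid, res$post_hoc)
  }
  tab <- do.call(rbind, rows)
  tab$pFDR <- adjustBH(tab$p)
  tab <- tab[, c("entity_id", "entity_type", "method", "statistic", "df",
                 "p", "pFDR", "mean_diff", "log2FC", "flag")]
  ph <- ph[!vapply(ph, is.null, TRUE)]
  structure(list(table = tab,
                 post_hoc = if (length(ph)) do.call(rbind, ph) else NULL,
                 design = design, method = method),
            class = "featureTestResults")
}

#' @export
print.featureTestResults <- function(x, ...) {
  cat(sprintf("featureTestResults: %d features, design '%s', method '%s'\n",
              nrow(x$table), x$design@design, x$method))
  nsig <- sum(x$table$pFDR < 0.05, na.rm = TRUE)
  cat(sprintf("significant at pFDR < 0.05: %d\n", nsig))
  invisible(x)
}

.na_result <- function(flag = "insufficient_data") {
  list(statistic = NA_real_, df = NA_real_, p = NA_real_,
       mean_diff = NA_real_, log2FC = NA_real_, flag = flag, post_hoc = NULL)
}

.test_one_feature <- function(y, design, method, fac1, fac2, subj) {
  des <- design@design
  out <- .na_result(flag = "")
  if (des %in% c("two_independent", "multi_independent")) {
    gr <- split(y, fac1)
    gr <- lapply(gr, function(v) v[!is.na(v)])
    if (any(lengths(gr) < 2) ||
        (des == "two_independent" && length(gr) != 2)) return(.na_result())
    if (des == "two_independent") {
      r <- twoGroupTest(gr[[1L]], gr[[2L]], method)
      out[c("statistic", "df", "p", "mean_diff", "log2FC")] <-
        r[c("statistic", "df", "p", "mean_diff", "log2FC")]
    } else {
      r <- multiGroupTest(gr, method)
      out$statistic <- r$statistic; out$df <- r$df1; out$p <- r$p
      ph_method <- if (method == "kruskal") "dunn_bonferroni" else "games_howell"
      out$post_hoc <- tryCatch(postHoc(gr, ph_method), error = function(e) NULL)
    }
  } else if (des == "two_paired") {
    blocks <- tapply(y, list(subj, fac1), mean)
    blocks <- blocks[complete.cases(blocks), , drop = FALSE]
    if (nrow(blocks) < 2 || ncol(blocks) != 2) return(.na_result())
    r <- twoGroupTest(blocks[, 1L], blocks[, 2L], method, paired = TRUE)
    out[c("statistic", "df", "p", "mean_diff", "log2FC")] <-
      r[c("statistic", "df", "p", "mean_diff", "log2FC")]
  } else if (des == "multi_paired") {
    blocks <- tapply(y, list(subj, fac1), mean)
    blocks <- blocks[complete.cases(blocks), , drop = FALSE]
    if (nrow(blocks) < 2) return(.na_result())
    r <- repeatedTest(blocks, method)
    out$statistic <- r$statistic; out$df <- r$df1; out$p <- r$p
    ph_method <- if (method == "friedman") "wilcoxon_bonferroni"
                 else "pairwise_bonferroni"
    out$post_hoc <- tryCatch(postHoc(blocks, ph_method), error = function(e) NULL)
  } else {  # two-way designs
    robust <- identical(method, "twoway_anova_robust")
    within2 <- design@factors[2L] %in% design@within
    A <- fac1; B <- fac2
    if (des == "twoway_mixed" && !within2) { A <- fac2; B <- fac1 }
    r <- tryCatch(factorialTest(y, A, B, design = des, subject = subj,
                                robust = robust),
                  error = function(e) NULL)
    if (is.null(r)) return(.na_result())
    it <- r$anova[r$anova$effect == "A:B", ]
    out$statistic <- it$statistic; out$df <- it$df1; out$p <- it$p
    main <- r$anova[r$anova$effect != "A:B", ]
    main_rows <- data.frame(group1 = paste("main", main$effect),
                            group2 = "", statistic = main$statistic,
                            df = main$df1, p_adj = main$p,
                            stringsAsFactors = FALSE)
    sme_rows <- NULL
    if (!is.null(r$simple_main_effects)) {
      s <- r$simple_main_effects
      sme_rows <- data.frame(group1 = paste("simple", s$factor),
                             group2 = s$at, statistic = s$statistic,
                             df = s$df1, p_adj = s$p_adj,
                             stringsAsFactors = FALSE)
    }
    out$post_hoc <- rbind(main_rows, sme_rows)
  }
  out
}
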