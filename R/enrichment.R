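#' Combine p-values across entities or node types
#'
#' Fisher's combined probability test: X2 = -2 * sum(log p) referred to a
#' chi-square distribution with 2k degrees of freedom. Stouffer's method:
#' Z = sum(qnorm(1 - p)) / sqrt(k) referred to the upper tail of the
#' standard normal (one-sided aggregation of significance). Boundary
#' p-values (0 or 1) are clipped into the open interval with a warning.
#'
#' @param p numeric vector of p-values.
#' @param method `"fisher"` or `"stouffer"`.
#' @return list with `statistic` (X2 or Z), `p` (combined), `k`, `method`.
#' @examples
#' combinePvalues(c(0.05, 0.05), "fisher")   # X2 ~ 11.98, p ~ 0.0175
#' @export
combinePvalues <- function(p, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  .assert(length(p) >= 1 && !anyNA(p) && all(p >= 0 & p <= 1),
          "p-values must lie in [0, 1]")
  eps <- .Machine$double.eps
  if (any(p <= 0) || any(p >= 1)) {
    warning("boundary p-value(s) clipped into (0, 1)")
    p <- pmin(pmax(p, eps), 1 - 1e-16)
  }
  k <- length(p)
  if (method == "fisher") {
    x2 <- -2 * sum(log(p))
    list(statistic = x2, p = pchisq(x2, df = 2 * k, lower.tail = FALSE),
         k = k, method = method)
  } else {
    z <- sum(qnorm(1 - p)) / sqrt(k)
    list(statistic = z, p = pnorm(z, lower.tail = FALSE), k = k, method = method)
  }
}

#' Functional class scoring (set enrichment from entity-level statistics)
#'
#' Scores annotation terms from per-entity statistics without a hard
#' significance cutoff on the entities. Set statistics:
#' \describe{
#'   \item{fisher}{-2 * sum(log p) over member p-values.}
#'   \item{stouffer}{sum(qnorm(1 - p)) / sqrt(k).}
#'   \item{reporter}{the Stouffer Z standardized against a background of
#'     random same-size entity sets (mean/sd over `n_background` draws).}
#'   \item{median, mean}{median/mean of the member entities' `statistic`
#'     column.}
#' }
#' Significance is assessed by entity-label permutation: the set statistic
#' is recomputed for `n_perm` random same-size draws from the universe and
#' p = (1 + #\{perm >= observed\}) / (n_perm + 1) (for median/mean, two-sided
#' via the absolute deviation from the permutation mean). BH adjustment
#' across terms.
#'
#' @param stats a stats table (data.frame with `entity_id`, `p` and, for
#'   median/mean, `statistic`).
#' @param sets named list of annotation sets ([annotationSet()]).
#' @param method one of `"fisher"`, `"stouffer"`, `"reporter"`, `"median"`,
#'   `"mean"`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation and background draws.
#' @param n_background background draws per set size (reporter method).
#' @return data.frame with `term_id`, `term_name`, `size`, `statistic`,
#'   `p`, `pFDR`, `direction`, `method`, sorted by `p`.
#' @export
fcsEnrich <- function(stats, sets, method = c("fisher", "stouffer", "reporter",
                                              "median", "mean"),
                      n_perm = 1000, seed = 1, n_background = 1000) {
  method <- match.arg(method)
  .assert(n_perm >= 100, "n_perm must be at least 100")
  .assert("entity_id" %in% colnames(stats), "stats needs an entity_id column")
  p_based <- method %in% c("fisher", "stouffer", "reporter")
  vcol <- if (p_based) "p" else "statistic"
  .assert(vcol %in% colnames(stats), "method '%s' needs a '%s' column", method, vcol)
  univ <- stats$entity_id[!is.na(stats[[vcol]])]
  vals <- stats[[vcol]][!is.na(stats[[vcol]])]
  names(vals) <- univ
  if (p_based) vals <- pmin(pmax(vals, .Machine$double.eps), 1 - 1e-16)
  .assert(length(univ) >= 2, "universe of scored entities is too small")

  member_idx <- lapply(sets, function(s) which(univ %in% s$members))
  empty <- lengths(member_idx) == 0L
  if (any(empty)) {
    warning(sprintf("set(s) with no members in the universe dropped: %s",
                    paste(vapply(sets[empty], `[[`, "", "term_id"), collapse = ", ")))
    sets <- sets[!empty]; member_idx <- member_idx[!empty]
  }
  .assert(length(sets) >= 1, "no usable annotation sets")

  set_stat <- switch(method,
    fisher = function(v) -2 * sum(log(v)),
    stouffer = ,
    reporter = function(v) sum(qnorm(1 - v)) / sqrt(length(v)),
    median = function(v) median(v),
    mean = function(v) mean(v))

  sizes <- lengths(member_idx)
  .with_seed(seed, {
    bg <- NULL
    if (method == "reporter") {
      bg <- lapply(unique(sizes), function(k) {
        zs <- vapply(seq_len(n_background), function(b)
          set_stat(vals[sample.int(length(vals), k)]), 0)
        c(mu = mean(zs), sigma = sd(zs))
      })
      names(bg) <- as.character(unique(sizes))
    }
    obs <- vapply(seq_along(sets), function(i) {
      s <- set_stat(vals[member_idx[[i]]])
      if (method == "reporter") {
        b <- bg[[as.character(sizes[i])]]
        s <- (s - b["mu"]) / b["sigma"]
      }
      unname(s)
    }, 0)
    # permutation null per distinct set size
    perm_by_size <- lapply(unique(sizes), function(k) {
      vapply(seq_len(n_perm), function(b) {
        s <- set_stat(vals[sample.int(length(vals), k)])
        if (method == "reporter") {
          b2 <- bg[[as.character(k)]]
          s <- unname((s - b2["mu"]) / b2["sigma"])
        }
        s
      }, 0)
    })
    names(perm_by_size) <- as.character(unique(sizes))
    pv <- vapply(seq_along(sets), function(i) {
      perm <- perm_by_size[[as.character(sizes[i])]]
      if (p_based)
        (1 + sum(perm >= obs[i])) / (n_perm + 1)
      else {
        ctr <- mean(perm)
        (1 + sum(abs(perm - ctr) >= abs(obs[i] - ctr))) / (n_perm + 1)
      }
    }, 0)
  })
  direction <- if ("log2FC" %in% colnames(stats)) {
    fc <- setNames(stats$log2FC, stats$entity_id)
    vapply(sets, function(s) {
      mfc <- mean(fc[intersect(s$members, univ)], na.rm = TRUE)
      if (is.na(mfc) || mfc == 0) "" else if (mfc > 0) "up" else "down"
    }, "")
  } else rep("", length(sets))
  out <- data.frame(
    term_id = vapply(sets, `[[`, "", "term_id"),
    term_name = vapply(sets, `[[`, "", "term_name"),
    size = sizes, statistic = obs, p = pv, pFDR = adjustBH(pv),
    direction = unname(direction), method = method,
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$term_id), ]
}

#' Hypergeometric overrepresentation analysis
#'
#' For each annotation term with K members in the universe (size N), the
#' probability of observing at least the actual overlap k within a selected
#' list of size n under random sampling without replacement:
#' p = P(X >= k), X ~ Hypergeometric(N, K, n). Upper tail only
#' (overrepresentation). BH adjustment across terms.
#'
#' @param selected character vector of selected entity ids (must be a
#'   subset of `universe`).
#' @param universe character vector of all measured/considered entity ids.
#' @param sets named list of annotation sets.
#' @return data.frame with `term_id`, `term_name`, `size` (K), `overlap`
#'   (k), `p`, `pFDR`, sorted by `p`; terms with no member in the universe
#'   are dropped.
#' @export
oraHypergeometric <- function(selected, universe, sets) {
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  stray <- setdiff(selected, universe)
  if (length(stray))
    stop(sprintf("selected id(s) not in the universe: %s",
                 paste(head(stray, 10), collapse = ", ")), call. = FALSE)
  N <- length(universe); n <- length(selected)
  rows <- lapply(sets, function(s) {
    memb <- intersect(s$members, universe)
    K <- length(memb)
    if (K == 0L) return(NULL)
    k <- length(intersect(memb, selected))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = s$term_id, term_name = s$term_name, size = K,
               overlap = k, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  .assert(length(rows) >= 1, "no annotation set intersects the universe")
  out <- do.call(rbind, rows)
  out$pFDR <- adjustBH(out$p)
  rownames(out) <- NULL
  out[order(out$p, out$term_id), ]
}

#' Overrepresentation analysis across multiple node types
#'
#' For networks mixing node types (genes, proteins, compounds), runs the
#' hypergeometric test per node type against that type's universe and
#' combines the per-type p-values for each term with Fisher's method over
#' the types in which the term has members.
#'
#' @param selected_by_type named list (by node type) of selected id vectors.
#' @param universe_by_type named list (by node type) of universe id vectors.
#' @param sets named list of annotation sets (members may span types).
#' @return data.frame with `term_id`, `term_name`, `types` (combined
#'   types), `statistic` (Fisher X2), `p`, `pFDR`, plus per-type p columns.
#' @export
multitypeOra <- function(selected_by_type, universe_by_type, sets) {
  .assert(length(selected_by_type) >= 1, "at least one node type required")
  types <- names(selected_by_type)
  .assert(!is.null(types) && all(types %in% names(universe_by_type)),
          "selected and universe lists must share node-type names")
  per_type <- lapply(types, function(ty) {
    res <- tryCatch(
      oraHypergeometric(selected_by_type[[ty]], universe_by_type[[ty]], sets),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    setNames(res$p, res$term_id)
  })
  names(per_type) <- types
  term_ids <- unique(unlist(lapply(per_type, names)))
  .assert(length(term_ids) >= 1, "no term has members in any type's universe")
  nm <- setNames(vapply(sets, `[[`, "", "term_name"),
                 vapply(sets, `[[`, "", "term_id"))
  rows <- lapply(term_ids, function(tid) {
    ps <- unlist(lapply(types, function(ty) per_type[[ty]][tid]))
    ps <- ps[!is.na(ps)]
    used <- types[vapply(types, function(ty) !is.na(per_type[[ty]][tid]), TRUE)]
    if (length(ps) == 1L)
      comb <- list(statistic = NA_real_, p = unname(ps))
    else
      comb <- suppressWarnings(combinePvalues(ps, "fisher"))
    row <- data.frame(term_id = tid, term_name = unname(nm[tid]),
                      types = paste(used, collapse = ","),
                      statistic = comb$statistic, p = comb$p,
                      stringsAsFactors = FALSE)
    for (ty in types) row[[paste0("p_", ty)]] <- unname(per_type[[ty]][tid])
    row
  })
  out <- do.call(rbind, rows)
  out$pFDR <- adjustBH(out$p)
  out[order(out$p, out$term_id), ]
}

#' Annotation term frequencies
#'
#' Multiset counts of annotation terms for a list of entities — the numeric
#' backbone of a word-cloud summary (a term's display size is proportional
#' to its member count). Deterministic ordering: count descending, then term
#' ascending.
#'
#' @param terms character vector of annotation terms (one entry per
#'   entity-term association; duplicates are counted).
#' @return data.frame with `term` and `count`; empty input gives an empty
#'   table.
#' @export
termFrequencies <- function(terms) {
  terms <- as.character(terms)
  if (!length(terms))
    return(data.frame(term = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tb <- table(terms)
  out <- data.frame(term = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$term), ]
  rownames(out) <- NULL
  out
}
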