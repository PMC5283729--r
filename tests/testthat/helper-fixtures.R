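# shared in-code fixtures and independent oracles

toy_dataset <- function(m = NULL, group = c("a", "a", "b", "b")) {
  if (is.null(m))
    m <- matrix(c(1, 2, 4, 8,
                  2, 4, 6, 8,
                  5, 5, 5, 5), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  MetaboSet(m, data.frame(group = group))
}

write_toy_tsv <- function(path, dup_sample = FALSE, empty_cell = FALSE) {
  df <- data.frame(sample = paste0("s", 1:4),
                   group = c("a", "a", "b", "b"),
                   f1 = c(1, 2, 3, 4), f2 = c(2, 4, 6, 8), f3 = c(1, 1, 2, 2))
  if (dup_sample) df$sample[2] <- "s1"
  lines <- c(paste(colnames(df), collapse = "\t"),
             apply(df, 1L, paste, collapse = "\t"))
  if (empty_cell) lines[2] <- sub("\t1\t2\t", "\t\t2\t", lines[2])
  writeLines(lines, path)
  path
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(nx + ny, nx)
  us <- apply(combs, 2L, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# hypergeometric upper-tail p by enumeration of all draws of size n
ora_enum_oracle <- function(N, K, n, k) {
  draws <- combn(N, n)
  ann <- seq_len(K)  # first K entities annotated
  overlaps <- apply(draws, 2L, function(d) sum(d %in% ann))
  mean(overlaps >= k)
}

# exhaustive maximum-scoring connected subgraph (tiny graphs only)
subnet_exhaustive_oracle <- function(net, scores) {
  ids <- networkNodes(net)$id
  g <- asIgraph(net)
  best <- max(scores[ids])
  n <- length(ids)
  if (n >= 2) for (m in 2:n) for (comb in combn(n, m, simplify = FALSE)) {
    sg <- igraph::induced_subgraph(g, ids[comb])
    if (igraph::is_connected(sg)) best <- max(best, sum(scores[ids[comb]]))
  }
  best
}

random_test_network <- function(seed, nmin = 5, nmax = 10, p_edge = 0.35) {
  set.seed(seed)
  n <- sample(nmin:nmax, 1)
  ids <- paste0("n", seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  ed <- if (any(keep))
    data.frame(source = ids[pairs[keep, 1]], target = ids[pairs[keep, 2]],
               weight = 1, kind = "partial", stringsAsFactors = FALSE)
  else NULL
  scores <- setNames(round(rnorm(n), 2), ids)
  if (all(scores <= 0)) scores[1] <- 0.5
  list(net = WeightedNetwork(data.frame(id = ids, node_type = "compound",
                                        stringsAsFactors = FALSE), ed),
       scores = scores)
}

toy_annotation_sets <- function(universe, sizes = c(3, 5, 8), seed = 99) {
  set.seed(seed)
  sets <- lapply(seq_along(sizes), function(i)
    annotationSet(paste0("T", i), paste0("term", i),
                  sample(universe, sizes[i])))
  names(sets) <- vapply(sets, `[[`, "", "term_id")
  sets
}
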