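#' Fit a beta-uniform mixture to a p-value distribution
#'
#' Maximum-likelihood fit of f(p) = lambda + (1 - lambda) * a * p^(a - 1),
#' a uniform noise component (weight lambda) plus a Beta(a, 1) signal
#' component concentrating near zero (0 < a < 1). The fit underlies node
#' scoring for high-scoring subnetwork search: from the requested FDR level
#' the model yields the p-value threshold tau at which calls have the
#' desired false discovery rate,
#' tau = (((pi - fdr * lambda) / (fdr * (1 - lambda))))^(1 / (a - 1)) with
#' pi = lambda + (1 - lambda) * a the density upper bound at p = 1.
#'
#' Optimization is over (lambda, a) in the open unit square from a small
#' grid of starts; zero p-values are clipped to machine epsilon with a
#' warning.
#'
#' @param p numeric vector of p-values in (0, 1]; at least 100 values are
#'   recommended for a stable fit.
#' @param fdr FDR level used to derive the threshold tau (default 0.05).
#' @return a [BumFit-class].
#' @seealso [scoreNodes()], [maxScoringSubnetwork()], [simulatePvalues()]
#' @export
fitBum <- function(p, fdr = 0.05) {
  p <- as.numeric(p)
  .assert(!anyNA(p) && all(p <= 1) && all(p >= 0), "p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-values equal to 0 clipped to machine epsilon")
    p[p == 0] <- .Machine$double.eps
  }
  .assert(fdr > 0 && fdr < 1, "fdr must be in (0, 1)")
  lp <- log(p)
  negll <- function(par) {
    lam <- par[1L]; a <- par[2L]
    -sum(log(lam + (1 - lam) * a * exp((a - 1) * lp)))
  }
  eps <- 1e-6
  starts <- expand.grid(lambda = c(0.3, 0.5, 0.7, 0.9),
                        a = c(0.1, 0.3, 0.5, 0.7))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), negll, method = "L-BFGS-B",
            lower = c(eps, eps), upper = c(1 - eps, 1 - eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  .assert(!is.null(best), "beta-uniform mixture fit failed")
  lam <- best$par[1L]; a <- best$par[2L]
  pihat <- lam + (1 - lam) * a
  tau <- ((pihat - fdr * lam) / (fdr * (1 - lam)))^(1 / (a - 1))
  if (!is.finite(tau) || tau >= 1 || tau <= 0) {
    warning("FDR level implies no usable p-value threshold; tau clamped")
    tau <- min(max(tau, .Machine$double.eps), 1 - 1e-12)
  }
  new("BumFit", lambda = lam, a = a, fdr = fdr, tau = tau,
      loglik = -best$value, n = length(p))
}

#' Log-likelihood of a beta-uniform mixture
#'
#' @param p p-values in (0, 1].
#' @param lambda,a mixture parameters.
#' @return the log-likelihood (sum of log densities).
#' @export
bumLogLik <- function(p, lambda, a) {
  sum(log(lambda + (1 - lambda) * a * p^(a - 1)))
}

#' Score network nodes from a beta-uniform mixture fit
#'
#' Converts per-node p-values into additive node scores
#' score(p) = (a - 1) * (log p - log tau): positive exactly when p < tau
#' (the FDR-controlled significance threshold of the fit), monotone
#' decreasing in p. Nodes without a p-value receive `default_score`
#' (by default the score at p = 1, the most negative attainable) with a
#' warning.
#'
#' @param fit a [BumFit-class].
#' @param p named numeric vector of p-values (names = node ids).
#' @param node_ids ids to score (default: names of `p`).
#' @param default_score score for nodes missing from `p`.
#' @return named numeric vector of scores for `node_ids`.
#' @export
scoreNodes <- function(fit, p, node_ids = names(p), default_score = NULL) {
  stopifnot(is(fit, "BumFit"))
  .assert(!is.null(names(p)), "p must be a named vector")
  default_score <- default_score %||% ((fit@a - 1) * (0 - log(fit@tau)))
  .assert(default_score <= 0, "the default score for unscored nodes must be <= 0")
  pv <- pmax(p[node_ids], .Machine$double.eps)
  sc <- (fit@a - 1) * (log(pv) - log(fit@tau))
  miss <- is.na(sc)
  if (any(miss)) {
    warning(sprintf("%d node(s) without a p-value scored at the default %.3g",
                    sum(miss), default_score))
    sc[miss] <- default_score
  }
  names(sc) <- node_ids
  sc
}

#' Heuristic maximum-scoring connected subnetwork
#'
#' Searches a node-scored network for a connected subgraph with a large
#' total score (the "active module"). Two deterministic candidates are
#' computed and the better one returned:
#' \enumerate{
#'   \item Greedy prize-collecting expansion: from each positive-scoring
#'     node in turn, the subgraph grows by the neighbor move with the best
#'     score gain — a single neighbor or, with one step of lookahead, a
#'     negative "bridge" neighbor together with its best positive neighbor —
#'     while the gain is positive; negative nodes whose removal keeps the
#'     subgraph connected are pruned afterwards.
#'   \item Spanning-tree refinement: on each connected component, a minimum
#'     spanning tree with edge cost -(score(u) + score(v))/2 concentrates
#'     high-scoring nodes into subtrees, and the maximum-weight connected
#'     subtree is then found exactly by dynamic programming on the tree.
#'     This candidate can cross chains of several negative connector nodes
#'     that stepwise expansion cannot justify.
#' }
#' Ties break deterministically (higher node score, then lexicographic id).
#'
#' The result is always connected, is a subgraph of the input, and its score
#' is at least the best single-node score. If every score is negative the
#' best single node is returned with a warning.
#'
#' @param net a [WeightedNetwork-class].
#' @param scores named numeric vector covering all node ids of `net`.
#' @return list with `nodes` (ids), `score` (total), `network`
#'   (the induced [WeightedNetwork-class] subgraph).
#' @export
maxScoringSubnetwork <- function(net, scores) {
  stopifnot(is(net, "WeightedNetwork"))
  ids <- net@nodes$id
  .assert(all(ids %in% names(scores)), "scores must cover every node id")
  scores <- scores[ids]
  if (!length(ids)) stop("empty network", call. = FALSE)
  adj <- .adjacency_list(net)
  starts <- ids[scores > 0]
  if (!length(starts)) {
    warning("all node scores are negative; returning the single best node")
    best <- ids[order(-scores, ids)][1L]
    return(.subnet_result(net, best, scores))
  }
  starts <- starts[order(-scores[starts], starts)]
  best_set <- NULL; best_score <- -Inf
  for (s in starts) {
    res <- .greedy_expand(s, adj, scores)
    if (res$score > best_score + 1e-12) {
      best_score <- res$score; best_set <- res$nodes
    }
  }
  cands <- list(.mst_subtree(net, scores), .cluster_merge(net, scores))
  # Steiner-style hubs: a negative node shared by several connector paths is
  # undervalued by pairwise path costs; retry the merge with its cost waived
  # (capped sweep, ordered by least cost), rescoring with the true scores.
  hubs <- .bridge_hubs(adj, scores)
  for (v in head(hubs, 25L)) {
    sc2 <- scores; sc2[v] <- 0
    cand <- .cluster_merge(net, sc2)
    if (!is.null(cand)) {
      cand$score <- sum(scores[cand$nodes])
      cands <- c(cands, list(cand))
    }
  }
  for (cand in cands) {
    if (!is.null(cand) && cand$score > best_score + 1e-12) {
      best_score <- cand$score; best_set <- cand$nodes
    }
  }
  .subnet_result(net, best_set, scores)
}

.adjacency_list <- function(net) {
  ids <- net@nodes$id
  adj <- setNames(vector("list", length(ids)), ids)
  ed <- net@edges
  for (i in seq_len(nrow(ed))) {
    s <- ed$source[i]; t <- ed$target[i]
    if (s == t) next
    adj[[s]] <- c(adj[[s]], t)
    adj[[t]] <- c(adj[[t]], s)
  }
  lapply(adj, unique)
}

.greedy_expand <- function(start, adj, scores) {
  inset <- start
  total <- scores[[start]]
  repeat {
    nbrs <- setdiff(unique(unlist(adj[inset], use.names = FALSE)), inset)
    if (!length(nbrs)) break
    # single-node moves
    gains <- scores[nbrs]
    # bridge moves: negative neighbor + its best positive neighbor outside
    bridge_gain <- rep(-Inf, length(nbrs)); bridge_partner <- rep(NA_character_, length(nbrs))
    for (i in seq_along(nbrs)) {
      v <- nbrs[i]
      if (scores[[v]] > 0) next
      cand <- setdiff(adj[[v]], c(inset, v))
      cand <- cand[scores[cand] > 0]
      if (!length(cand)) next
      w <- cand[order(-scores[cand], cand)][1L]
      bridge_gain[i] <- scores[[v]] + scores[[w]]
      bridge_partner[i] <- w
    }
    move_gain <- pmax(gains, bridge_gain)
    ord <- order(-move_gain, -scores[nbrs], nbrs)
    bi <- ord[1L]
    if (move_gain[bi] <= 1e-12) break
    if (bridge_gain[bi] > gains[bi])
      inset <- c(inset, nbrs[bi], bridge_partner[bi])
    else
      inset <- c(inset, nbrs[bi])
    total <- sum(scores[inset])
  }
  # prune: drop any negative node whose removal keeps the subgraph connected
  # (redundant bridges become removable once alternative paths join the set)
  repeat {
    if (length(inset) <= 1L) break
    neg <- inset[scores[inset] < 0]
    neg <- neg[order(scores[neg], neg)]
    dropped <- FALSE
    for (v in neg) {
      rest <- setdiff(inset, v)
      if (.connected_set(rest, adj)) { inset <- rest; dropped <- TRUE; break }
    }
    if (!dropped) break
  }
  list(nodes = inset, score = sum(scores[inset]))
}

# MST-based candidate: exact max-weight connected subtree of a score-driven
# minimum spanning tree (dynamic programming, bottom-up over a BFS order)
.mst_subtree <- function(net, scores) {
  if (!nrow(net@edges)) return(NULL)
  g <- igraph::graph_from_data_frame(net@edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = net@nodes$id)
  ends <- igraph::ends(g, igraph::E(g))
  igraph::E(g)$weight <- -(scores[ends[, 1]] + scores[ends[, 2]]) / 2
  tree <- igraph::mst(g)
  best <- NULL
  for (comp in igraph::decompose(tree)) {
    vs <- igraph::V(comp)$name
    if (length(vs) == 1L) {
      cand <- list(nodes = vs, score = unname(scores[vs]))
    } else {
      root <- vs[1L]
      ord <- igraph::bfs(comp, root = root, father = TRUE)
      order_v <- as.integer(ord$order)
      father <- as.integer(ord$father)
      nms <- igraph::V(comp)$name
      down <- scores[nms]               # best subtree hanging below each node
      incl <- lapply(nms, function(v) v)
      names(incl) <- nms
      for (vi in rev(order_v)) {        # children before parents
        fi <- father[vi]
        if (is.na(fi)) next
        if (down[[nms[vi]]] > 0) {
          down[[nms[fi]]] <- down[[nms[fi]]] + down[[nms[vi]]]
          incl[[nms[fi]]] <- c(incl[[nms[fi]]], incl[[nms[vi]]])
        }
      }
      top <- names(down)[order(-unlist(down), names(down))][1L]
      cand <- list(nodes = unname(incl[[top]]), score = unname(down[[top]]))
    }
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

# negative nodes adjacent to >= 2 positive nodes, cheapest first
.bridge_hubs <- function(adj, scores) {
  neg <- names(scores)[scores < 0]
  npos <- vapply(neg, function(v) sum(scores[adj[[v]]] > 0), 0L)
  hubs <- neg[npos >= 2L]
  hubs[order(-scores[hubs], hubs)]
}

# Cluster-merge candidate: contract connected clusters of positive nodes to
# supernodes, link them by cheapest negative-connector paths, pick the best
# supernode subtree (DP on the metagraph MST), then expand back to nodes.
.cluster_merge <- function(net, scores) {
  if (!nrow(net@edges)) return(NULL)
  g <- igraph::simplify(igraph::graph_from_data_frame(
    net@edges[, c("source", "target")], directed = FALSE,
    vertices = net@nodes$id))
  ids <- net@nodes$id
  pos <- ids[scores[ids] > 0]
  if (!length(pos)) return(NULL)
  sub_pos <- igraph::induced_subgraph(g, pos)
  comp <- igraph::components(sub_pos)
  clusters <- split(igraph::V(sub_pos)$name, comp$membership)
  cl_w <- vapply(clusters, function(cl) sum(scores[cl]), 0)
  if (length(clusters) == 1L)
    return(list(nodes = clusters[[1L]], score = unname(cl_w[1L])))
  # node-cost shortest paths: each negative node on a path costs -score
  ends <- igraph::ends(g, igraph::E(g))
  ncost <- function(v) ifelse(scores[v] < 0, -scores[v], 0)
  ew <- (ncost(ends[, 1]) + ncost(ends[, 2])) / 2
  D <- igraph::distances(g, weights = ew)
  k <- length(clusters)
  # cheapest inter-cluster connector (cost and representative endpoint pair)
  cost <- matrix(Inf, k, k); from <- matrix("", k, k); to <- matrix("", k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    block <- D[clusters[[i]], clusters[[j]], drop = FALSE]
    mi <- which(block == min(block), arr.ind = TRUE)[1L, ]
    cost[i, j] <- cost[j, i] <- min(block)
    from[i, j] <- to[j, i] <- clusters[[i]][mi[1L]]
    to[i, j] <- from[j, i] <- clusters[[j]][mi[2L]]
  }
  meta_pairs <- which(upper.tri(cost) & is.finite(cost), arr.ind = TRUE)
  if (!nrow(meta_pairs))
    return(list(nodes = clusters[[which.max(cl_w)]],
                score = unname(max(cl_w))))
  meta <- igraph::graph_from_data_frame(
    data.frame(from = as.character(meta_pairs[, 1]),
               to = as.character(meta_pairs[, 2])),
    directed = FALSE, vertices = as.character(seq_len(k)))
  igraph::E(meta)$weight <- cost[meta_pairs]
  mtree <- igraph::mst(meta)
  # DP over each metatree component: keep a child branch if its best subtree
  # outweighs the connector cost
  best <- NULL
  for (tcomp in igraph::decompose(mtree)) {
    vs <- igraph::V(tcomp)$name
    down <- setNames(cl_w[as.integer(vs)], vs)
    incl <- setNames(lapply(vs, identity), vs)
    if (length(vs) > 1L) {
      ord <- igraph::bfs(tcomp, root = 1, father = TRUE)
      order_v <- as.integer(ord$order); father <- as.integer(ord$father)
      nms <- igraph::V(tcomp)$name
      for (vi in rev(order_v)) {
        fi <- father[vi]
        if (is.na(fi)) next
        eid <- igraph::get_edge_ids(tcomp, c(fi, vi))
        gain <- down[[nms[vi]]] - igraph::E(tcomp)$weight[eid]
        if (gain > 0) {
          down[[nms[fi]]] <- down[[nms[fi]]] + gain
          incl[[nms[fi]]] <- c(incl[[nms[fi]]], incl[[nms[vi]]])
        }
      }
    }
    top <- names(down)[order(-unlist(down), names(down))][1L]
    chosen <- as.integer(incl[[top]])
    # expand supernodes + connector paths back to concrete nodes
    nodeset <- unlist(clusters[chosen], use.names = FALSE)
    if (length(chosen) > 1L) {
      sub <- igraph::induced_subgraph(mtree, as.character(chosen))
      sends <- igraph::ends(sub, igraph::E(sub))
      for (r in seq_len(nrow(sends))) {
        i <- as.integer(sends[r, 1]); j <- as.integer(sends[r, 2])
        sp <- igraph::shortest_paths(g, from = from[i, j], to = to[i, j],
                                     weights = ew)$vpath[[1L]]
        nodeset <- c(nodeset, names(sp))
      }
    }
    nodeset <- unique(nodeset)
    cand <- list(nodes = nodeset, score = sum(scores[nodeset]))
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

# BFS connectivity of a node set under the adjacency list
.connected_set <- function(set, adj) {
  if (length(set) <= 1L) return(TRUE)
  seen <- set[1L]
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(intersect(unique(unlist(adj[frontier], use.names = FALSE)), set),
                   seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(set)
}

.subnet_result <- function(net, node_ids, scores) {
  nodes <- net@nodes[net@nodes$id %in% node_ids, , drop = FALSE]
  nodes$score <- scores[nodes$id]
  ed <- net@edges
  keep <- ed$source %in% node_ids & ed$target %in% node_ids
  sub <- WeightedNetwork(nodes, ed[keep, , drop = FALSE],
                         threshold = net@threshold)
  list(nodes = sort(unname(node_ids)), score = sum(scores[node_ids]),
       network = sub)
}
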