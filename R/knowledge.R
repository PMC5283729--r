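#' Load a knowledge graph from node and edge tables
#'
#' Reads a property graph from two delimited files: nodes
#' (`id`, `node_type`, `name`) and edges (`source`, `target`,
#' `relation_type`, optional `attributes` JSON column). The graph is
#' validated against the relation schema (see [KnowledgeGraph-class]):
#' dangling endpoints and endpoint types a relation does not admit are
#' rejected with the offending edges listed.
#'
#' @param nodes_path,edges_path TSV/CSV file paths.
#' @param sep delimiter override.
#' @return a validated [KnowledgeGraph-class].
#' @export
loadGraph <- function(nodes_path, edges_path, sep = NULL) {
  nodes <- .read_delim(nodes_path, sep)
  edges <- .read_delim(edges_path, sep)
  knowledgeGraph(nodes, edges)
}

#' @rdname loadGraph
#' @param nodes,edges data.frames with the columns described above.
#' @export
knowledgeGraph <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"name" %in% colnames(nodes)) nodes$name <- nodes$id
  for (col in c("id", "node_type", "name")) nodes[[col]] <- as.character(nodes[[col]])
  if (!nrow(edges))
    edges <- data.frame(source = character(), target = character(),
                        relation_type = character(), stringsAsFactors = FALSE)
  for (col in intersect(c("source", "target", "relation_type"), colnames(edges)))
    edges[[col]] <- as.character(edges[[col]])
  new("KnowledgeGraph", nodes = nodes, edges = edges)
}

#' Write a knowledge graph back to node/edge tables
#'
#' @param g a [KnowledgeGraph-class]
#' @param nodes_path,edges_path output paths.
#' @param sep delimiter override.
#' @return invisibly, the two paths.
#' @export
writeGraph <- function(g, nodes_path, edges_path, sep = NULL) {
  stopifnot(is(g, "KnowledgeGraph"))
  .write_delim(g@nodes, nodes_path, sep)
  .write_delim(g@edges, edges_path, sep)
  invisible(c(nodes_path, edges_path))
}

#' Query a single-relation biological network around seed entities
#'
#' Returns the subgraph induced by edges of exactly one relation type that
#' lie within `steps` hops of any seed id (breadth-first over edges of that
#' type, ignoring direction). Nodes not reached are excluded.
#'
#' @param g a [KnowledgeGraph-class]
#' @param seeds character vector of node ids.
#' @param relation_type one relation type name.
#' @param steps traversal depth from the seeds, 1 (default) to 3.
#' @return a [WeightedNetwork-class]; knowledge edges carry weight 1 and
#'   `kind` = the relation type. Empty (with a warning) when no seed is in
#'   the graph or no edge matches.
#' @export
querySimpleNetwork <- function(g, seeds, relation_type, steps = 1) {
  stopifnot(is(g, "KnowledgeGraph"))
  .assert(relation_type %in% names(.kg_schema),
          "unknown relation_type '%s'", relation_type)
  queryHeterogeneousNetwork(g, seeds, relation_type, steps = steps)
}

#' Query a heterogeneous network over one or more relation types
#'
#' Union of single-relation queries: edges of any requested relation type
#' within `steps` hops of the seeds, deduplicated. Combining e.g.
#' CONVERSION and CATALYSIS links genes to the compounds their encoded
#' enzymes act on, with the enzymes as linking nodes. Node records keep
#' their `node_type` for downstream multi-type overrepresentation analysis.
#'
#' @inheritParams querySimpleNetwork
#' @param relation_types character vector of relation type names.
#' @return a [WeightedNetwork-class].
#' @export
queryHeterogeneousNetwork <- function(g, seeds, relation_types, steps = 1) {
  stopifnot(is(g, "KnowledgeGraph"))
  .assert(length(relation_types) >= 1, "at least one relation type required")
  bad <- setdiff(relation_types, names(.kg_schema))
  .assert(!length(bad), "unknown relation_type(s): %s", paste(bad, collapse = ", "))
  .assert(steps >= 1 && steps <= 3, "steps must be between 1 and 3")
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, g@nodes$id)
  ed <- g@edges[g@edges$relation_type %in% relation_types, , drop = FALSE]
  if (!length(present)) {
    warning("none of the seed ids are in the graph; returning an empty network")
    return(.empty_network())
  }
  frontier <- sort(present)
  reached <- frontier
  keep <- rep(FALSE, nrow(ed))
  for (s in seq_len(steps)) {
    touch <- (ed$source %in% frontier) | (ed$target %in% frontier)
    keep <- keep | touch
    nxt <- setdiff(unique(c(ed$source[touch], ed$target[touch])), reached)
    if (!length(nxt)) break
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  sub <- unique(ed[keep, , drop = FALSE])
  if (!nrow(sub)) {
    warning("no edges of the requested type(s) touch the seeds")
    return(.empty_network())
  }
  ids <- unique(c(sub$source, sub$target))
  nodes <- g@nodes[match(sort(ids), g@nodes$id), c("id", "node_type", "name")]
  edges <- data.frame(source = sub$source, target = sub$target,
                      weight = 1, kind = sub$relation_type,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target, edges$kind), , drop = FALSE]
  WeightedNetwork(nodes, edges)
}

.empty_network <- function() {
  WeightedNetwork(data.frame(id = character(), node_type = character(),
                             stringsAsFactors = FALSE))
}

#' Derive annotation sets from a knowledge graph
#'
#' One annotation set per pathway node, with members the ANNOTATION targets
#' of the requested entity type. Pathways annotating no entity of that type
#' are dropped.
#'
#' @param g a [KnowledgeGraph-class]
#' @param entity_type `"compound"`, `"gene"`, `"protein"` or `"microRNA"`.
#' @return named list of annotation sets (see [annotationSet()]).
#' @export
annotationSetsFromGraph <- function(g, entity_type = "compound") {
  stopifnot(is(g, "KnowledgeGraph"))
  .assert(entity_type %in% setdiff(.kg_node_types, "pathway"),
          "entity_type must be a non-pathway node type")
  ntype <- setNames(g@nodes$node_type, g@nodes$id)
  nname <- setNames(g@nodes$name, g@nodes$id)
  ann <- g@edges[g@edges$relation_type == "ANNOTATION", , drop = FALSE]
  ann <- ann[ntype[ann$target] == entity_type, , drop = FALSE]
  if (!nrow(ann)) return(list())
  sets <- lapply(split(ann$target, ann$source), unique)
  out <- lapply(names(sets), function(pw)
    annotationSet(pw, nname[[pw]], sets[[pw]], source = "pathway"))
  names(out) <- names(sets)
  out
}

#' Map entity identifiers through a two-column table
#'
#' Deterministic identifier conversion: each input id is replaced by its
#' mapped value(s). One-to-many mappings expand the output with a warning;
#' ids absent from the table are reported unmapped.
#'
#' @param ids character vector of input ids.
#' @param mapping data.frame whose first column is the input namespace and
#'   second the output namespace.
#' @return list with `mapped` (data.frame `from`, `to`) and `unmapped`
#'   (character vector).
#' @export
mapIdentifiers <- function(ids, mapping) {
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  .assert(ncol(mapping) >= 2, "mapping table needs two columns")
  from <- as.character(mapping[[1L]]); to <- as.character(mapping[[2L]])
  ids <- as.character(ids)
  hit <- from %in% ids
  mapped <- data.frame(from = from[hit], to = to[hit], stringsAsFactors = FALSE)
  mapped <- mapped[order(match(mapped$from, ids)), , drop = FALSE]
  rownames(mapped) <- NULL
  unmapped <- setdiff(ids, from)
  if (anyDuplicated(mapped$from))
    warning(sprintf("one-to-many mapping expanded for id(s): %s",
                    paste(unique(mapped$from[duplicated(mapped$from)]),
                          collapse = ", ")))
  list(mapped = mapped, unmapped = unmapped)
}
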