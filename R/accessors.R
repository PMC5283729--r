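#' Accessors for metabolokit objects
#'
#' Accessor generics for the core containers: the intensity matrix and
#' metadata tables of a [MetaboSet-class], and the node/edge tables of
#' [WeightedNetwork-class] and [KnowledgeGraph-class] objects.
#'
#' @param x the object
#' @param value replacement value
#' @return `intensities` returns the numeric feature-by-sample matrix;
#'   `sampleInfo` and `featureInfo` return plain `data.frame`s;
#'   `networkNodes`/`networkEdges` and `graphNodes`/`graphEdges` return the
#'   underlying node and edge tables.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("intensities<-", function(x, value) standardGeneric("intensities<-"))

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname accessors
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setMethod("intensities", "MetaboSet", function(x)
  SummarizedExperiment::assay(x, "intensity"))

#' @rdname accessors
#' @export
setReplaceMethod("intensities", "MetaboSet", function(x, value) {
  SummarizedExperiment::assay(x, "intensity") <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("sampleInfo", "MetaboSet", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
#' @export
setMethod("featureInfo", "MetaboSet", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname accessors
#' @export
setMethod("networkNodes", "WeightedNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("networkEdges", "WeightedNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("networkThreshold", "WeightedNetwork", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("graphNodes", "KnowledgeGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "KnowledgeGraph", function(x) x@edges)

#' Convert a WeightedNetwork to an igraph graph
#'
#' @param net a [WeightedNetwork-class]
#' @param directed logical; data-driven networks are undirected.
#' @return an [igraph][igraph::graph_from_data_frame] graph whose vertices
#'   carry the node attributes and edges the weight/kind attributes.
#' @export
asIgraph <- function(net, directed = FALSE) {
  stopifnot(is(net, "WeightedNetwork"))
  igraph::graph_from_data_frame(net@edges, directed = directed,
                                vertices = net@nodes)
}
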