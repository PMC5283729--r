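#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aov coef cor cov lm loess median na.omit optim p.adjust
#'   pchisq pf pnorm prcomp predict pt ptukey punif qf qnorm qt quantile
#'   rbinom rlnorm rnorm runif sd setNames uniroot var wilcox.test t.test
#'   kruskal.test friedman.test oneway.test anova ks.test rbeta phyper
#'   complete.cases aggregate terms
#' @importFrom utils combn head read.delim write.table
NULL

#' MetaboSet: an intensity dataset with sample and feature annotation
#'
#' `MetaboSet` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a single assay named `"intensity"` holding a feature-by-sample matrix
#' of measured abundances (non-negative on the raw scale; transformed or
#' scaled data may be negative). Column data carries the study metadata used
#' downstream: group factors, a subject identifier for paired designs, a
#' `batch` label, an integer `injection_order` and a `sample_type` column
#' with values `"biological"`, `"qc"` or `"blank"`.
#'
#' Structural invariants enforced at construction: unique, non-empty feature
#' and sample identifiers matching the matrix dimensions; a numeric intensity
#' assay; when present, `sample_type` restricted to the three recognised
#' values and `injection_order` unique within each batch. Content-level
#' checks (negative raw intensities, degenerate design factors) are reported
#' by [validateDataset()] rather than blocking construction, because
#' transformation and feature scaling legitimately produce negative values.
#'
#' @slot . inherits all slots from SummarizedExperiment.
#' @seealso [MetaboSet()], [validateDataset()], [readDataset()]
#' @export
setClass("MetaboSet", contains = "SummarizedExperiment")

.validate_metaboset <- function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    m <- SummarizedExperiment::assay(object, "intensity")
    if (!is.numeric(m)) msg <- c(msg, "intensity assay must be numeric")
  }
  fid <- rownames(object); sid <- colnames(object)
  if (is.null(fid) || anyNA(fid) || any(fid == ""))
    msg <- c(msg, "feature ids (rownames) must be present and non-empty")
  else if (anyDuplicated(fid))
    msg <- c(msg, sprintf("duplicated feature ids: %s",
                          paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    msg <- c(msg, "sample ids (colnames) must be present and non-empty")
  else if (anyDuplicated(sid))
    msg <- c(msg, sprintf("duplicated sample ids: %s",
                          paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if ("sample_type" %in% colnames(cd)) {
    bad <- setdiff(unique(as.character(cd$sample_type)),
                   c("biological", "qc", "blank"))
    if (length(bad))
      msg <- c(msg, sprintf("unknown sample_type value(s): %s",
                            paste(bad, collapse = ", ")))
  }
  if (all(c("injection_order", "batch") %in% colnames(cd))) {
    io <- cd$injection_order; b <- as.character(cd$batch)
    ok <- !is.na(io)
    if (any(ok) && anyDuplicated(data.frame(b = b[ok], io = io[ok])))
      msg <- c(msg, "injection_order must be unique within batch")
  }
  if (length(msg)) msg else TRUE
}

setValidity("MetaboSet", .validate_metaboset)

#' Construct a MetaboSet
#'
#' @param intensities numeric feature-by-sample matrix with rownames
#'   (feature ids) and colnames (sample ids). Missing values allowed.
#' @param sample_meta `data.frame` (or DataFrame) of per-sample metadata,
#'   one row per sample, in column order of `intensities`. Recognised
#'   columns: group factors (any name), `subject`, `batch`,
#'   `injection_order`, `sample_type`.
#' @param feature_meta `data.frame` of per-feature annotation (external ids,
#'   optional fingerprint strings), one row per feature.
#' @return a validated [MetaboSet-class] object.
#' @examples
#' m <- matrix(rlnorm(12), 3, 4,
#'             dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' ms <- MetaboSet(m, data.frame(group = c("a", "a", "b", "b")))
#' dim(ms)
#' @export
MetaboSet <- function(intensities, sample_meta = NULL, feature_meta = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(sample_meta))
    sample_meta <- S4Vectors::DataFrame(row.names = colnames(intensities))
  else {
    sample_meta <- S4Vectors::DataFrame(sample_meta)
    rownames(sample_meta) <- colnames(intensities)
  }
  if (is.null(feature_meta))
    feature_meta <- S4Vectors::DataFrame(row.names = rownames(intensities))
  else {
    feature_meta <- S4Vectors::DataFrame(feature_meta)
    rownames(feature_meta) <- rownames(intensities)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    colData = sample_meta, rowData = feature_meta)
  new("MetaboSet", se)
}

#' @describeIn MetaboSet show a compact summary.
#' @param object a MetaboSet
#' @export
setMethod("show", "MetaboSet", function(object) {
  m <- intensities(object)
  cat(sprintf("MetaboSet: %d features x %d samples\n", nrow(m), ncol(m)))
  cd <- SummarizedExperiment::colData(object)
  if (ncol(cd)) cat("sample metadata:", paste(colnames(cd), collapse = ", "), "\n")
  if ("sample_type" %in% colnames(cd)) {
    tb <- table(cd$sample_type)
    cat("sample types:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  nmiss <- sum(is.na(m))
  if (nmiss) cat(sprintf("missing values: %d (%.1f%%)\n", nmiss, 100 * nmiss / length(m)))
  invisible(NULL)
})

#' Weighted, typed molecular network
#'
#' Container for the network objects produced by both knowledge-graph
#' queries and data-driven construction. Nodes carry an id, a `node_type`
#' and optionally a per-node p-value or score; edges carry a signed weight
#' and a `kind` recording how the edge was derived (`pearson`, `spearman`,
#' `kendall`, `partial`, `tanimoto`, or a knowledge relation type). The
#' `threshold` slot records the cutoff applied to |weight| at construction.
#'
#' Data-driven networks are undirected with no self-edges, and correlation or
#' Tanimoto weights satisfy |w| <= 1.
#'
#' @slot nodes data.frame with columns `id`, `node_type` and optional extras.
#' @slot edges data.frame with columns `source`, `target`, `weight`, `kind`.
#' @slot threshold numeric scalar, the |weight| cutoff used (NA if none).
#' @export
setClass("WeightedNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        threshold = "numeric"))

.data_driven_kinds <- c("pearson", "spearman", "kendall", "partial", "tanimoto")

setValidity("WeightedNetwork", function(object) {
  msg <- character()
  nd <- object@nodes; ed <- object@edges
  if (!all(c("id", "node_type") %in% colnames(nd)))
    msg <- c(msg, "nodes need columns id, node_type")
  if (!all(c("source", "target", "weight", "kind") %in% colnames(ed)))
    msg <- c(msg, "edges need columns source, target, weight, kind")
  if (!length(msg) && nrow(ed)) {
    dangling <- setdiff(c(ed$source, ed$target), nd$id)
    if (length(dangling))
      msg <- c(msg, sprintf("edge endpoints not in node set: %s",
                            paste(head(dangling, 5), collapse = ", ")))
    dd <- ed$kind %in% .data_driven_kinds
    if (any(dd & ed$source == ed$target))
      msg <- c(msg, "self-edges not allowed in data-driven networks")
    corlike <- ed$kind %in% .data_driven_kinds
    w <- ed$weight[corlike]
    if (length(w) && any(abs(w) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "correlation/tanimoto edge weights must satisfy |w| <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WeightedNetwork
#'
#' @param nodes data.frame with at least `id`; a `node_type` column is added
#'   (default `"compound"`) when absent.
#' @param edges data.frame with `source`, `target`, `weight`, `kind`;
#'   defaults to an empty edge list.
#' @param threshold numeric, the |weight| cutoff recorded with the network.
#' @return a [WeightedNetwork-class] object.
#' @export
WeightedNetwork <- function(nodes, edges = NULL, threshold = NA_real_) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"node_type" %in% colnames(nodes)) nodes$node_type <- "compound"
  nodes$id <- as.character(nodes$id)
  if (is.null(edges) || !nrow(as.data.frame(edges)))
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), kind = character(),
                        stringsAsFactors = FALSE)
  else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("WeightedNetwork", nodes = nodes, edges = edges,
      threshold = as.numeric(threshold))
}

#' @describeIn WeightedNetwork compact summary.
#' @param object a WeightedNetwork
#' @export
setMethod("show", "WeightedNetwork", function(object) {
  cat(sprintf("WeightedNetwork: %d nodes, %d edges", nrow(object@nodes),
              nrow(object@edges)))
  if (!is.na(object@threshold))
    cat(sprintf(" (|weight| > %g)", object@threshold))
  cat("\n")
  if (nrow(object@edges)) {
    tb <- table(object@edges$kind)
    cat("edge kinds:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Property-graph knowledge base held in memory
#'
#' A typed biological knowledge graph loaded from flat node/edge TSV files.
#' Node types: gene, protein, compound, microRNA, pathway. Relation types and
#' the endpoint types they admit (source -> target):
#' \itemize{
#'   \item BIOCHEMICAL_REACTION: compound -> compound (substrate-product)
#'   \item CATALYSIS: protein -> compound (enzyme catalysis)
#'   \item MOLECULAR_BINDING: protein -> protein
#'   \item CONVERSION: gene -> protein (gene encodes protein)
#'   \item CONTROL: protein -> gene or microRNA -> gene (regulation)
#'   \item GENETIC_ASSOCIATION: gene -> gene
#'   \item ANNOTATION: pathway -> gene/protein/compound/microRNA
#' }
#'
#' @slot nodes data.frame with columns `id`, `node_type`, `name`.
#' @slot edges data.frame with columns `source`, `target`, `relation_type`
#'   and optional `attributes` (JSON string).
#' @seealso [loadGraph()], [querySimpleNetwork()]
#' @export
setClass("KnowledgeGraph",
         representation(nodes = "data.frame", edges = "data.frame"))

.kg_node_types <- c("gene", "protein", "compound", "microRNA", "pathway")
.kg_schema <- list(
  BIOCHEMICAL_REACTION = list(source = "compound", target = "compound"),
  CATALYSIS            = list(source = "protein",  target = "compound"),
  MOLECULAR_BINDING    = list(source = "protein",  target = "protein"),
  CONVERSION           = list(source = "gene",     target = "protein"),
  CONTROL              = list(source = c("protein", "microRNA"), target = "gene"),
  GENETIC_ASSOCIATION  = list(source = "gene",     target = "gene"),
  ANNOTATION           = list(source = "pathway",
                              target = c("gene", "protein", "compound", "microRNA")))

setValidity("KnowledgeGraph", function(object) {
  msg <- .kg_violations(object@nodes, object@edges)
  if (length(msg)) msg else TRUE
})

.kg_violations <- function(nodes, edges) {
  msg <- character()
  if (!all(c("id", "node_type", "name") %in% colnames(nodes)))
    return("nodes need columns id, node_type, name")
  if (!all(c("source", "target", "relation_type") %in% colnames(edges)))
    return("edges need columns source, target, relation_type")
  if (anyDuplicated(nodes$id))
    msg <- c(msg, sprintf("duplicated node ids: %s",
                          paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")))
  badt <- setdiff(unique(nodes$node_type), .kg_node_types)
  if (length(badt))
    msg <- c(msg, sprintf("unknown node_type(s): %s", paste(badt, collapse = ", ")))
  if (nrow(edges)) {
    dang <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(dang))
      msg <- c(msg, sprintf("edges reference unknown node(s): %s",
                            paste(head(dang, 10), collapse = ", ")))
    badr <- setdiff(unique(edges$relation_type), names(.kg_schema))
    if (length(badr))
      msg <- c(msg, sprintf("unknown relation_type(s): %s", paste(badr, collapse = ", ")))
    if (!length(dang) && !length(badr)) {
      ntype <- setNames(nodes$node_type, nodes$id)
      for (i in seq_len(nrow(edges))) {
        rel <- edges$relation_type[i]
        rule <- .kg_schema[[rel]]
        st <- ntype[[edges$source[i]]]; tt <- ntype[[edges$target[i]]]
        if (!(st %in% rule$source) || !(tt %in% rule$target))
          msg <- c(msg, sprintf(
            "edge %s -> %s: %s does not admit %s -> %s",
            edges$source[i], edges$target[i], rel, st, tt))
      }
    }
  }
  msg
}

#' @describeIn KnowledgeGraph compact summary.
#' @param object a KnowledgeGraph
#' @export
setMethod("show", "KnowledgeGraph", function(object) {
  cat(sprintf("KnowledgeGraph: %d nodes, %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
  tb <- table(object@nodes$node_type)
  cat("node types:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  if (nrow(object@edges)) {
    tb <- table(object@edges$relation_type)
    cat("relations:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Beta-uniform mixture fit of a p-value distribution
#'
#' Model: f(p) = lambda + (1 - lambda) * a * p^(a - 1) on (0, 1], a uniform
#' noise component plus a Beta(a, 1) signal component. `tau` is the p-value
#' threshold at which the estimated false discovery rate among calls equals
#' the `fdr` slot; node scores derived from the fit are positive exactly for
#' p < tau.
#'
#' @slot lambda mixing weight of the uniform component, in [0, 1].
#' @slot a beta shape parameter, in (0, 1).
#' @slot fdr FDR level used to derive `tau`.
#' @slot tau p-value threshold implied by the fit and `fdr`.
#' @slot loglik maximized log-likelihood.
#' @slot n number of p-values fitted.
#' @seealso [fitBum()], [scoreNodes()]
#' @export
setClass("BumFit", representation(lambda = "numeric", a = "numeric",
                                  fdr = "numeric", tau = "numeric",
                                  loglik = "numeric", n = "integer"))

setValidity("BumFit", function(object) {
  msg <- character()
  if (object@lambda < 0 || object@lambda > 1) msg <- c(msg, "lambda must be in [0,1]")
  if (object@a <= 0 || object@a >= 1) msg <- c(msg, "a must be in (0,1)")
  if (!is.na(object@tau) && (object@tau <= 0 || object@tau >= 1))
    msg <- c(msg, "tau must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn BumFit compact summary.
#' @param object a BumFit
#' @export
setMethod("show", "BumFit", function(object) {
  cat(sprintf("BumFit: lambda = %.4f, a = %.4f (n = %d, logL = %.2f)\n",
              object@lambda, object@a, object@n, object@loglik))
  cat(sprintf("FDR %.3g => p-value threshold tau = %.4g\n", object@fdr, object@tau))
  invisible(NULL)
})

#' Declarative study design
#'
#' Describes the experimental layout of a dataset so that the statistics
#' engine can pick appropriate hypothesis tests and post hoc procedures.
#' Seven designs are supported: `two_independent`, `two_paired`,
#' `multi_independent`, `multi_paired`, `twoway_independent`,
#' `twoway_paired`, `twoway_mixed`.
#'
#' @slot design one of the seven design names.
#' @slot factors names of the group-factor columns in the sample metadata
#'   (one factor for one-way designs, exactly two for two-way designs).
#' @slot subject sample-metadata column holding the subject id; required for
#'   paired and mixed designs, `NA` otherwise.
#' @slot within for two-way designs, which of `factors` vary within subject
#'   (both for `twoway_paired`, exactly one for `twoway_mixed`).
#' @seealso [designSpec()], [suggestMethods()], [testFeatures()]
#' @export
setClass("DesignSpec", representation(design = "character",
                                      factors = "character",
                                      subject = "character",
                                      within = "character"))

.design_names <- c("two_independent", "two_paired", "multi_independent",
                   "multi_paired", "twoway_independent", "twoway_paired",
                   "twoway_mixed")

setValidity("DesignSpec", function(object) {
  msg <- character()
  if (length(object@design) != 1L || !object@design %in% .design_names)
    msg <- c(msg, sprintf("design must be one of: %s",
                          paste(.design_names, collapse = ", ")))
  twoway <- grepl("^twoway", object@design)
  if (twoway && length(object@factors) != 2L)
    msg <- c(msg, "two-way designs require exactly 2 factors")
  if (!twoway && length(object@factors) != 1L)
    msg <- c(msg, "one-way designs require exactly 1 factor")
  paired <- object@design %in% c("two_paired", "multi_paired",
                                 "twoway_paired", "twoway_mixed")
  if (paired && (length(object@subject) != 1L || is.na(object@subject)))
    msg <- c(msg, "paired/mixed designs require a subject id column")
  if (object@design == "twoway_mixed" && length(object@within) != 1L)
    msg <- c(msg, "twoway_mixed requires exactly one within-subject factor")
  if (length(object@within) && !all(object@within %in% object@factors, na.rm = TRUE))
    msg <- c(msg, "within-subject factors must be among the design factors")
  if (length(msg)) msg else TRUE
})

#' Construct a DesignSpec
#'
#' @param design one of `"two_independent"`, `"two_paired"`,
#'   `"multi_independent"`, `"multi_paired"`, `"twoway_independent"`,
#'   `"twoway_paired"`, `"twoway_mixed"`.
#' @param factors character vector of factor column names (1 for one-way,
#'   2 for two-way designs).
#' @param subject subject-id column name, required for paired/mixed designs.
#' @param within for two-way designs, the subset of `factors` that varies
#'   within subjects. Defaults: both for `twoway_paired`, none for
#'   `twoway_independent`; must name exactly one factor for `twoway_mixed`.
#' @return a validated [DesignSpec-class].
#' @examples
#' designSpec("two_paired", factors = "tissue", subject = "patient")
#' @export
designSpec <- function(design, factors, subject = NA_character_,
                       within = character()) {
  design <- match.arg(design, .design_names)
  if (design == "twoway_paired" && !length(within)) within <- factors
  if (design %in% c("two_paired", "multi_paired")) within <- factors
  new("DesignSpec", design = design, factors = as.character(factors),
      subject = as.character(subject), within = as.character(within))
}

#' @describeIn DesignSpec compact summary.
#' @param object a DesignSpec
#' @export
setMethod("show", "DesignSpec", function(object) {
  cat(sprintf("DesignSpec: %s on factor(s) %s", object@design,
              paste(object@factors, collapse = " x ")))
  if (!is.na(object@subject)) cat(sprintf(", subject = %s", object@subject))
  cat("\n")
  invisible(NULL)
})
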