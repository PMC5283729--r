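#' Read an intensity table into a MetaboSet
#'
#' Reads a delimited feature-by-sample (or sample-by-feature) intensity table
#' together with sample metadata. The first column of the file must hold the
#' row identifiers. The delimiter is chosen from the file extension
#' (`.csv` = comma, otherwise tab) unless `sep` is given.
#'
#' With `orientation = "samples"` the file has one row per sample and the
#' study metadata (group factors, `subject`, `batch`, `injection_order`,
#' `sample_type`) live in named columns of the same file, listed in
#' `meta_cols`; every remaining column is a feature. With
#' `orientation = "features"` the file has one row per feature and one column
#' per sample, and sample metadata may be supplied as a separate table
#' (`sample_meta_path`, first column = sample id).
#'
#' Missing cells are kept missing — nothing is imputed here; downstream
#' statistics use per-feature complete cases. Setting `impute_min = TRUE`
#' replaces missing values with half the per-feature minimum (a conventional
#' detection-limit surrogate), off by default.
#'
#' @param path intensity table (CSV/TSV).
#' @param orientation `"samples"` (rows = samples) or `"features"`
#'   (rows = features, the conventional export layout).
#' @param meta_cols names of sample-metadata columns inside the table
#'   (only meaningful for `orientation = "samples"`).
#' @param sample_meta_path optional separate sample-metadata table for
#'   `orientation = "features"`.
#' @param sep field delimiter override.
#' @param impute_min logical, impute missing values with half the feature
#'   minimum (default `FALSE`).
#' @return a validated [MetaboSet-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(sample = c("s1", "s2", "s3", "s4"),
#'                  group = c("a", "a", "b", "b"),
#'                  f1 = c(1, 2, 3, 4), f2 = c(2, 4, 6, 8))
#' write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' d <- readDataset(tf, orientation = "samples", meta_cols = "group")
#' dim(d)
#' @export
readDataset <- function(path, orientation = c("samples", "features"),
                        meta_cols = character(), sample_meta_path = NULL,
                        sep = NULL, impute_min = FALSE) {
  orientation <- match.arg(orientation)
  tab <- .read_delim(path, sep)
  .assert(ncol(tab) >= 2, "table in '%s' needs an id column plus data columns", path)
  ids <- as.character(tab[[1L]])
  .assert(!anyNA(ids) && all(ids != ""), "empty id cell(s) in first column of '%s'", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicated ids in '%s': %s", path, paste(dup, collapse = ", ")),
         call. = FALSE)
  body <- tab[, -1L, drop = FALSE]

  if (orientation == "samples") {
    missing_meta <- setdiff(meta_cols, colnames(body))
    .assert(!length(missing_meta), "declared meta column(s) absent: %s",
            paste(missing_meta, collapse = ", "))
    meta <- body[, meta_cols, drop = FALSE]
    dat <- body[, setdiff(colnames(body), meta_cols), drop = FALSE]
    mat <- t(.numeric_matrix(dat, row_ids = ids, rows_are = "sample"))
    colnames(mat) <- ids
    sample_meta <- meta
  } else {
    mat <- .numeric_matrix(body, row_ids = ids, rows_are = "feature")
    rownames(mat) <- ids
    sample_meta <- NULL
    if (!is.null(sample_meta_path)) {
      sm <- .read_delim(sample_meta_path, sep)
      smids <- as.character(sm[[1L]])
      .assert(!anyDuplicated(smids), "duplicated sample ids in '%s'", sample_meta_path)
      missing <- setdiff(colnames(mat), smids)
      .assert(!length(missing), "sample metadata lacks sample(s): %s",
              paste(missing, collapse = ", "))
      sample_meta <- sm[match(colnames(mat), smids), -1L, drop = FALSE]
    }
  }
  if (impute_min) {
    for (i in seq_len(nrow(mat))) {
      miss <- is.na(mat[i, ])
      if (any(miss) && !all(miss)) mat[i, miss] <- min(mat[i, ], na.rm = TRUE) / 2
    }
  }
  MetaboSet(mat, sample_meta = sample_meta)
}

# coerce a data.frame of intensity cells to numeric, naming offenders
.numeric_matrix <- function(df, row_ids, rows_are) {
  out <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (is.numeric(col)) { out[, j] <- col; next }
    raw <- trimws(as.character(col))
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric intensity at %s '%s', column '%s': \"%s\"",
                   rows_are, row_ids[bad[1L]], colnames(df)[j], raw[bad[1L]]),
           call. = FALSE)
    out[, j] <- num
  }
  out
}

#' Validate a MetaboSet against content-level expectations
#'
#' Structural invariants (dimensions, unique ids) are already enforced by
#' the class; this reports content-level problems without throwing:
#' negative intensities on what should be a raw scale, features with no
#' observed values, degenerate design factors, missing columns a
#' [DesignSpec-class] requires.
#'
#' @param d a [MetaboSet-class]
#' @param design optional [DesignSpec-class] to check the metadata against.
#' @return a `data.frame` with columns `severity` (`"error"`/`"warning"`)
#'   and `message`; zero rows iff no problem was found.
#' @export
validateDataset <- function(d, design = NULL) {
  stopifnot(is(d, "MetaboSet"))
  sev <- character(); msg <- character()
  add <- function(s, m) { sev <<- c(sev, s); msg <<- c(msg, m) }
  m <- intensities(d)
  nneg <- sum(m < 0, na.rm = TRUE)
  if (nneg) add("warning", sprintf("%d negative intensity value(s) (expected nonnegative on the raw scale)", nneg))
  allmiss <- rownames(m)[rowSums(!is.na(m)) == 0L]
  if (length(allmiss))
    add("warning", sprintf("feature(s) with no observed values: %s",
                           paste(head(allmiss, 5), collapse = ", ")))
  si <- sampleInfo(d)
  if (!is.null(design)) {
    absent <- setdiff(design@factors, colnames(si))
    if (length(absent))
      add("error", sprintf("design factor(s) missing from sample metadata: %s",
                           paste(absent, collapse = ", ")))
    for (f in intersect(design@factors, colnames(si))) {
      nlev <- length(unique(na.omit(si[[f]])))
      if (nlev < 2L)
        add("warning", sprintf("factor '%s' has %d level(s); a group comparison needs at least 2", f, nlev))
      if (grepl("^two_", design@design) && nlev > 2L)
        add("warning", sprintf("factor '%s' has %d levels under a two-group design", f, nlev))
    }
    if (!is.na(design@subject) && !design@subject %in% colnames(si))
      add("error", sprintf("subject column '%s' missing from sample metadata", design@subject))
  }
  data.frame(severity = sev, message = msg, stringsAsFactors = FALSE)
}

#' Write an analysis table or network to a delimited text file
#'
#' All result objects are exported as plain tab- or comma-delimited text so
#' they can be consumed by other software. Tables round-trip through
#' [readStatsTable()] / [readNetwork()] field-for-field (ids exactly,
#' numerics to printed precision, ~15 significant digits).
#'
#' @param obj a `data.frame` (stats or enrichment table) or a
#'   [WeightedNetwork-class] (written as an edge list with columns
#'   `source`, `target`, `relation_type`, `weight`).
#' @param path output file; extension decides the delimiter unless `sep`
#'   is given.
#' @param sep delimiter override.
#' @param nodes_path for networks, optional companion node-attribute table.
#' @return the path, invisibly.
#' @export
setGeneric("writeTable", function(obj, path, sep = NULL, nodes_path = NULL)
  standardGeneric("writeTable"))

#' @rdname writeTable
#' @export
setMethod("writeTable", "data.frame", function(obj, path, sep = NULL, nodes_path = NULL) {
  .write_delim(obj, path, sep)
})

#' @rdname writeTable
#' @export
setMethod("writeTable", "WeightedNetwork", function(obj, path, sep = NULL, nodes_path = NULL) {
  ed <- obj@edges
  out <- data.frame(source = ed$source, target = ed$target,
                    relation_type = ed$kind, weight = ed$weight,
                    stringsAsFactors = FALSE)
  .write_delim(out, path, sep)
  if (!is.null(nodes_path)) .write_delim(obj@nodes, nodes_path, sep)
  invisible(path)
})

#' Read a per-entity statistics table
#'
#' Expected columns: `entity_id`, and any of `entity_type`, `statistic`,
#' `p`, `pFDR`, `log2FC`. Validates p-value ranges.
#'
#' @param path delimited file written by [writeTable()] or external software.
#' @param sep delimiter override.
#' @return a validated `data.frame`.
#' @export
readStatsTable <- function(path, sep = NULL) {
  df <- .read_delim(path, sep)
  .assert("entity_id" %in% colnames(df), "stats table needs an entity_id column")
  df$entity_id <- as.character(df$entity_id)
  for (col in intersect(c("p", "pFDR"), colnames(df))) {
    v <- df[[col]]
    .assert(all(is.na(v) | (v >= 0 & v <= 1)), "column '%s' outside [0,1]", col)
  }
  df
}

#' Read a network edge list (with optional node attributes)
#'
#' @param path edge list with columns `source`, `target`, `relation_type`
#'   (or `kind`), `weight`.
#' @param nodes_path optional node table with at least an `id` column.
#' @param sep delimiter override.
#' @param threshold recorded |weight| cutoff (not re-applied).
#' @return a [WeightedNetwork-class].
#' @export
readNetwork <- function(path, nodes_path = NULL, sep = NULL, threshold = NA_real_) {
  ed <- .read_delim(path, sep)
  if ("relation_type" %in% colnames(ed) && !"kind" %in% colnames(ed))
    names(ed)[names(ed) == "relation_type"] <- "kind"
  need <- c("source", "target", "weight", "kind")
  .assert(all(need %in% colnames(ed)), "edge list needs columns %s",
          paste(need, collapse = ", "))
  if (!is.null(nodes_path)) nodes <- .read_delim(nodes_path, sep)
  else {
    ids <- unique(c(as.character(ed$source), as.character(ed$target)))
    nodes <- data.frame(id = ids, node_type = "compound", stringsAsFactors = FALSE)
  }
  WeightedNetwork(nodes, ed, threshold = threshold)
}

#' Annotation sets: construction and GMT I/O
#'
#' An annotation set maps a term (pathway, MeSH heading or custom category)
#' to its member entity ids; a list of them is the unit of
#' overrepresentation analysis and functional class scoring. The plain-text
#' GMT format (one term per line: id, description, then members) is used for
#' interchange.
#'
#' @param term_id,term_name term identifier and display name.
#' @param members character vector of member entity ids (deduplicated;
#'   must be nonempty).
#' @param source one of `"pathway"`, `"mesh"`, `"custom"`.
#' @return `annotationSet()` returns one set (a list with class
#'   `"AnnotationSet"`); `readGMT()` a named list of them; `writeGMT()` the
#'   path, invisibly.
#' @examples
#' s <- annotationSet("P1", "glycolysis", c("c1", "c2", "c3"))
#' s$members
#' @export
annotationSet <- function(term_id, term_name = term_id, members,
                          source = c("custom", "pathway", "mesh")) {
  source <- match.arg(source)
  members <- unique(as.character(members))
  .assert(length(members) > 0, "annotation set '%s' has no members", term_id)
  structure(list(term_id = as.character(term_id),
                 term_name = as.character(term_name),
                 source = source, members = members),
            class = "AnnotationSet")
}

#' @rdname annotationSet
#' @param path GMT file path.
#' @export
readGMT <- function(path, source = c("custom", "pathway", "mesh")) {
  source <- match.arg(source)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    .assert(length(f) >= 3, "GMT line with fewer than 3 fields: '%s'",
            substr(l, 1, 40))
    annotationSet(f[1L], f[2L], f[-(1:2)], source = source)
  })
  names(sets) <- vapply(sets, `[[`, "", "term_id")
  sets
}

#' @rdname annotationSet
#' @param sets a list of annotation sets.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$term_id, s$term_name, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
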