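#' Write a MetaboSet to a delimited text file
#'
#' Samples-as-rows layout: first column `sample_id`, then the sample
#' metadata columns, then one column per feature. The file round-trips
#' through [readDataset()] with `orientation = "samples"` and
#' `meta_cols` set to the metadata column names.
#'
#' @param d a [MetaboSet-class]
#' @param path output file.
#' @param sep delimiter override.
#' @return the path, invisibly.
#' @export
writeDataset <- function(d, path, sep = NULL) {
  stopifnot(is(d, "MetaboSet"))
  si <- sampleInfo(d)
  out <- cbind(data.frame(sample_id = colnames(intensities(d)),
                          stringsAsFactors = FALSE),
               si, as.data.frame(t(intensities(d))))
  .write_delim(out, path, sep)
}

#' Run a configuration-driven analysis pipeline
#'
#' Executes an ordered list of analysis stages described in a YAML file (or
#' an equivalent list): `process` (transformation, sample/feature
#' normalization, PCA report), `stats` (design-driven feature testing),
#' `network` (correlation, partial correlation, Tanimoto, or high-scoring
#' subnetwork) and `enrich` (FCS or ORA). Each stage writes its artifact as
#' a delimited text file into `out_dir` and passes its result to the next
#' stage; any stage can instead read its input from a file, so every stage
#' is runnable standalone. A pre-flight check verifies stage order and
#' input availability before any computation; a run log records parameters,
#' seeds and warnings. Given fixed seeds, re-running a config reproduces
#' identical artifacts.
#'
#' See the package vignette for the configuration keys of each stage.
#'
#' @param config path to a YAML config, or a list with elements `seed`
#'   (optional) and `stages` (list of stage blocks, each with a `stage`
#'   name).
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `out_dir` or the working directory.
#' @return list with `artifacts` (named paths), `log` (log file path) and
#'   `results` (in-memory stage results).
#' @export
runConfig <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .assert(is.list(cfg) && !is.null(cfg$stages), "config needs a 'stages' list")
  out_dir <- out_dir %||% cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  stages <- cfg$stages
  kinds <- vapply(stages, function(s) s$stage %||% "", "")
  .assert(all(kinds %in% c("process", "stats", "network", "enrich")),
          "unknown stage(s): %s",
          paste(setdiff(kinds, c("process", "stats", "network", "enrich")),
                collapse = ", "))
  stochastic <- any(vapply(stages, function(s)
    (s$stage %||% "") == "enrich" && (s$type %||% "fcs") == "fcs", TRUE))
  .assert(!stochastic || !is.null(seed),
          "config has a stochastic stage; a seed is required")

  # pre-flight: each stage's input must be produced earlier or given as a file
  have <- character()
  for (s in stages) {
    need <- switch(s$stage,
                   process = if (is.null(s$input)) "dataset" else character(),
                   stats = if (is.null(s$input)) "dataset" else character(),
                   network = switch(s$type %||% "corr",
                                    corr = , pcor = if (is.null(s$input)) "dataset" else character(),
                                    tanimoto = character(),
                                    subnet = c(if (is.null(s$input)) "network",
                                               if (is.null(s$stats_input)) "stats_table")),
                   enrich = c(if (is.null(s$stats_input)) "stats_table"))
    missing_kind <- setdiff(need, have)
    if (length(missing_kind))
      stop(sprintf("pre-flight: stage '%s' needs %s produced by an earlier stage or a file input",
                   s$stage, paste(missing_kind, collapse = " and ")), call. = FALSE)
    have <- c(have, switch(s$stage, process = "dataset", stats = "stats_table",
                           network = "network", enrich = "enrichment"))
  }

  log_path <- file.path(out_dir, "run.log")
  logcon <- file(log_path, open = "wt")
  on.exit(close(logcon), add = TRUE)
  logline <- function(fmt, ...)
    writeLines(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...),
               logcon)
  logline("metabolokit %s; seed = %s",
          as.character(utils::packageVersion("metabolokit")),
          if (is.null(seed)) "none" else seed)

  env <- new.env()
  artifacts <- list(); results <- list()
  for (i in seq_along(stages)) {
    s <- stages[[i]]
    logline("stage %d: %s (%s)", i, s$stage,
            paste(sprintf("%s=%s", names(s), vapply(s, function(v)
              paste(format(v), collapse = ","), "")), collapse = " "))
    res <- withCallingHandlers(
      .run_stage(s, env, out_dir, seed),
      warning = function(w) {
        logline("warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    artifacts <- c(artifacts, res$artifacts)
    results[[s$stage]] <- res$value
  }
  logline("done")
  list(artifacts = artifacts, log = log_path, results = results)
}

.stage_dataset <- function(s, env) {
  if (!is.null(s$input))
    readDataset(s$input, orientation = s$orientation %||% "samples",
                meta_cols = unlist(s$meta_cols %||% character()))
  else env$dataset
}

.run_stage <- function(s, env, out_dir, seed) {
  switch(s$stage,
    process = {
      d <- .stage_dataset(s, env)
      if (!is.null(s$transform) && s$transform != "none")
        d <- transformValues(d, s$transform, exponent = s$exponent %||% 0.5)
      spans <- NULL
      sn <- s$sample_norm %||% "none"
      if (sn == "qc_loess") {
        r <- qcLoessNormalize(d, degree = s$loess_degree %||% 2)
        d <- r$dataset; spans <- r$spans
      } else if (sn != "none")
        d <- normalizeSamples(d, sn, meta_col = s$meta_col,
                              reference_type = s$reference_type %||% "qc")
      fn <- s$feature_norm %||% "none"
      if (fn != "none") d <- scaleFeatures(d, fn)
      env$dataset <- d
      paths <- list(processed = file.path(out_dir, "processed.tsv"))
      writeDataset(d, paths$processed)
      if (!is.null(spans)) {
        paths$spans <- file.path(out_dir, "loess_spans.tsv")
        .write_delim(spans, paths$spans)
      }
      if (isTRUE(s$pca)) {
        m <- intensities(d)
        dd <- d[rowSums(is.na(m)) == 0L, ]
        pca <- pcaOverview(dd, n_components = s$n_components %||% 2)
        paths$pca <- file.path(out_dir, "pca_scores.tsv")
        .write_delim(data.frame(sample_id = rownames(pca$scores), pca$scores,
                                check.names = FALSE), paths$pca)
      }
      list(artifacts = paths, value = d)
    },
    stats = {
      d <- .stage_dataset(s, env)
      design <- designSpec(s$design, factors = unlist(s$factors),
                           subject = s$subject %||% NA_character_,
                           within = unlist(s$within %||% character()))
      res <- testFeatures(d, design, method = s$method)
      env$stats_table <- res$table
      paths <- list(stats = file.path(out_dir, "stats.tsv"))
      .write_delim(res$table, paths$stats)
      if (!is.null(res$post_hoc)) {
        paths$post_hoc <- file.path(out_dir, "post_hoc.tsv")
        .write_delim(res$post_hoc, paths$post_hoc)
      }
      list(artifacts = paths, value = res)
    },
    network = {
      type <- s$type %||% "corr"
      paths <- list()
      if (type %in% c("corr", "pcor")) {
        d <- .stage_dataset(s, env)
        net <- if (type == "corr")
          correlationNetwork(d, method = s$method %||% "pearson",
                             threshold = s$threshold %||% 0.7,
                             min_pairs = s$min_pairs %||% 5)
        else partialCorrelationNetwork(d, threshold = s$threshold %||% 0.2,
                                       shrinkage = s$shrinkage %||% "auto")
      } else if (type == "tanimoto") {
        fps <- readFingerprints(s$fingerprints, length = s$bits %||% 881)
        net <- tanimotoNetwork(fps, threshold = s$threshold %||% 0.7)
      } else {  # subnet
        base <- if (!is.null(s$input)) readNetwork(s$input) else env$network
        st <- if (!is.null(s$stats_input)) readStatsTable(s$stats_input)
              else env$stats_table
        fit <- fitBum(st$p[!is.na(st$p)], fdr = s$fdr %||% 0.05)
        sc <- scoreNodes(fit, setNames(st$p, st$entity_id),
                         node_ids = base@nodes$id)
        sub <- maxScoringSubnetwork(base, sc)
        net <- sub$network
        paths$subnet_nodes <- file.path(out_dir, "subnet_nodes.tsv")
        .write_delim(net@nodes, paths$subnet_nodes)
      }
      env$network <- net
      paths$network <- file.path(out_dir, "network_edges.tsv")
      writeTable(net, paths$network)
      list(artifacts = paths, value = net)
    },
    enrich = {
      st <- if (!is.null(s$stats_input)) readStatsTable(s$stats_input)
            else env$stats_table
      sets <- readGMT(s$gmt)
      type <- s$type %||% "fcs"
      res <- if (type == "fcs")
        fcsEnrich(st, sets, method = s$method %||% "reporter",
                  n_perm = s$n_perm %||% 1000, seed = seed)
      else {
        cut <- s$fdr %||% 0.05
        oraHypergeometric(st$entity_id[!is.na(st$pFDR) & st$pFDR < cut],
                          st$entity_id, sets)
      }
      paths <- list(enrichment = file.path(out_dir, "enrichment.tsv"))
      .write_delim(res, paths$enrichment)
      list(artifacts = paths, value = res)
    })
}
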