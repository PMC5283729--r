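#' Elementwise value transformation
#'
#' Applies a variance-stabilising transform to every intensity. Log methods
#' require strictly positive values; power raises each value to
#' `exponent` (> 0). Missing values stay missing; metadata are untouched.
#'
#' @param d a [MetaboSet-class]
#' @param method `"none"`, `"log2"`, `"log10"`, `"ln"` or `"power"`.
#' @param exponent positive exponent for `method = "power"` (default 0.5,
#'   the square root).
#' @return a transformed [MetaboSet-class].
#' @export
transformValues <- function(d, method = c("none", "log2", "log10", "ln", "power"),
                            exponent = 0.5) {
  stopifnot(is(d, "MetaboSet"))
  method <- match.arg(method)
  m <- intensities(d)
  if (method %in% c("log2", "log10", "ln")) {
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("nonpositive intensity under %s at feature '%s', sample '%s'",
                   method, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
           call. = FALSE)
  }
  m <- switch(method,
              none = m,
              log2 = log2(m),
              log10 = log10(m),
              ln = log(m),
              power = {
                .assert(is.numeric(exponent) && exponent > 0,
                        "power exponent must be > 0")
                m^exponent
              })
  intensities(d) <- m
  d
}

#' Sample-based normalization
#'
#' Removes between-sample systematic variation. Three schemes:
#' \describe{
#'   \item{sum}{divide each sample by its intensity total, then rescale by
#'     the median of all sample totals so values stay on the original scale.}
#'   \item{metadata}{divide each sample by a positive numeric sample-metadata
#'     value (e.g. dry mass), rescaled by the median of those values.}
#'   \item{batch_median}{divide each sample, feature-wise, by the per-batch
#'     median vector of a designated reference `sample_type`
#'     (default `"qc"`).}
#' }
#' Missing values are ignored in totals and medians and stay missing.
#'
#' @param d a [MetaboSet-class]
#' @param method `"sum"`, `"metadata"` or `"batch_median"`.
#' @param meta_col sample-metadata column for `method = "metadata"`.
#' @param reference_type `sample_type` defining the reference samples for
#'   `method = "batch_median"`.
#' @return the normalized [MetaboSet-class].
#' @export
normalizeSamples <- function(d, method = c("sum", "metadata", "batch_median"),
                             meta_col = NULL, reference_type = "qc") {
  stopifnot(is(d, "MetaboSet"))
  method <- match.arg(method)
  m <- intensities(d)
  si <- sampleInfo(d)
  if (method == "sum") {
    totals <- colSums(m, na.rm = TRUE)
    zero <- colnames(m)[totals == 0]
    .assert(!length(zero), "sample(s) with zero total intensity: %s",
            paste(zero, collapse = ", "))
    m <- sweep(m, 2L, totals, "/") * median(totals)
  } else if (method == "metadata") {
    .assert(!is.null(meta_col) && meta_col %in% colnames(si),
            "metadata normalization needs an existing sample-meta column")
    w <- as.numeric(si[[meta_col]])
    .assert(all(!is.na(w)) && all(w > 0),
            "metadata column '%s' must be positive numeric for all samples", meta_col)
    m <- sweep(m, 2L, w, "/") * median(w)
  } else {
    .assert("batch" %in% colnames(si), "batch_median requires a 'batch' column")
    .assert("sample_type" %in% colnames(si),
            "batch_median requires a 'sample_type' column")
    for (b in unique(as.character(si$batch))) {
      inb <- as.character(si$batch) == b
      ref <- inb & si$sample_type == reference_type
      .assert(any(ref), "no reference samples of type '%s' in batch '%s'",
              reference_type, b)
      med <- apply(m[, ref, drop = FALSE], 1L, median, na.rm = TRUE)
      .assert(all(is.na(med) | med != 0),
              "zero reference median for some feature in batch '%s'", b)
      m[, inb] <- m[, inb, drop = FALSE] / med
    }
  }
  intensities(d) <- m
  d
}

#' Feature-based scaling
#'
#' Per-feature centering and scaling to make variables comparable in total
#' variance, as used ahead of multivariate analysis:
#' auto = (x - mean)/sd, Pareto = (x - mean)/sqrt(sd),
#' range = (x - mean)/(max - min). The sd is the n-1 sample standard
#' deviation; a constant feature is set to 0 with a warning rather than
#' dividing by zero.
#'
#' @param d a [MetaboSet-class] with >= 2 non-missing values per feature.
#' @param method `"auto"`, `"pareto"` or `"range"`.
#' @return the scaled [MetaboSet-class].
#' @export
scaleFeatures <- function(d, method = c("auto", "pareto", "range")) {
  stopifnot(is(d, "MetaboSet"))
  method <- match.arg(method)
  m <- intensities(d)
  nobs <- rowSums(!is.na(m))
  .assert(all(nobs >= 2), "feature(s) with < 2 non-missing values: %s",
          paste(head(rownames(m)[nobs < 2], 5), collapse = ", "))
  ctr <- rowMeans(m, na.rm = TRUE)
  m <- m - ctr
  div <- switch(method,
                auto = apply(m, 1L, sd, na.rm = TRUE),
                pareto = sqrt(apply(m, 1L, sd, na.rm = TRUE)),
                range = apply(m, 1L, function(x) diff(range(x, na.rm = TRUE))))
  const <- div == 0 | is.na(div)
  if (any(const)) {
    warning(sprintf("constant feature(s) scaled to 0: %s",
                    paste(head(rownames(m)[const], 5), collapse = ", ")))
    div[const] <- 1  # centered values are already 0
  }
  intensities(d) <- m / div
  d
}

#' PCA overview of a dataset
#'
#' Principal components of the centered sample-by-feature matrix, for
#' detecting outliers and judging normalization choices. Missing values must
#' be resolved first (complete-case filtering or imputation).
#'
#' @param d a [MetaboSet-class] without missing values.
#' @param n_components number of components (default
#'   `min(dim)` capped at 10).
#' @param scale. logical, scale features to unit variance first.
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components) and `explained` (variance fractions, descending).
#' @export
pcaOverview <- function(d, n_components = NULL, scale. = FALSE) {
  stopifnot(is(d, "MetaboSet"))
  m <- intensities(d)
  if (anyNA(m))
    stop("PCA requires complete data: impute or drop features/samples with missing values",
         call. = FALSE)
  kmax <- min(dim(m), nrow(t(m)) - 1L)
  k <- min(n_components %||% min(10L, kmax), kmax)
  .assert(k >= 1, "n_components must be >= 1 and <= min(dim)")
  pc <- prcomp(t(m), center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       center = pc$center)
}
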