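#' QC-LOESS signal-drift and batch-effect correction
#'
#' Corrects within-batch instrument drift using repeated injections of a
#' pooled quality-control (QC) sample. Per feature and per batch, a locally
#' weighted polynomial regression (tricube weights) of QC intensity on
#' injection order is fitted; the smoothing span is selected from
#' `span_grid` by leave-one-out cross-validation on the QC samples
#' (minimum squared prediction error). Every sample's intensity is divided
#' by the fitted drift curve at its injection order and rescaled by the
#' batch QC median, keeping values on the original scale. Finally the
#' batches are aligned to a common QC median (batch-effect correction).
#'
#' Features whose QC values are missing (or too few to cross-validate) are
#' passed through unchanged with a warning. Spans whose fit fails or
#' predicts a nonpositive curve anywhere in the batch are excluded from the
#' grid; if no span survives, the feature falls back to a degree-1 fit at
#' span 1, and failing that is passed through.
#'
#' @param d a [MetaboSet-class] whose sample metadata has `injection_order`,
#'   `sample_type` (with QC rows) and optionally `batch` (single batch
#'   assumed when absent). At least 4 QC samples per batch.
#' @param span_grid candidate spans, each in (0, 1]; default
#'   `seq(0.3, 1, 0.1)`.
#' @param degree local polynomial degree, 1 or 2 (default 2).
#' @param qc_type the `sample_type` value marking QC samples.
#' @return a list with `dataset` (corrected [MetaboSet-class]) and `spans`
#'   (data.frame feature/batch/span; NA span = passed through).
#' @export
qcLoessNormalize <- function(d, span_grid = seq(0.3, 1, by = 0.1),
                             degree = 2, qc_type = "qc") {
  stopifnot(is(d, "MetaboSet"))
  .assert(all(span_grid > 0 & span_grid <= 1), "spans must lie in (0, 1]")
  .assert(degree %in% 1:2, "degree must be 1 or 2")
  si <- sampleInfo(d)
  .assert("injection_order" %in% colnames(si),
          "QC-LOESS requires an 'injection_order' sample-metadata column")
  .assert("sample_type" %in% colnames(si),
          "QC-LOESS requires a 'sample_type' sample-metadata column")
  batch <- if ("batch" %in% colnames(si)) as.character(si$batch)
           else rep("1", nrow(si))
  io <- as.numeric(si$injection_order)
  is_qc <- si$sample_type == qc_type
  for (b in unique(batch)) {
    nqc <- sum(is_qc & batch == b)
    .assert(nqc >= 4, "batch '%s' has %d QC samples; at least 4 required", b, nqc)
  }

  m <- intensities(d)
  out <- m
  batches <- unique(batch)
  spans <- expand.grid(feature = rownames(m), batch = batches,
                       stringsAsFactors = FALSE)
  spans$span <- NA_real_
  passed_through <- character()

  for (b in batches) {
    inb <- which(batch == b)
    qcb <- inb[is_qc[inb]]
    for (i in seq_len(nrow(m))) {
      y <- m[i, qcb]; x <- io[qcb]
      ok <- !is.na(y)
      if (sum(ok) < 4) { passed_through <- c(passed_through, rownames(m)[i]); next }
      fit <- .loess_drift_fit(x[ok], y[ok], span_grid, degree, io[inb])
      if (is.null(fit)) { passed_through <- c(passed_through, rownames(m)[i]); next }
      spans$span[spans$feature == rownames(m)[i] & spans$batch == b] <- fit$span
      out[i, inb] <- m[i, inb] / fit$curve * median(y[ok])
    }
  }
  # align batches to a common QC median, feature-wise
  if (length(batches) > 1L) {
    for (i in seq_len(nrow(out))) {
      qcall <- out[i, is_qc]
      grand <- median(qcall, na.rm = TRUE)
      if (is.na(grand) || grand == 0) next
      for (b in batches) {
        inb <- which(batch == b)
        bm <- median(out[i, inb[is_qc[inb]]], na.rm = TRUE)
        if (!is.na(bm) && bm != 0) out[i, inb] <- out[i, inb] / bm * grand
      }
    }
  }
  if (length(passed_through))
    warning(sprintf("feature(s) passed through uncorrected (insufficient QC values): %s",
                    paste(unique(passed_through), collapse = ", ")))
  intensities(d) <- out
  list(dataset = d, spans = spans)
}

# LOOCV span selection + final drift curve prediction at `at`
.loess_drift_fit <- function(x, y, span_grid, degree, at) {
  cv_err <- vapply(span_grid, function(s) {
    errs <- vapply(seq_along(x), function(j) {
      f <- .quiet_loess(x[-j], y[-j], s, degree)
      if (is.null(f)) return(NA_real_)
      p <- .quiet_predict(f, x[j])
      if (is.na(p)) NA_real_ else (p - y[j])^2
    }, 0)
    if (anyNA(errs)) Inf else sum(errs)
  }, 0)
  for (s in span_grid[order(cv_err)]) {
    if (!is.finite(cv_err[match(s, span_grid)])) break
    f <- .quiet_loess(x, y, s, degree)
    if (is.null(f)) next
    curve <- .quiet_predict(f, at)
    if (!anyNA(curve) && all(curve > 0)) return(list(span = s, curve = curve))
  }
  # degree-1 full-span fallback
  f <- .quiet_loess(x, y, 1, 1)
  if (!is.null(f)) {
    curve <- .quiet_predict(f, at)
    if (!anyNA(curve) && all(curve > 0)) return(list(span = 1, curve = curve))
  }
  NULL
}

.quiet_loess <- function(x, y, span, degree) {
  tryCatch(suppressWarnings(
    loess(y ~ x, span = span, degree = degree, family = "gaussian",
          control = stats::loess.control(surface = "direct"))),
    error = function(e) NULL)
}

.quiet_predict <- function(fit, at) {
  p <- tryCatch(suppressWarnings(predict(fit, data.frame(x = at))),
                error = function(e) rep(NA_real_, length(at)))
  as.numeric(p)
}
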