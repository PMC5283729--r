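#' Correlation network from an intensity dataset
#'
#' Pairwise feature-feature association network. Correlations use
#' pairwise-complete observations; a pair must share at least `min_pairs`
#' complete samples or its correlation is treated as undefined. An
#' undirected edge is created where |r| exceeds the threshold (both strong
#' positive and strong negative associations are kept); the signed
#' coefficient is the edge weight. Constant features have undefined
#' correlations and are excluded with a warning.
#'
#' @param d a [MetaboSet-class]
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @param threshold |r| cutoff (default 0.7).
#' @param min_pairs minimum complete sample pairs per feature pair
#'   (default 5).
#' @param node_type node type recorded on the nodes (default `"compound"`).
#' @return a [WeightedNetwork-class] whose nodes are the (non-constant)
#'   features.
#' @export
correlationNetwork <- function(d, method = c("pearson", "spearman", "kendall"),
                               threshold = 0.7, min_pairs = 5,
                               node_type = "compound") {
  stopifnot(is(d, "MetaboSet"))
  method <- match.arg(method)
  m <- intensities(d)
  .assert(nrow(m) >= 2, "need at least 2 features")
  sds <- apply(m, 1L, sd, na.rm = TRUE)
  const <- is.na(sds) | sds == 0
  if (any(const)) {
    warning(sprintf("constant feature(s) excluded (undefined correlation): %s",
                    paste(head(rownames(m)[const], 5), collapse = ", ")))
    m <- m[!const, , drop = FALSE]
  }
  x <- t(m)
  r <- suppressWarnings(cor(x, method = method, use = "pairwise.complete.obs"))
  npairs <- crossprod(!is.na(x))
  r[npairs < min_pairs] <- NA
  .matrix_to_network(r, rownames(m), threshold, kind = method, node_type)
}

.matrix_to_network <- function(r, ids, threshold, kind, node_type) {
  ut <- upper.tri(r)
  sel <- which(ut & !is.na(r) & abs(r) > threshold, arr.ind = TRUE)
  edges <- if (nrow(sel))
    data.frame(source = ids[sel[, 1L]], target = ids[sel[, 2L]],
               weight = r[sel], kind = kind, stringsAsFactors = FALSE)
  else NULL
  nodes <- data.frame(id = ids, node_type = node_type, stringsAsFactors = FALSE)
  WeightedNetwork(nodes, edges, threshold = threshold)
}

#' Shrinkage partial-correlation network
#'
#' Full-order partial correlations: the association of every feature pair
#' with the linear effects of all other features removed, obtained from the
#' inverse of the (regularized) correlation matrix. With more features than
#' samples the sample correlation matrix is singular; a shrinkage estimator
#' toward the identity with analytically chosen intensity (the
#' Ledoit-Wolf/Schafer-Strimmer rule) keeps the inversion well posed.
#'
#' @param d a [MetaboSet-class] with >= 3 features and >= 4 samples with
#'   complete data (rows with missing values are dropped).
#' @param threshold |partial correlation| cutoff for edges (default 0.2;
#'   partial correlations are typically much smaller than marginal ones).
#' @param shrinkage `"auto"` (analytic intensity), a number in \[0, 1\], or
#'   0 for no shrinkage (errors if the matrix is singular).
#' @param node_type node type recorded on the nodes.
#' @return a [WeightedNetwork-class] with `kind = "partial"` edges; the
#'   shrinkage intensity used is attached as attribute `"shrinkage"`.
#' @export
partialCorrelationNetwork <- function(d, threshold = 0.2, shrinkage = "auto",
                                      node_type = "compound") {
  stopifnot(is(d, "MetaboSet"))
  m <- intensities(d)
  .assert(nrow(m) >= 2, "need at least 2 features")
  x <- t(m)
  x <- x[complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  .assert(n >= 4, "need at least 4 complete samples")
  sds <- apply(x, 2L, sd)
  .assert(all(sds > 0), "constant feature(s): %s",
          paste(head(colnames(x)[sds == 0], 5), collapse = ", "))
  R <- cor(x)
  lambda <- if (identical(shrinkage, "auto")) .shrinkage_intensity(x)
            else as.numeric(shrinkage)
  .assert(lambda >= 0 && lambda <= 1, "shrinkage must lie in [0, 1]")
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  Om <- tryCatch(solve(Rs), error = function(e)
    stop("correlation matrix is singular; use shrinkage = \"auto\"", call. = FALSE))
  D <- sqrt(diag(Om))
  P <- -Om / tcrossprod(D)
  diag(P) <- 1
  net <- .matrix_to_network(P, colnames(x), threshold, kind = "partial", node_type)
  attr(net, "shrinkage") <- lambda
  net
}

# analytic shrinkage intensity toward the identity target:
# lambda* = sum Var(r_ij) / sum r_ij^2 over off-diagonal entries
.shrinkage_intensity <- function(x) {
  n <- nrow(x); p <- ncol(x)
  xs <- scale(x)                      # unit-variance columns
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) {
    wi <- xs[, i] * xs[, (i + 1):p, drop = FALSE]
    wbar <- colMeans(wi)
    vr <- n / (n - 1)^3 * colSums((wi - matrix(wbar, n, length(wbar),
                                               byrow = TRUE))^2)
    r <- (n / (n - 1)) * wbar
    num <- num + sum(vr)
    den <- den + sum(r^2)
  }
  if (den == 0) return(1)
  max(0, min(1, num / den))
}

#' Substructure fingerprints and Tanimoto similarity networks
#'
#' A fingerprint records which positions of a fixed-length binary
#' substructure space are set for a compound (881 positions by default, the
#' PubChem substructure key space). The Tanimoto coefficient of two
#' fingerprints is |intersection| / |union| of their set bits; compound
#' pairs with T above the threshold become network edges.
#'
#' @param id compound identifier.
#' @param positions integer vector of set bit positions, each in
#'   `[0, length)`.
#' @param length fingerprint bit length (default 881).
#' @return `fingerprint()`: a list with class `"Fingerprint"`;
#'   `readFingerprints()`: a named list of them.
#' @examples
#' a <- fingerprint("c1", c(1, 2, 3))
#' b <- fingerprint("c2", c(2, 3, 4))
#' tanimoto(a, b)  # 0.5
#' @export
fingerprint <- function(id, positions, length = 881) {
  positions <- sort(unique(as.integer(positions)))
  .assert(all(positions >= 0 & positions < length),
          "bit positions must lie in [0, %d)", length)
  structure(list(id = as.character(id), positions = positions,
                 length = as.integer(length)), class = "Fingerprint")
}

#' @rdname fingerprint
#' @param path TSV with columns `id` and `bits` (comma-separated set bit
#'   positions).
#' @param sep delimiter override.
#' @export
readFingerprints <- function(path, length = 881, sep = NULL) {
  df <- .read_delim(path, sep)
  .assert(all(c("id", "bits") %in% colnames(df)),
          "fingerprint table needs columns 'id' and 'bits'")
  fps <- lapply(seq_len(nrow(df)), function(i)
    fingerprint(df$id[i],
                as.integer(strsplit(as.character(df$bits[i]), ",")[[1L]]),
                length = length))
  names(fps) <- df$id
  fps
}

#' @rdname fingerprint
#' @param a,b fingerprints of equal bit length.
#' @export
tanimoto <- function(a, b) {
  .assert(a$length == b$length, "fingerprints must share the same bit length")
  inter <- length(intersect(a$positions, b$positions))
  uni <- length(union(a$positions, b$positions))
  if (uni == 0) return(NA_real_)
  inter / uni
}

#' @rdname fingerprint
#' @param fps list of fingerprints (equal bit length; all-zero fingerprints
#'   are excluded with a warning).
#' @param threshold similarity cutoff for edges (default 0.7).
#' @export
tanimotoNetwork <- function(fps, threshold = 0.7) {
  .assert(length(fps) >= 2, "need at least 2 fingerprints")
  lens <- vapply(fps, `[[`, 0L, "length")
  .assert(length(unique(lens)) == 1L, "fingerprints must share one bit length")
  empty <- vapply(fps, function(f) length(f$positions) == 0L, TRUE)
  if (any(empty)) {
    warning(sprintf("all-zero fingerprint(s) excluded: %s",
                    paste(vapply(fps[empty], `[[`, "", "id"), collapse = ", ")))
    fps <- fps[!empty]
  }
  .assert(length(fps) >= 2, "fewer than 2 usable fingerprints")
  ids <- vapply(fps, `[[`, "", "id")
  k <- length(fps)
  Tm <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    Tm[i, j] <- Tm[j, i] <- tanimoto(fps[[i]], fps[[j]])
  dimnames(Tm) <- list(ids, ids)
  .matrix_to_network(Tm, ids, threshold, kind = "tanimoto",
                     node_type = "compound")
}
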