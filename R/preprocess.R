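#' Filter microRNAs by detection
#'
#' Keeps mature microRNAs with more than two read counts in more than two
#' samples, i.e. at least 3 counts in at least 3 samples (strict reading of
#' the detection rule). Idempotent.
#'
#' @param counts An [omics_matrix()] of kind `"mirna"` holding raw counts.
#' @return The filtered `omics_matrix`, with `"detection_filter"` appended to
#'   its transform log.
#' @export
filter_detected_mirnas <- function(counts) {
  stopifnot(inherits(counts, "omics_matrix"))
  v <- counts$values
  if (min(v) < 0 || any(v != round(v))) {
    stop("detection filter expects non-negative integer counts", call. = FALSE)
  }
  keep <- rowSums(v > 2) > 2
  log_transform(subset_features(counts, keep), "detection_filter")
}

#' Upper-quartile normalization of miRNA counts
#'
#' Scales each sample so that its 75th percentile of non-zero counts equals
#' the geometric mean of the per-sample upper quartiles, then applies
#' log2(x + 1). Quantiles use the linear-interpolation (type 7) definition.
#' Invariant to per-sample positive rescaling of the input.
#'
#' @param counts A detection-filtered miRNA [omics_matrix()] of raw counts.
#' @return Normalized log2-scale `omics_matrix`.
#' @export
upper_quartile_normalize <- function(counts) {
  stopifnot(inherits(counts, "omics_matrix"))
  v <- counts$values
  uq <- apply(v, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) return(NA_real_)
    stats::quantile(nz, 0.75, names = FALSE, type = 7)
  })
  if (anyNA(uq)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(v)[is.na(uq)], collapse = ", "), call. = FALSE)
  }
  target <- exp(mean(log(uq)))
  scaled <- sweep(v, 2, target / uq, `*`)
  counts$values <- log2(scaled + 1)
  log_transform(counts, "upper_quartile_log2")
}

#' Select the most variant features
#'
#' Retains the `ceiling(fraction * F)` features with the largest sample
#' standard deviation; ties are broken by feature id in lexicographic order
#' so the selection is deterministic.
#'
#' @param matrix An [omics_matrix()].
#' @param fraction Fraction of features to keep, in (0, 1\].
#' @return The reduced `omics_matrix`.
#' @export
select_most_variant <- function(matrix, fraction) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  f <- nrow(matrix$values)
  if (f == 0) stop("empty matrix", call. = FALSE)
  n_keep <- ceiling(fraction * f)
  sds <- matrixStats::rowSds(matrix$values)
  ord <- order(-sds, rownames(matrix$values), method = "radix")
  keep <- sort(ord[seq_len(n_keep)])
  log_transform(subset_features(matrix, keep),
                sprintf("select_most_variant_%g", fraction))
}

#' Center features to zero mean
#'
#' Gene-wise (feature-wise) zero-centering without variance scaling, the
#' preprocessing applied before ICA and clustering.
#'
#' @param matrix An [omics_matrix()].
#' @return The centered `omics_matrix`.
#' @export
center_features <- function(matrix) {
  stopifnot(inherits(matrix, "omics_matrix"))
  matrix$values <- matrix$values - rowMeans(matrix$values)
  log_transform(matrix, "center_features")
}

#' Pearson distance between samples
#'
#' `d(i, j) = 1 - cor(column i, column j)`, the sample dissimilarity used by
#' the per-omics hierarchical consensus clustering. Symmetric, zero diagonal,
#' range \[0, 2\].
#'
#' @param matrix An [omics_matrix()] or a plain numeric feature-by-sample
#'   matrix.
#' @return A symmetric sample-by-sample dissimilarity matrix.
#' @export
pearson_distance <- function(matrix) {
  v <- if (inherits(matrix, "omics_matrix")) matrix$values else matrix
  sds <- matrixStats::colSds(v)
  if (any(sds == 0)) {
    stop("zero-variance sample column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  d
}
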