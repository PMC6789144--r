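#' Feature-by-sample omics matrix
#'
#' The central data container of the package: a numeric feature-by-sample
#' matrix together with the omics kind, optional per-feature genomic
#' annotation (including the 14q32 microRNA cluster flag) and an append-only
#' log of the preprocessing steps that have been applied.
#'
#' Orientation is fixed throughout the package: rows are features, columns
#' are samples. Values are log2 intensities for mRNA, raw or normalized
#' log2 counts for miRNA, and beta values in \[0, 1\] for methylation.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique non-empty rownames (feature ids) and colnames (sample ids) and no
#'   missing values.
#' @param omics_kind One of `"mrna"`, `"mirna"`, `"methylation"`.
#' @param feature_annotation Optional tibble/data.frame with a `feature_id`
#'   column and (typically) `chromosome`, `start`, `is_14q32` columns. Joined
#'   to the matrix rows by `feature_id`; features without a row get
#'   `is_14q32 = FALSE`.
#' @param transform_log Character vector of already-applied preprocessing
#'   step names (normally left empty; operations append to it).
#'
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `omics_kind`, `annotation` (tibble, one row per feature) and
#'   `transform_log`.
#' @export
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
#' omics_matrix(m, "methylation")
omics_matrix <- function(values, omics_kind = c("mrna", "mirna", "methylation"),
                         feature_annotation = NULL, transform_log = character()) {
  omics_kind <- match.arg(omics_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  x <- structure(
    list(values = values, omics_kind = omics_kind,
         annotation = .build_annotation(rownames(values), feature_annotation),
         transform_log = as.character(transform_log)),
    class = "omics_matrix"
  )
  validate_omics_matrix(x)
}

.build_annotation <- function(feature_ids, feature_annotation) {
  ann <- tibble::tibble(feature_id = feature_ids)
  if (is.null(feature_annotation)) {
    ann$chromosome <- NA_character_
    ann$start <- NA_real_
    ann$is_14q32 <- FALSE
    return(ann)
  }
  fa <- tibble::as_tibble(feature_annotation)
  if (!"feature_id" %in% names(fa)) {
    stop("feature annotation must have a `feature_id` column", call. = FALSE)
  }
  if (anyDuplicated(fa$feature_id)) {
    stop("feature annotation has duplicated feature_id entries", call. = FALSE)
  }
  for (col in c("chromosome", "start", "is_14q32")) {
    if (!col %in% names(fa)) fa[[col]] <- NA
  }
  fa$is_14q32 <- as.logical(fa$is_14q32) %in% TRUE
  ann <- dplyr::left_join(ann, fa[, c("feature_id", "chromosome", "start", "is_14q32")],
                          by = "feature_id")
  ann$is_14q32[is.na(ann$is_14q32)] <- FALSE
  ann$chromosome <- as.character(ann$chromosome)
  ann$start <- as.numeric(ann$start)
  ann
}

#' Validate an omics_matrix against its invariants
#'
#' Checks the container invariants: no missing values, unique feature and
#' sample ids, methylation beta values in \[0, 1\], raw miRNA counts
#' non-negative integers (only before normalization steps are logged).
#'
#' @param x An `omics_matrix`.
#' @return `x`, invisibly unchanged, or an error naming the violation.
#' @export
validate_omics_matrix <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  if (anyNA(v)) stop("omics matrix contains missing values", call. = FALSE)
  dup_f <- unique(rownames(v)[duplicated(rownames(v))])
  if (length(dup_f)) {
    stop("duplicated feature ids: ", paste(dup_f, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(v)[duplicated(colnames(v))])
  if (length(dup_s)) {
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (x$omics_kind == "methylation" && !length(x$transform_log) &&
      (min(v) < 0 || max(v) > 1)) {
    stop("methylation beta values must lie in [0, 1]", call. = FALSE)
  }
  if (x$omics_kind == "mirna" && !length(x$transform_log)) {
    if (min(v) < 0 || any(v != round(v))) {
      stop("raw miRNA counts must be non-negative integers", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d features x %d samples\n",
              x$omics_kind, nrow(x$values), ncol(x$values)))
  if (any(x$annotation$is_14q32)) {
    cat(sprintf("  14q32-flagged features: %d\n", sum(x$annotation$is_14q32)))
  }
  if (length(x$transform_log)) {
    cat("  transforms:", paste(x$transform_log, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids_of <- function(x) colnames(x$values)

# append a preprocessing step name; transform_log is append-only by construction
log_transform <- function(x, step) {
  x$transform_log <- c(x$transform_log, step)
  x
}

# subset features keeping annotation in sync
subset_features <- function(x, keep) {
  x$values <- x$values[keep, , drop = FALSE]
  x$annotation <- x$annotation[match(rownames(x$values), x$annotation$feature_id), ]
  x
}

#' Sample or consensus labels for one subtyping scheme
#'
#' A labelled partition of samples under a named scheme, e.g. `"mrna:E"`
#' (E1/E2 expression subtypes), `"mirna:Mir"` (Mir1-Mir4), `"methylation:M"`
#' (M1-M3), `"multiomics:C"` (C1/2, C3-C6) or `"mirna:14q32"`
#' (14q32_high / 14q32_low).
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param labels Vector (coerced to factor) of the same length.
#' @param scheme_name Scheme identifier string.
#' @return A `label_vector` object.
#' @export
label_vector <- function(sample_ids, labels, scheme_name = "unnamed") {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids in label vector", call. = FALSE)
  if (length(labels) != length(sample_ids)) {
    stop("labels and sample_ids differ in length", call. = FALSE)
  }
  structure(list(sample_ids = sample_ids, labels = as.factor(labels),
                 scheme_name = scheme_name),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("<label_vector> scheme %s, %d samples\n", x$scheme_name,
              length(x$sample_ids)))
  print(table(x$labels))
  invisible(x)
}

#' @export
length.label_vector <- function(x) length(x$sample_ids)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a label vector into a tibble
#'
#' @param x A `label_vector`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `label`, `scheme`.
#' @export
tidy.label_vector <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_ids, label = as.character(x$labels),
                 scheme = x$scheme_name)
}

#' Tidy an omics matrix into a long tibble
#'
#' @param x An `omics_matrix`.
#' @param ... Unused.
#' @return Long tibble with columns `feature_id`, `sample_id`, `value`.
#' @export
tidy.omics_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "value")
}
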