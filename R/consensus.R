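#' Feature-resampled hierarchical consensus clustering
#'
#' Clusters samples of one omics matrix in a resampling framework: the most
#' variant features are selected once, and in each iteration a random subset
#' of them is drawn (all samples are retained every iteration), samples are
#' clustered by Ward linkage on Pearson distance, and the tree is cut at
#' every k in `k_range`. The per-K co-classification matrix records the
#' frequency with which each sample pair lands in the same cluster.
#'
#' Consensus labels are obtained by complete-linkage clustering of
#' `1 - co-classification`, and the number of clusters is selected by the
#' cophenetic criterion (see [select_k_cophenetic()]).
#'
#' @param matrix A preprocessed (confound-filtered, centered)
#'   [omics_matrix()].
#' @param k_range Integer vector of cluster numbers, default `2:9`.
#' @param n_iterations Number of resampling iterations, default 1000.
#' @param variant_fraction Fraction of most-variant features forming the
#'   resampling pool (0.2 for mRNA/methylation, 0.5 for miRNA in the
#'   reference analysis).
#' @param feature_subsample Fraction of the pool drawn per iteration,
#'   default 0.8, without replacement.
#' @param seed Integer seed; the run is deterministic given the seed.
#' @return A `consensus_clustering` object: list with `coclassification`
#'   (named list of per-K symmetric matrices, unit diagonal),
#'   `labels` (named list of [label_vector()]s), `k_curve` (tibble `k`,
#'   `statistic`), `selected_k`, `k_range`, `n_iterations`, `seed`,
#'   `scheme_prefix`.
#' @export
run_consensus <- function(matrix, k_range = 2:9, n_iterations = 1000,
                          variant_fraction = 0.2, feature_subsample = 0.8,
                          seed = 1L) {
  stopifnot(inherits(matrix, "omics_matrix"))
  sel <- if (variant_fraction < 1) select_most_variant(matrix, variant_fraction) else matrix
  v <- sel$values
  f <- nrow(v)
  n <- ncol(v)
  n_draw <- ceiling(feature_subsample * f)
  if (n_draw < 3) stop("fewer than 3 features available for resampling", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  counts <- lapply(k_range, function(k) matrix(0L, n, n))
  names(counts) <- as.character(k_range)
  withr::local_seed(seed)
  for (it in seq_len(n_iterations)) {
    feats <- sample.int(f, n_draw)
    d <- pearson_distance(v[feats, , drop = FALSE])
    hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    for (ki in seq_along(k_range)) {
      cl <- stats::cutree(hc, k = k_range[ki])
      same <- outer(cl, cl, `==`)
      counts[[ki]] <- counts[[ki]] + same
    }
  }
  coclass <- lapply(counts, function(m) {
    m <- m / n_iterations
    diag(m) <- 1
    dimnames(m) <- list(colnames(v), colnames(v))
    m
  })
  .finish_consensus(coclass, k_range, n_iterations, seed,
                    scheme_prefix = matrix$omics_kind,
                    label_fun = consensus_labels,
                    stat_fun = cophenetic_coefficient,
                    select_fun = select_k_cophenetic,
                    statistic_name = "cophenetic")
}

.finish_consensus <- function(coclass, k_range, n_iterations, seed,
                              scheme_prefix, label_fun, stat_fun, select_fun,
                              statistic_name) {
  labels <- lapply(seq_along(k_range), function(ki) {
    label_fun(coclass[[ki]], k_range[ki])
  })
  names(labels) <- names(coclass)
  stat <- vapply(coclass, stat_fun, numeric(1))
  k_curve <- tibble::tibble(k = k_range, statistic = unname(stat))
  attr(k_curve, "statistic_name") <- statistic_name
  selected_k <- select_fun(k_curve)
  structure(list(coclassification = coclass, labels = labels,
                 k_curve = k_curve, selected_k = selected_k,
                 k_range = k_range, n_iterations = n_iterations,
                 seed = as.integer(seed), scheme_prefix = scheme_prefix,
                 statistic_name = statistic_name),
            class = "consensus_clustering")
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf("<consensus_clustering> %s, %d iterations, k in [%d, %d]\n",
              x$scheme_prefix, x$n_iterations, min(x$k_range), max(x$k_range)))
  cat(sprintf("  selected K = %d (%s criterion)\n", x$selected_k, x$statistic_name))
  invisible(x)
}

#' Consensus labels from a co-classification matrix
#'
#' Final partition at a given k: complete-linkage tree on
#' `D = 1 - coclassification`, cut into k groups. Class codes are renamed
#' deterministically by decreasing class size, ties by first sample
#' occurrence, so labels are comparable across runs.
#'
#' @param coclassification Symmetric co-classification matrix in \[0, 1\]
#'   with unit diagonal and sample ids as dimnames.
#' @param k Number of clusters.
#' @param scheme_name Scheme label for the returned [label_vector()].
#' @return A [label_vector()] with classes `"1"`, `"2"`, ... by size.
#' @export
consensus_labels <- function(coclassification, k, scheme_name = "consensus") {
  n <- nrow(coclassification)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (k == 1) {
    return(label_vector(colnames(coclassification), rep("1", n), scheme_name))
  }
  hc <- stats::hclust(stats::as.dist(1 - coclassification), method = "complete")
  cl <- stats::cutree(hc, k = k)
  label_vector(colnames(coclassification), rename_by_size(cl), scheme_name)
}

# deterministic class renaming: decreasing size, ties by first occurrence
rename_by_size <- function(cl) {
  tab <- table(cl)
  first <- vapply(names(tab), function(g) match(g, as.character(cl)), integer(1))
  ord <- order(-as.integer(tab), first)
  map <- stats::setNames(seq_along(ord), names(tab)[ord])
  factor(map[as.character(cl)], levels = seq_along(ord))
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Builds the complete-linkage tree on `D = 1 - coclassification` and returns
#' the Pearson correlation between the tree's cophenetic distances (the
#' dendrogram height at which two samples' branches merge) and D itself,
#' over all sample pairs. Measures how faithfully a tree represents the
#' consensus: ultrametric consensus gives exactly 1.
#'
#' @param coclassification Symmetric co-classification matrix, unit diagonal.
#' @return The coefficient in \[-1, 1\]; `NaN` with a warning when D is
#'   constant (all samples identical).
#' @export
cophenetic_coefficient <- function(coclassification) {
  d <- stats::as.dist(1 - coclassification)
  if (stats::sd(d) == 0) {
    warning("constant consensus distances; cophenetic coefficient undefined")
    return(NaN)
  }
  hc <- stats::hclust(d, method = "complete")
  stats::cor(as.vector(stats::cophenetic(hc)), as.vector(d))
}

#' Select K by the cophenetic criterion
#'
#' Returns the K immediately preceding the largest decrease
#' `c(k) - c(k + 1)` of the cophenetic correlation coefficient; ties go to
#' the smaller K. A non-decreasing curve returns the largest K with a
#' warning.
#'
#' @param k_curve Data frame with columns `k` and `statistic` (the per-K
#'   cophenetic coefficients).
#' @return Integer selected K.
#' @export
select_k_cophenetic <- function(k_curve) {
  if (nrow(k_curve) < 2) return(as.integer(k_curve$k[1]))
  drops <- -diff(k_curve$statistic)
  if (max(drops) <= 0) {
    warning("cophenetic curve never decreases; returning max K")
    return(as.integer(max(k_curve$k)))
  }
  # ties (within numerical tolerance) resolve toward the smaller K
  as.integer(k_curve$k[which(drops >= max(drops) - 1e-9)[1]])
}

#' Tidy a consensus clustering
#'
#' @param x A `consensus_clustering`.
#' @param k Which K's labels to return; default the selected K.
#' @param ... Unused.
#' @return Tibble `sample_id`, `label`, `scheme`, `k`.
#' @export
tidy.consensus_clustering <- function(x, k = x$selected_k, ...) {
  out <- tidy(x$labels[[as.character(k)]])
  out$k <- as.integer(k)
  out$scheme <- paste0(x$scheme_prefix, ":k", k)
  out
}

#' One-line summary of a consensus clustering
#'
#' @param x A `consensus_clustering`.
#' @param ... Unused.
#' @return One-row tibble: `selected_k`, `statistic_at_k`, `n_iterations`,
#'   `criterion`, `seed`.
#' @export
glance.consensus_clustering <- function(x, ...) {
  tibble::tibble(
    selected_k = x$selected_k,
    statistic_at_k = x$k_curve$statistic[match(x$selected_k, x$k_curve$k)],
    n_iterations = x$n_iterations,
    criterion = x$statistic_name,
    seed = x$seed
  )
}

#' Plot the K-selection curve
#'
#' @param object A `consensus_clustering`.
#' @param ... Unused.
#' @return A ggplot: the selection statistic against K, with the selected K
#'   highlighted.
#' @export
autoplot.consensus_clustering <- function(object, ...) {
  df <- object$k_curve
  sel <- df[df$k == object$selected_k, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = sel, colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "number of clusters K",
                  y = paste(object$statistic_name, "coefficient"),
                  title = sprintf("%s: selected K = %d", object$scheme_prefix,
                                  object$selected_k)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a co-classification matrix
#'
#' @param x A `consensus_clustering`.
#' @param k Which K's matrix to draw; default the selected K.
#' @return A ggplot heatmap, samples ordered by the consensus dendrogram.
#' @export
plot_coclassification <- function(x, k = x$selected_k) {
  m <- x$coclassification[[as.character(k)]]
  hc <- stats::hclust(stats::as.dist(1 - m), method = "complete")
  ord <- hc$order
  df <- tibble::as_tibble(m[ord, ord], rownames = "sample_i") |>
    tidyr::pivot_longer(-"sample_i", names_to = "sample_j", values_to = "freq")
  df$sample_i <- factor(df$sample_i, levels = rownames(m)[ord])
  df$sample_j <- factor(df$sample_j, levels = rownames(m)[ord])
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_i, .data$sample_j,
                                   fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1), name = "co-classification") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s consensus at K = %d", x$scheme_prefix, k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
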