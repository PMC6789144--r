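#' Independent component analysis of an omics matrix (JADE)
#'
#' Decomposes a feature-centered omics matrix into `m` statistically
#' independent components over samples using the JADE algorithm (whitening by
#' singular value decomposition followed by joint approximate diagonalization
#' of the fourth-order cumulant matrices). Components live in sample space:
#' each component is a length-S projection vector, and every feature is
#' scored by its Pearson correlation with each projection.
#'
#' JADE is fully deterministic; `seed` is recorded in the result so that run
#' reports document the pipeline seed, but no random numbers are drawn.
#'
#' Conventions making the decomposition unique: components are ordered by
#' decreasing explained variance (sum of squared feature correlations), and
#' each component's sign is fixed so that its largest-magnitude sample
#' projection is positive (the heavy tail points up).
#'
#' @param matrix A feature-centered [omics_matrix()].
#' @param m Number of components, `2 <= m <= min(F, S) - 1`.
#' @param seed Integer seed recorded in the result.
#' @return A `component_decomposition`: list with `n_components`,
#'   `sample_projections` (m x S, rows uncorrelated, unit variance),
#'   `feature_correlations` (F x m), `selection_curve` (NULL here;
#'   filled by [component_count_curve()]) and `seed`.
#' @export
fit_ica <- function(matrix, m, seed = 1L) {
  stopifnot(inherits(matrix, "omics_matrix"))
  v <- matrix$values
  f <- nrow(v); s <- ncol(v)
  if (max(abs(rowMeans(v))) > 1e-8) {
    stop("fit_ica expects a feature-centered matrix; run center_features() first",
         call. = FALSE)
  }
  if (m < 2 || m > min(f, s) - 1) {
    stop(sprintf("m = %d out of range [2, %d]", m, min(f, s) - 1), call. = FALSE)
  }
  # whitening: samples are the observations, features the variables.
  # row-centering makes columns of t(v) centered; svd on the S x S Gram matrix.
  xt <- t(v) / sqrt(f)                     # S x F, scaled for conditioning
  gram <- tcrossprod(xt)                   # S x S
  eg <- eigen(gram, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  if (rank < m) {
    stop(sprintf("matrix rank %d is smaller than m = %d", rank, m), call. = FALSE)
  }
  # whitened scores: S x m, columns orthonormal scaled to unit variance
  z <- eg$vectors[, seq_len(m), drop = FALSE] * sqrt(s)
  rot <- .jade_rotation(z)
  y <- z %*% rot                           # S x m independent components
  fc <- stats::cor(t(v), y)                # F x m feature correlations
  # deterministic order and sign
  ord <- order(-colSums(fc^2))
  y <- y[, ord, drop = FALSE]
  fc <- fc[, ord, drop = FALSE]
  for (k in seq_len(m)) {
    i_max <- which.max(abs(y[, k]))
    if (y[i_max, k] < 0) {
      y[, k] <- -y[, k]
      fc[, k] <- -fc[, k]
    }
  }
  proj <- t(y)
  dimnames(proj) <- list(paste0("IC", seq_len(m)), colnames(v))
  dimnames(fc) <- list(rownames(v), paste0("IC", seq_len(m)))
  structure(list(n_components = m, sample_projections = proj,
                 feature_correlations = fc, selection_curve = NULL,
                 seed = as.integer(seed)),
            class = "component_decomposition")
}

# Joint approximate diagonalization of the fourth-order cumulant matrices
# (Cardoso's JADE, Jacobi sweeps over Givens rotations). z: T x m whitened.
.jade_rotation <- function(z) {
  T_ <- nrow(z); m <- ncol(z)
  nbcm <- m * (m + 1L) / 2L
  cm <- matrix(0, m, m * nbcm)
  R <- diag(m)
  rng <- seq_len(m)
  for (im in seq_len(m)) {
    xim <- z[, im]
    cm[, rng] <- crossprod(xim * xim * z, z) / T_ - R - 2 * tcrossprod(R[, im])
    rng <- rng + m
    if (im > 1L) for (jm in seq_len(im - 1L)) {
      xjm <- z[, jm]
      cm[, rng] <- sqrt(2) * (crossprod(xim * xjm * z, z) / T_ -
                                tcrossprod(R[, im], R[, jm]) -
                                tcrossprod(R[, jm], R[, im]))
      rng <- rng + m
    }
  }
  V <- diag(m)
  thr <- 1e-6 / sqrt(T_)
  for (sweep in 1:100) {
    rotated <- FALSE
    for (p in seq_len(m - 1L)) for (q in (p + 1L):m) {
      Ip <- seq(p, m * nbcm, by = m)
      Iq <- seq(q, m * nbcm, by = m)
      g <- rbind(cm[p, Ip] - cm[q, Iq], cm[p, Iq] + cm[q, Ip])
      gg <- tcrossprod(g)
      ton <- gg[1, 1] - gg[2, 2]
      toff <- gg[1, 2] + gg[2, 1]
      theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
      if (abs(sin(theta)) > thr) {
        rotated <- TRUE
        c_ <- cos(theta); s_ <- sin(theta)
        G <- matrix(c(c_, s_, -s_, c_), 2, 2)
        pair <- c(p, q)
        V[, pair] <- V[, pair] %*% G
        cm[pair, ] <- t(G) %*% cm[pair, ]
        cols <- c(Ip, Iq)
        cm[, cols] <- cbind(c_ * cm[, Ip] + s_ * cm[, Iq],
                            -s_ * cm[, Ip] + c_ * cm[, Iq])
      }
    }
    if (!rotated) break
  }
  V
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("<component_decomposition> %d components over %d samples\n",
              x$n_components, ncol(x$sample_projections)))
  invisible(x)
}

#' Tidy a component decomposition
#'
#' @param x A `component_decomposition`.
#' @param ... Unused.
#' @return Long tibble of sample projections: `component`, `sample_id`,
#'   `projection`.
#' @export
tidy.component_decomposition <- function(x, ...) {
  tibble::as_tibble(x$sample_projections, rownames = "component") |>
    tidyr::pivot_longer(-"component", names_to = "sample_id",
                        values_to = "projection")
}

#' Distance-correlation curve over candidate component counts
#'
#' For each `m` in `2..m_max`, fits ICA and records the Pearson correlation
#' between inter-sample Euclidean distances in the m-dimensional projection
#' space and in the original feature space. The gain at `m` is
#' `corr(m) - corr(m - 1)`, with `gain(2) = corr(2)`.
#'
#' @param matrix A feature-centered [omics_matrix()].
#' @param m_max Largest component count to consider (truncated with a warning
#'   if it exceeds the achievable rank).
#' @param seed Integer seed (recorded; JADE itself is deterministic).
#' @return A tibble of class `ica_selection_curve` with columns `m`,
#'   `distance_correlation`, `gain`; attribute `truncated` records whether
#'   `m_max` was reduced.
#' @export
component_count_curve <- function(matrix, m_max, seed = 1L) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (m_max < 2) stop("m_max must be at least 2", call. = FALSE)
  v <- matrix$values
  max_m <- min(nrow(v), ncol(v)) - 1L
  truncated <- FALSE
  if (m_max > max_m) {
    warning(sprintf("m_max truncated from %d to achievable rank %d", m_max, max_m))
    m_max <- max_m
    truncated <- TRUE
  }
  d_orig <- as.vector(stats::dist(t(v)))
  corr <- vapply(2:m_max, function(m) {
    dec <- fit_ica(matrix, m, seed = seed)
    # inter-sample distances in the reduced space: components carry unit
    # variance after whitening, so distances are taken on the least-squares
    # rank-m reconstruction, which restores each component's scale in the data
    y <- t(dec$sample_projections)               # S x m
    loadings <- v %*% y %*% solve(crossprod(y))  # F x m
    d_red <- as.vector(stats::dist(y %*% t(loadings)))
    stats::cor(d_red, d_orig)
  }, numeric(1))
  curve <- tibble::tibble(m = 2:m_max, distance_correlation = corr,
                          gain = c(corr[1], diff(corr)))
  class(curve) <- c("ica_selection_curve", class(curve))
  attr(curve, "truncated") <- truncated
  curve
}

#' Select the number of independent components
#'
#' Returns the component count immediately preceding the largest decrease in
#' distance-correlation gain; ties are broken toward the smaller count. If
#' the gain never decreases, the largest candidate is returned with a
#' warning.
#'
#' @param curve A curve from [component_count_curve()], or any data frame
#'   with columns `m` and `gain` (at least 3 rows).
#' @return Integer: the selected component count.
#' @export
select_component_count <- function(curve) {
  if (nrow(curve) < 3) stop("selection curve needs at least 3 points", call. = FALSE)
  drops <- -diff(curve$gain)         # drop at m -> m+1, attributed to m
  if (max(drops) <= 0) {
    warning("distance-correlation gain never decreases; returning m_max")
    return(as.integer(max(curve$m)))
  }
  as.integer(curve$m[which(drops >= max(drops) - 1e-9)[1]])
}

#' Remove features associated with unwanted components
#'
#' For each flagged component (non-neoplastic contamination or technical
#' signal), marks the `ceiling(fraction * F)` features with the largest
#' absolute Pearson correlation to that component's sample projection, then
#' removes the union of marked features. Correlations are computed against
#' the features of `matrix` itself, so the removal universe is whatever
#' matrix is passed (the ICA input set, or the full feature set).
#'
#' @param matrix An [omics_matrix()] over the same samples as `decomp`.
#' @param decomp A `component_decomposition` from [fit_ica()].
#' @param unwanted Integer indices of components to scrub (empty = identity).
#' @param fraction Fraction of features removed per unwanted component,
#'   default 0.20.
#' @return The filtered `omics_matrix`; samples are never touched.
#' @export
remove_confounded_features <- function(matrix, decomp, unwanted,
                                       fraction = 0.20) {
  stopifnot(inherits(matrix, "omics_matrix"),
            inherits(decomp, "component_decomposition"))
  if (!length(unwanted)) return(matrix)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)", call. = FALSE)
  if (!all(unwanted %in% seq_len(decomp$n_components))) {
    stop("unwanted component index out of range", call. = FALSE)
  }
  f <- nrow(matrix$values)
  n_mark <- ceiling(fraction * f)
  proj <- decomp$sample_projections[, colnames(matrix$values), drop = FALSE]
  marked <- logical(f)
  for (k in unwanted) {
    r <- abs(as.vector(stats::cor(t(matrix$values), proj[k, ])))
    ord <- order(-r, rownames(matrix$values), method = "radix")
    marked[ord[seq_len(n_mark)]] <- TRUE
  }
  log_transform(subset_features(matrix, !marked),
                sprintf("remove_confounded_%s_f%g",
                        paste(unwanted, collapse = "+"), fraction))
}

#' Report top correlated features per component
#'
#' Support for the manual annotation of components (muscle, hematopoietic,
#' technical): the features most correlated with each component's sample
#' projection.
#'
#' @param decomp A `component_decomposition`.
#' @param n Number of features per component.
#' @return Tibble with `component`, `feature_id`, `correlation`, ordered by
#'   decreasing absolute correlation within component.
#' @export
top_component_features <- function(decomp, n = 25) {
  fc <- decomp$feature_correlations
  purrr::map_dfr(seq_len(ncol(fc)), function(k) {
    ord <- order(-abs(fc[, k]))[seq_len(min(n, nrow(fc)))]
    tibble::tibble(component = colnames(fc)[k],
                   feature_id = rownames(fc)[ord],
                   correlation = fc[ord, k])
  })
}
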