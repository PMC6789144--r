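#' Average per-omics co-classification matrices into a multi-omics similarity
#'
#' The similarity between two samples is the mean, across omics, of the
#' frequency with which they were co-classified in that omics' consensus
#' clustering — i.e. the mean probability of belonging to the same subtype in
#' each single-omics classification system. Matrices are re-indexed by sample
#' id before averaging.
#'
#' @param matrices List of co-classification matrices (or
#'   `consensus_clustering` objects, from which the matrix at the selected K
#'   is taken), all over the same sample set.
#' @param source_omics Optional list/character describing the sources; filled
#'   automatically from `consensus_clustering` inputs.
#' @return A `multiomics_similarity`: list with `similarity` (symmetric,
#'   unit diagonal, entries in \[0, 1\]) and `source_omics`.
#' @export
average_coclassification <- function(matrices, source_omics = NULL) {
  if (length(matrices) < 2) stop("need at least 2 co-classification matrices", call. = FALSE)
  if (is.null(source_omics)) {
    source_omics <- purrr::map(matrices, function(m) {
      if (inherits(m, "consensus_clustering")) {
        list(omics_kind = m$scheme_prefix, selected_k = m$selected_k)
      } else list(omics_kind = "unknown", selected_k = NA_integer_)
    })
  }
  mats <- purrr::map(matrices, function(m) {
    if (inherits(m, "consensus_clustering")) {
      m$coclassification[[as.character(m$selected_k)]]
    } else m
  })
  ids <- sort(colnames(mats[[1]]))
  for (m in mats[-1]) {
    if (!setequal(colnames(m), ids)) {
      diff <- union(setdiff(colnames(m), ids), setdiff(ids, colnames(m)))
      stop("sample sets differ between co-classification matrices: ",
           paste(diff, collapse = ", "), call. = FALSE)
    }
  }
  mats <- purrr::map(mats, function(m) m[ids, ids])
  sim <- Reduce(`+`, mats) / length(mats)
  diag(sim) <- 1
  structure(list(similarity = sim, source_omics = source_omics),
            class = "multiomics_similarity")
}

#' @export
print.multiomics_similarity <- function(x, ...) {
  cat(sprintf("<multiomics_similarity> %d samples, %d source omics\n",
              nrow(x$similarity), length(x$source_omics)))
  invisible(x)
}

#' Partition around medoids on a dissimilarity matrix
#'
#' Classic PAM: greedy BUILD initialization followed by steepest-descent SWAP
#' until no swap of a medoid with a non-medoid reduces the total cost
#' `sum_i d(i, medoid(i))`. Because single-swap descent can stall in a local
#' optimum, the descent is restarted from deterministic alternative
#' initializations (the k most central samples, the medoids of a
#' complete-linkage k-cut) and, on instances small enough to afford it,
#' stalls are escaped through the best improving double (then triple) swap.
#' The best solution is kept. Fully
#' deterministic: ties are broken toward the smallest index at every step.
#'
#' @param d Square symmetric non-negative dissimilarity matrix with zero
#'   diagonal.
#' @param k Number of medoids, `1 <= k <= n`.
#' @return List with `medoid_ids` (column names or indices), `labels`
#'   (a [label_vector()], classes renamed by decreasing size) and `cost`
#'   (the achieved objective).
#' @export
pam_medoids <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (k < 1) stop("k must be positive", call. = FALSE)
  ids <- colnames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  starts <- list(.pam_build(d, k))
  if (k > 1 && k < n) {
    central <- sort(order(colSums(d))[seq_len(k)])
    starts <- c(starts, list(central))
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    cl <- stats::cutree(hc, k)
    hmed <- vapply(seq_len(k), function(g) {
      members <- which(cl == g)
      members[which.min(colSums(d[members, members, drop = FALSE]))]
    }, integer(1))
    starts <- c(starts, list(sort(hmed)))
  }
  best <- NULL
  for (st in unique(starts)) {
    cand <- .pam_swap(d, st)
    if (is.null(best) || cand$cost < best$cost - 1e-12) best <- cand
  }
  dm <- d[, best$med, drop = FALSE]
  which_near <- max.col(-dm, ties.method = "first")
  labels <- label_vector(ids, rename_by_size(which_near), "pam")
  list(medoid_ids = ids[best$med], labels = labels, cost = best$cost)
}

# greedy BUILD initialization
.pam_build <- function(d, k) {
  med <- which.min(colSums(d))
  nearest <- d[, med]
  while (length(med) < k) {
    gains <- colSums(pmax(nearest - d, 0))
    gains[med] <- -Inf
    nxt <- which.max(gains)
    med <- c(med, nxt)
    nearest <- pmin(nearest, d[, nxt])
  }
  sort(med)
}

# steepest-descent SWAP to a local optimum from a given medoid set
.pam_swap <- function(d, med) {
  n <- nrow(d)
  k <- length(med)
  repeat {
    dm <- d[, med, drop = FALSE]
    which_near <- max.col(-dm, ties.method = "first")
    n1 <- dm[cbind(seq_len(n), which_near)]
    n2 <- if (k == 1) rep(Inf, n) else {
      apply(dm, 1, function(r) sort(r, partial = 2)[2])
    }
    cost <- sum(n1)
    best_delta <- -1e-12
    best <- NULL
    for (hi in seq_along(med)) {
      backup <- ifelse(which_near == hi, n2, n1)
      for (i in setdiff(seq_len(n), med)) {
        delta <- sum(pmin(d[, i], backup)) - cost
        if (delta < best_delta) {
          best_delta <- delta
          best <- c(hi, i)
        }
      }
    }
    if (is.null(best)) {
      # on small instances, widen the neighborhood: escape via the best
      # improving pair of swaps, then resume single-swap descent
      if (choose(n, k) <= 5000 && k >= 2) {
        esc <- .pam_multi_swap(d, med, cost, 2)
        if (is.null(esc) && k >= 3 && n <= 40) {
          esc <- .pam_multi_swap(d, med, cost, 3)
        }
        if (!is.null(esc)) {
          med <- esc
          next
        }
      }
      break
    }
    med[best[1]] <- best[2]
    med <- sort(med)
  }
  list(med = med, cost = cost)
}

# best improving r-fold swap (r medoids out, r candidates in), or NULL
.pam_multi_swap <- function(d, med, cost, r) {
  n <- nrow(d)
  non <- setdiff(seq_len(n), med)
  if (length(non) < r || length(med) < r) return(NULL)
  best <- NULL
  best_cost <- cost - 1e-12
  for (hr in utils::combn(seq_along(med), r, simplify = FALSE)) {
    keep <- med[-hr]
    for (ir in utils::combn(non, r, simplify = FALSE)) {
      cand <- c(keep, ir)
      cc <- sum(matrixStats::rowMins(d[, cand, drop = FALSE]))
      if (cc < best_cost) {
        best_cost <- cc
        best <- sort(cand)
      }
    }
  }
  best
}

#' Resampled PAM consensus on the multi-omics similarity
#'
#' Adapts the consensus framework to a similarity matrix (there are no
#' features to resample, so samples are subsampled): each iteration draws
#' `ceiling(sample_subsample * n)` samples without replacement and partitions
#' them by PAM on the induced sub-dissimilarity `1 - similarity` at every K.
#' The co-classification entry for a pair is the fraction of iterations in
#' which the pair was co-clustered among those in which both samples were
#' included. Consensus labels are the PAM partition of the full
#' `1 - co-classification` matrix; K is selected by the dispersion
#' coefficient.
#'
#' @param similarity A `multiomics_similarity` (or plain similarity matrix).
#' @param k_range Integer vector of cluster numbers, default `2:9`.
#' @param n_iterations Number of resampling iterations, default 1000.
#' @param sample_subsample Fraction of samples drawn per iteration,
#'   default 0.8.
#' @param seed Integer seed.
#' @param k_rule `"argmax"` (default: K maximizing dispersion) or
#'   `"pre_drop"` (cophenetic-style: K before the largest drop).
#' @return A `consensus_clustering` with dispersion as the K-selection
#'   statistic and `scheme_prefix = "multiomics"`.
#' @export
run_pam_consensus <- function(similarity, k_range = 2:9, n_iterations = 1000,
                              sample_subsample = 0.8, seed = 1L,
                              k_rule = c("argmax", "pre_drop")) {
  k_rule <- match.arg(k_rule)
  sim <- if (inherits(similarity, "multiomics_similarity")) similarity$similarity else similarity
  d <- 1 - sim
  diag(d) <- 0
  n <- nrow(d)
  k_range <- sort(unique(as.integer(k_range)))
  n_draw <- ceiling(sample_subsample * n)
  co_cluster <- lapply(k_range, function(k) matrix(0L, n, n))
  co_include <- matrix(0L, n, n)
  withr::local_seed(seed)
  for (it in seq_len(n_iterations)) {
    sub <- sort(sample.int(n, n_draw))
    co_include[sub, sub] <- co_include[sub, sub] + 1L
    dsub <- d[sub, sub, drop = FALSE]
    for (ki in seq_along(k_range)) {
      fit <- pam_medoids(dsub, k_range[ki])
      cl <- as.integer(fit$labels$labels)
      same <- outer(cl, cl, `==`)
      co_cluster[[ki]][sub, sub] <- co_cluster[[ki]][sub, sub] + same
    }
  }
  if (any(co_include == 0 & upper.tri(co_include))) {
    warning("some sample pairs were never co-included; their consensus is set to 0")
  }
  coclass <- lapply(co_cluster, function(m) {
    out <- ifelse(co_include > 0, m / pmax(co_include, 1L), 0)
    diag(out) <- 1
    dimnames(out) <- dimnames(sim)
    out
  })
  names(coclass) <- as.character(k_range)
  select_fun <- if (k_rule == "argmax") select_k_dispersion else {
    function(kc) select_k_cophenetic(kc)
  }
  .finish_consensus(coclass, k_range, n_iterations, seed,
                    scheme_prefix = "multiomics",
                    label_fun = function(m, k) {
                      pam_medoids(1 - m, k)$labels
                    },
                    stat_fun = dispersion_coefficient,
                    select_fun = select_fun,
                    statistic_name = "dispersion")
}

#' Dispersion coefficient of a consensus matrix
#'
#' `rho = (1 / n^2) * sum_ij 4 * (M_ij - 1/2)^2`, over all entries including
#' the diagonal. Ranges from 0 to 1; equals 1 exactly when every entry is 0
#' or 1, i.e. when all resampling iterations agreed on the same partition.
#'
#' @param coclassification Consensus co-classification matrix.
#' @return The dispersion in \[0, 1\].
#' @export
dispersion_coefficient <- function(coclassification) {
  mean(4 * (coclassification - 0.5)^2)
}

#' Select K by maximal dispersion
#'
#' Returns the K maximizing the dispersion coefficient; ties go to the
#' smaller K.
#'
#' @param k_curve Data frame with columns `k` and `statistic` (per-K
#'   dispersion values).
#' @return Integer selected K.
#' @export
select_k_dispersion <- function(k_curve) {
  s <- k_curve$statistic
  as.integer(k_curve$k[which(s >= max(s) - 1e-9)[1]])
}
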