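# Linear SVM via the L2-regularized squared-hinge primal:
#   min 0.5 ||w||^2 + C sum_i max(0, 1 - y_i (w'x_i + b))^2
# Convex and differentiable, optimized by BFGS; deterministic from a zero
# start. x: n x d (already standardized), y in {-1, +1}.
.svm_linear_fit <- function(x, y, C = 1) {
  n <- nrow(x); d <- ncol(x)
  obj <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1]
    margin <- 1 - y * (drop(x %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(margin, 0)^2)
  }
  grad <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1]
    margin <- 1 - y * (drop(x %*% w) + b)
    act <- margin > 0
    gy <- -2 * C * (margin * y)[act]
    c(w + drop(crossprod(x[act, , drop = FALSE], gy)), sum(gy))
  }
  fit <- stats::optim(rep(0, d + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1])
}

#' Train an mRNA-only surrogate classifier
#'
#' Learns to reproduce one subtyping scheme (expression E1/E2, methylation
#' M1-M3 or the merged 14q32 high/low microRNA scheme) from mRNA profiles
#' alone: markers are selected on the training data by moderated t, features
#' are standardized with training means/SDs, and a linear support vector
#' machine is fitted (one-vs-rest with arg-max decision values for more than
#' two classes).
#'
#' @param matrix An [omics_matrix()] of mRNA log intensities.
#' @param labels A [label_vector()]: the scheme's classes for the training
#'   samples (each class needs at least 2 samples).
#' @param scheme One of `"mrna:E"`, `"methylation:M"`, `"mirna:14q32"`;
#'   decides the marker-selection rule (top 200 per class for the two first,
#'   FDR 5% for the 14q32 scheme).
#' @param cost SVM cost parameter C, default 1.
#' @param n_top Markers per class for the top-N rules, default 200.
#' @param fdr FDR threshold for the 14q32 scheme, default 0.05.
#' @return A `surrogate_model`: markers, per-feature standardization,
#'   linear weights/intercepts per class, class levels, scheme.
#' @export
train_surrogate <- function(matrix, labels,
                            scheme = c("mrna:E", "methylation:M", "mirna:14q32"),
                            cost = 1, n_top = 200, fdr = 0.05) {
  scheme <- match.arg(scheme)
  v <- matrix$values
  y <- droplevels(labels$labels[match(colnames(v), labels$sample_ids)])
  if (any(table(y) < 2)) stop("every class needs at least 2 training samples", call. = FALSE)
  # marker rule follows the realized class count: differential at FDR for
  # the merged 14q32 scheme, top-N per class for two classes, one-vs-rest
  # beyond two
  rule <- if (scheme == "mirna:14q32") "fdr" else
    if (nlevels(y) == 2) "top_per_class" else "top_one_vs_rest"
  yl <- label_vector(colnames(v), y, scheme)
  markers <- select_markers(matrix, yl, rule = rule, n_top = n_top, fdr = fdr)
  if (length(markers) < 2) stop("no usable markers for scheme ", scheme, call. = FALSE)
  x <- t(v[markers, , drop = FALSE])
  ctr <- colMeans(x)
  scl <- matrixStats::colSds(x)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  lev <- levels(y)
  fits <- lapply(lev, function(cl) {
    .svm_linear_fit(xs, ifelse(y == cl, 1, -1), C = cost)
  })
  W <- do.call(rbind, lapply(fits, `[[`, "w"))
  b <- vapply(fits, `[[`, numeric(1), "b")
  dimnames(W) <- list(lev, markers)
  structure(list(scheme = scheme, markers = markers, center = ctr, scale = scl,
                 weights = W, intercepts = stats::setNames(b, lev),
                 levels = lev, cost = cost),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate_model> scheme %s: %d markers, classes %s\n",
              x$scheme, length(x$markers), paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Predict subtype labels from mRNA profiles
#'
#' @param object A `surrogate_model`.
#' @param matrix An [omics_matrix()] (or plain matrix) containing at least
#'   the model's marker features.
#' @param ... Unused.
#' @return A [label_vector()] of predicted classes (arg-max of the linear
#'   decision values; deterministic and invariant to feature order).
#' @export
predict.surrogate_model <- function(object, matrix, ...) {
  v <- if (inherits(matrix, "omics_matrix")) matrix$values else matrix
  missing <- setdiff(object$markers, rownames(v))
  if (length(missing)) {
    stop("matrix lacks ", length(missing), " marker feature(s), e.g. ",
         missing[1], call. = FALSE)
  }
  x <- t(v[object$markers, , drop = FALSE])
  xs <- scale(x, center = object$center, scale = object$scale)
  dec <- xs %*% t(object$weights) + rep(object$intercepts, each = nrow(xs))
  pick <- if (length(object$levels) == 2) {
    # binary: the two one-vs-rest scores are mirror images; use the first
    ifelse(dec[, 1] >= 0, object$levels[1], object$levels[2])
  } else {
    object$levels[max.col(dec, ties.method = "first")]
  }
  label_vector(rownames(x), factor(pick, levels = object$levels), object$scheme)
}

#' Tidy a surrogate model
#'
#' @param x A `surrogate_model`.
#' @param ... Unused.
#' @return Tibble of linear weights: `class`, `feature_id`, `weight`.
#' @export
tidy.surrogate_model <- function(x, ...) {
  tibble::as_tibble(x$weights, rownames = "class") |>
    tidyr::pivot_longer(-"class", names_to = "feature_id", values_to = "weight")
}

#' Repeated stratified cross-validated accuracy
#'
#' 10-times repeated 10-fold (by default) stratified cross-validation of the
#' surrogate classifier. Marker selection and standardization are redone
#' inside every training fold, so the estimate carries no selection leakage;
#' `select_once = TRUE` instead selects markers once on the full data before
#' cross-validating, for comparability with workflows that fixed the
#' signature up front.
#'
#' @inheritParams train_surrogate
#' @param folds Number of folds, default 10.
#' @param repeats Number of repeats, default 10.
#' @param seed Integer seed driving fold assignment.
#' @param select_once Logical; see above. Default `FALSE`.
#' @return A one-row tibble: `scheme`, `mean_accuracy`, `sd_accuracy`,
#'   `folds`, `repeats`; per-repeat accuracies in attribute `per_repeat`.
#' @export
repeated_cv_accuracy <- function(matrix, labels, scheme, folds = 10,
                                 repeats = 10, seed = 1L, cost = 1,
                                 n_top = 200, fdr = 0.05, select_once = FALSE) {
  v <- matrix$values
  n <- ncol(v)
  if (n < folds) stop("fewer samples than folds", call. = FALSE)
  y <- droplevels(labels$labels[match(colnames(v), labels$sample_ids)])
  fixed_markers <- if (select_once) {
    rule <- if (scheme == "mirna:14q32") "fdr" else
      if (nlevels(y) == 2) "top_per_class" else "top_one_vs_rest"
    select_markers(matrix, label_vector(colnames(v), y, scheme), rule = rule,
                   n_top = n_top, fdr = fdr)
  } else NULL
  withr::local_seed(seed)
  acc <- vapply(seq_len(repeats), function(r) {
    fold_of <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    correct <- 0L
    for (fo in seq_len(folds)) {
      test_i <- which(fold_of == fo)
      train_i <- setdiff(seq_len(n), test_i)
      if (length(test_i) == 0) next
      ytr <- droplevels(y[train_i])
      if (nlevels(ytr) < nlevels(y) || any(table(ytr) < 2)) {
        stop("a fold lost a class entirely; reduce `folds`", call. = FALSE)
      }
      tr_mat <- matrix
      tr_mat$values <- v[, train_i, drop = FALSE]
      tr_lab <- label_vector(colnames(tr_mat$values), y[train_i], scheme)
      model <- if (is.null(fixed_markers)) {
        train_surrogate(tr_mat, tr_lab, scheme, cost = cost, n_top = n_top, fdr = fdr)
      } else {
        sub <- tr_mat
        sub$values <- sub$values[fixed_markers, , drop = FALSE]
        train_surrogate(sub, tr_lab, scheme, cost = cost,
                        n_top = length(fixed_markers), fdr = 1)
      }
      pred <- predict(model, v[, test_i, drop = FALSE])
      correct <- correct + sum(as.character(pred$labels) == as.character(y[test_i]))
    }
    correct / n
  }, numeric(1))
  out <- tibble::tibble(scheme = scheme, mean_accuracy = mean(acc),
                        sd_accuracy = stats::sd(acc), folds = folds,
                        repeats = repeats)
  attr(out, "per_repeat") <- acc
  out
}

#' Merge the 14q32-silenced microRNA subtypes
#'
#' Collapses the four-class miRNA subtyping into the two-class 14q32 scheme:
#' Mir1 becomes `14q32_high`, the silenced subtypes Mir2, Mir3 and Mir4
#' become `14q32_low`.
#'
#' @param labels A [label_vector()] with classes among Mir1-Mir4.
#' @return A [label_vector()] with scheme `"mirna:14q32"`.
#' @export
merge_mirna_classes <- function(labels) {
  stopifnot(inherits(labels, "label_vector"))
  lv <- as.character(labels$labels)
  known <- c("Mir1", "Mir2", "Mir3", "Mir4")
  bad <- setdiff(unique(lv), known)
  if (length(bad)) stop("unknown miRNA class code(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  merged <- ifelse(lv == "Mir1", "14q32_high", "14q32_low")
  label_vector(labels$sample_ids,
               factor(merged, levels = c("14q32_high", "14q32_low")),
               "mirna:14q32")
}

#' Combine single-omics predictions into the multi-omics class
#'
#' Recursive partitioning of the three per-omics predictions into the
#' six-class system: the M3 methylation class maps to the
#' dedifferentiated-like C6; among the remaining IDH-mutant (M2) samples the
#' 14q32 status separates C5 (silenced) from C4 (retained); among IDH
#' wild-type (M1) samples the expression class separates the mitotic C3 (E2)
#' from the quiescent C1/2 (E1). C1 and C2 cannot be told apart by the three
#' schemes and are emitted as the merged `"C1/2"` label.
#'
#' @param e [label_vector()] of expression classes (E1/E2).
#' @param m [label_vector()] of methylation classes (M1/M2/M3).
#' @param mir [label_vector()] of merged 14q32 classes
#'   (14q32_high/14q32_low).
#' @return A [label_vector()] with classes C1/2, C3, C4, C5, C6 and scheme
#'   `"multiomics:C"`.
#' @export
assign_multiomics_class <- function(e, m, mir) {
  ids <- e$sample_ids
  if (!setequal(ids, m$sample_ids) || !setequal(ids, mir$sample_ids)) {
    stop("the three predictions cover different samples", call. = FALSE)
  }
  ev <- as.character(e$labels)[match(ids, e$sample_ids)]
  mv <- as.character(m$labels)[match(ids, m$sample_ids)]
  mirv <- as.character(mir$labels)[match(ids, mir$sample_ids)]
  if (anyNA(ev) || anyNA(mv) || anyNA(mirv)) {
    stop("missing prediction for at least one sample", call. = FALSE)
  }
  cls <- dplyr::case_when(
    mv == "M3" ~ "C6",
    mv == "M2" & mirv == "14q32_low" ~ "C5",
    mv == "M2" & mirv == "14q32_high" ~ "C4",
    mv == "M1" & ev == "E2" ~ "C3",
    mv == "M1" & ev == "E1" ~ "C1/2",
    TRUE ~ NA_character_
  )
  if (anyNA(cls)) {
    stop("unrecognized class code combination, e.g. (",
         ev[is.na(cls)][1], ", ", mv[is.na(cls)][1], ", ",
         mirv[is.na(cls)][1], ")", call. = FALSE)
  }
  label_vector(ids, factor(cls, levels = c("C1/2", "C3", "C4", "C5", "C6")),
               "multiomics:C")
}
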