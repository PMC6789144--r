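#' Empirical-Bayes moderated two-group t-test
#'
#' Per-feature two-group comparison with variance shrinkage: the pooled
#' residual variance of each feature is moderated toward a global prior,
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`, and the t statistic uses
#' the posterior variance with `d0 + d` degrees of freedom. The prior
#' (`d0`, `s0^2`) is estimated by moment matching on the log sample
#' variances (trigamma inversion), the standard empirical-Bayes route.
#'
#' The group-mean difference is `mean(group2) - mean(group1)` where groups
#' are ordered by their factor levels, so positive t means over-expression
#' in the second level.
#'
#' @param matrix An [omics_matrix()] (log scale) or plain numeric matrix.
#' @param labels A [label_vector()] (or factor) with exactly two levels over
#'   the matrix samples; each group needs at least 2 samples.
#' @param d0_override Optional fixed prior degrees of freedom; `0` disables
#'   shrinkage and reproduces the ordinary pooled t-test.
#' @return A `moderated_t_result`: tibble with `feature_id`, `mean_diff`,
#'   `pooled_sd`, `t`, `df_total`, `p_value`, `q_value` plus attributes
#'   `d0` and `s0_sq`.
#' @export
moderated_t_test <- function(matrix, labels, d0_override = NULL) {
  v <- if (inherits(matrix, "omics_matrix")) matrix$values else matrix
  if (inherits(labels, "label_vector")) {
    if (!setequal(labels$sample_ids, colnames(v))) {
      stop("label sample ids do not match matrix samples", call. = FALSE)
    }
    y <- labels$labels[match(colnames(v), labels$sample_ids)]
  } else {
    y <- as.factor(labels)
  }
  y <- droplevels(y)
  if (nlevels(y) != 2) stop("moderated t-test needs exactly 2 groups", call. = FALSE)
  n1 <- sum(y == levels(y)[1]); n2 <- sum(y == levels(y)[2])
  if (min(n1, n2) < 2) stop("each group needs at least 2 samples", call. = FALSE)
  m1 <- rowMeans(v[, y == levels(y)[1], drop = FALSE])
  m2 <- rowMeans(v[, y == levels(y)[2], drop = FALSE])
  ss1 <- rowSums((v[, y == levels(y)[1], drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, y == levels(y)[2], drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  if (is.null(d0_override)) {
    prior <- .fit_f_dist(s2, d)
  } else {
    prior <- list(d0 = d0_override, s0_sq = if (d0_override > 0)
      .fit_f_dist(s2, d)$s0_sq else NA_real_)
  }
  d0 <- prior$d0
  s2_post <- if (d0 == 0) s2 else if (is.infinite(d0)) rep(prior$s0_sq, length(s2)) else
    (d0 * prior$s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  tstat[se == 0] <- 0
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat)) else
    2 * stats::pt(-abs(tstat), df = df_total)
  out <- tibble::tibble(
    feature_id = rownames(v),
    mean_diff = m2 - m1,
    pooled_sd = sqrt(s2),
    t = tstat,
    df_total = df_total,
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH")
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- prior$s0_sq
  attr(out, "groups") <- levels(y)
  class(out) <- c("moderated_t_result", class(out))
  out
}

# moment estimation of the scaled-F prior on sample variances:
# log s^2 ~ log s0^2 + log F(d, d0); match mean and variance of log s^2
# using digamma/trigamma, inverting trigamma by Newton iteration.
.fit_f_dist <- function(s2, d) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  ev <- mean((e - ebar)^2) * length(e) / (length(e) - 1)
  excess <- ev - trigamma(d / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(ebar)))
  }
  d0 <- 2 * .trigamma_inverse(excess)
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve trigamma(y) = x, monotone decreasing on (0, Inf)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Select marker features for a surrogate scheme
#'
#' Implements the three marker-selection rules used by the mRNA surrogate
#' classifiers:
#' \describe{
#'   \item{`top_per_class`}{two-group scheme: the `n_top` most over-expressed
#'     features of each group (by moderated-t sign and magnitude), union of
#'     both directions (at most `2 * n_top`).}
#'   \item{`top_one_vs_rest`}{multi-class scheme: for each class, the `n_top`
#'     most over-expressed features of that class versus all others; union.}
#'   \item{`fdr`}{all features differential at `q <= fdr` (used for the
#'     merged 14q32 high/low scheme; the count is data-dependent).}
#' }
#'
#' @param matrix An [omics_matrix()] of mRNA log intensities.
#' @param labels A [label_vector()] over the matrix samples.
#' @param rule One of `"top_per_class"`, `"top_one_vs_rest"`, `"fdr"`.
#' @param n_top Markers per class for the top rules, default 200.
#' @param fdr FDR threshold for the `"fdr"` rule, default 0.05.
#' @return Character vector of marker feature ids.
#' @export
select_markers <- function(matrix, labels,
                           rule = c("top_per_class", "top_one_vs_rest", "fdr"),
                           n_top = 200, fdr = 0.05) {
  rule <- match.arg(rule)
  v <- matrix$values
  y <- labels$labels[match(colnames(v), labels$sample_ids)]
  take_top <- function(stat_tbl, direction) {
    s <- stat_tbl$t * direction
    ord <- order(-s, stat_tbl$feature_id, method = "radix")
    keep <- ord[seq_len(min(n_top, sum(s > 0), length(ord)))]
    stat_tbl$feature_id[keep]
  }
  if (rule == "top_per_class") {
    if (nlevels(droplevels(y)) != 2) stop("top_per_class needs 2 classes", call. = FALSE)
    st <- moderated_t_test(v, y)
    markers <- union(take_top(st, +1), take_top(st, -1))
  } else if (rule == "top_one_vs_rest") {
    markers <- character(0)
    for (cl in levels(droplevels(y))) {
      yy <- factor(ifelse(y == cl, "this", "rest"), levels = c("rest", "this"))
      st <- moderated_t_test(v, yy)
      markers <- union(markers, take_top(st, +1))
    }
  } else {
    st <- moderated_t_test(v, y)
    markers <- st$feature_id[st$q_value <= fdr]
  }
  if (length(markers) < 2) {
    warning("fewer than 2 markers selected under rule ", rule)
  }
  markers
}
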