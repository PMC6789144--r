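test_that("consensus co-classification separates planted groups into blocks", {
  v <- blob_matrix(n_features = 80, n1 = 8, n2 = 8, shift = 4)
  om <- center_features(toy_matrix(v, "mrna"))
  cons <- run_consensus(om, k_range = 2:4, n_iterations = 50,
                        variant_fraction = 1, seed = 6)
  cc <- cons$coclassification[["2"]]
  within <- c(cc[1:8, 1:8][upper.tri(diag(8))], cc[9:16, 9:16][upper.tri(diag(8))])
  between <- cc[1:8, 9:16]
  expect_gte(min(within), 0.99)
  expect_lte(max(between), 0.01)
  # matrix invariants at every K
  for (m in cons$coclassification) {
    expect_true(isSymmetric(m))
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(diag(m), rep(1, 16), ignore_attr = TRUE)
  }
  expect_equal(adjusted_rand_index(
    cons$labels[["2"]],
    label_vector(colnames(v), rep(c("a", "b"), each = 8))), 1)
})

test_that("consensus is deterministic under a seed and degenerates correctly", {
  v <- blob_matrix(n_features = 40, seed = 13)
  om <- center_features(toy_matrix(v, "mrna"))
  c1 <- run_consensus(om, k_range = 2:3, n_iterations = 20, variant_fraction = 0.8, seed = 5)
  c2 <- run_consensus(om, k_range = 2:3, n_iterations = 20, variant_fraction = 0.8, seed = 5)
  expect_identical(c1$coclassification, c2$coclassification)
  # single iteration with full features equals a single Ward cut
  c3 <- run_consensus(om, k_range = 2:2, n_iterations = 1, variant_fraction = 1,
                      feature_subsample = 1, seed = 5)
  cc <- c3$coclassification[["2"]]
  expect_true(all(cc %in% c(0, 1)))
  hc <- stats::hclust(stats::as.dist(pearson_distance(om$values)), "ward.D2")
  cl <- stats::cutree(hc, 2)
  expect_equal(cc, outer(cl, cl, function(a, b) as.numeric(a == b)),
               ignore_attr = TRUE)
})

test_that("co-classification is exchangeable under sample permutation", {
  v <- blob_matrix(n_features = 40, seed = 21)
  om <- center_features(toy_matrix(v, "mrna"))
  base <- run_consensus(om, k_range = 2:2, n_iterations = 30,
                        variant_fraction = 0.8, seed = 9)
  perm <- sample(ncol(v))
  vp <- v[, perm]
  omp <- center_features(toy_matrix(vp, "mrna"))
  pc <- run_consensus(omp, k_range = 2:2, n_iterations = 30,
                      variant_fraction = 0.8, seed = 9)
  m1 <- base$coclassification[["2"]][colnames(vp), colnames(vp)]
  expect_equal(pc$coclassification[["2"]], m1, tolerance = 0.25)
  # exact permutation equivariance holds for the block structure
  expect_equal(pc$coclassification[["2"]] > 0.5, m1 > 0.5, ignore_attr = TRUE)
})

test_that("consensus labels recover planted blocks from noisy matrices", {
  cc <- block_coclass(c(1, 1, 2, 2, 3, 3))
  off <- upper.tri(cc) & cc == 0
  cc[off] <- 0.1
  cc[lower.tri(cc)] <- t(cc)[lower.tri(cc)]
  lab <- consensus_labels(cc, 3)
  expect_equal(ari_bruteforce(as.integer(lab$labels), c(1, 1, 2, 2, 3, 3)), 1)
  expect_equal(nlevels(consensus_labels(cc, 1)$labels), 1)
  expect_error(consensus_labels(cc, 9), "exceeds")
  # class codes are renamed by decreasing size
  cc2 <- block_coclass(c(1, 2, 2, 2, 3, 3))
  lab2 <- consensus_labels(cc2, 3)
  expect_equal(as.integer(table(lab2$labels)), c(3L, 2L, 1L))
})

test_that("cophenetic coefficient equals brute-force tree tracing", {
  # ultrametric (nested binary blocks) gives exactly 1
  cc <- block_coclass(c(1, 1, 1, 2, 2, 2))
  expect_equal(cophenetic_coefficient(cc), 1, tolerance = 1e-9)
  # direct oracle on a general 5x5 consensus: trace merge heights by hand
  set.seed(14)
  m <- matrix(runif(25, 0, 1), 5)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(paste0("s", 1:5), paste0("s", 1:5))
  d <- 1 - m
  hc <- stats::hclust(stats::as.dist(d), "complete")
  # brute force: cophenetic distance = height of the first merge joining i, j
  n <- 5
  coph <- matrix(0, n, n)
  groups <- as.list(seq_len(n))
  for (step in seq_len(n - 1)) {
    mem <- hc$merge[step, ]
    pick <- function(x) if (x < 0) -x else groups[[n + x]]
    g1 <- pick(mem[1]); g2 <- pick(mem[2])
    for (i in g1) for (j in g2) coph[i, j] <- coph[j, i] <- hc$height[step]
    groups[[n + step]] <- c(g1, g2)
  }
  expected <- cor(coph[upper.tri(coph)], d[upper.tri(d)])
  expect_equal(cophenetic_coefficient(m), expected, tolerance = 1e-12)
  expect_true(abs(cophenetic_coefficient(m)) <= 1)
  # constant distances are undefined
  ones <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_warning(val <- cophenetic_coefficient(ones), "undefined|constant")
  expect_true(is.nan(val))
})

test_that("cophenetic K selection takes the K before the largest drop", {
  kc <- tibble::tibble(k = 2:5, statistic = c(0.99, 0.98, 0.80, 0.78))
  expect_equal(select_k_cophenetic(kc), 3L)
  expect_equal(select_k_cophenetic(tibble::tibble(k = 2:3, statistic = c(0.9, 0.4))), 2L)
  # equal largest drops resolve to the smaller K
  kc2 <- tibble::tibble(k = 2:5, statistic = c(1, 0.8, 0.9, 0.7))
  expect_equal(select_k_cophenetic(kc2), 2L)
  expect_warning(sel <- select_k_cophenetic(
    tibble::tibble(k = 2:4, statistic = c(0.7, 0.8, 0.9))), "never decreases")
  expect_equal(sel, 4L)
})

test_that("tidiers and plots expose the consensus results", {
  v <- blob_matrix(n_features = 40, seed = 3)
  om <- center_features(toy_matrix(v, "mrna"))
  cons <- run_consensus(om, k_range = 2:3, n_iterations = 10,
                        variant_fraction = 1, seed = 2)
  td <- tidy(cons)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16)
  gl <- glance(cons)
  expect_equal(gl$selected_k, cons$selected_k)
  expect_s3_class(autoplot(cons), "ggplot")
  expect_s3_class(plot_coclassification(cons), "ggplot")
})
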