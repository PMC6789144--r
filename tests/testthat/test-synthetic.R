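test_that("the default cohort honors its shape and annotation contract", {
  co <- simulate_cohort(simulation_params(), seed = 1)
  expect_equal(dim(co$mrna$values), c(2000L, 102L))
  expect_equal(dim(co$mirna$values), c(800L, 102L))
  expect_equal(dim(co$methylation$values), c(5000L, 102L))
  expect_equal(sum(co$mirna$annotation$is_14q32), 102L)
  expect_equal(as.integer(table(co$truth_multiomics$labels)),
               c(18L, 19L, 15L, 19L, 20L, 11L))
  # container invariants
  expect_true(all(co$methylation$values >= 0 & co$methylation$values <= 1))
  expect_true(all(co$mirna$values >= 0 & co$mirna$values == round(co$mirna$values)))
  expect_false(anyNA(co$mrna$values))
  # per-omics truths are consistent with the class attributes
  expect_equal(as.integer(table(co$truth_e$labels)), c(56L, 46L))
  expect_equal(as.integer(table(co$truth_m$labels)), c(52L, 39L, 11L))
  expect_equal(as.integer(table(co$truth_mir$labels)), c(61L, 10L, 20L, 11L))
})

test_that("simulation is bitwise reproducible by seed and varies across seeds", {
  a <- simulate_cohort(simulation_params(n_mrna = 200, n_mirna = 120, n_cpg = 200,
                                         n_14q32 = 30), seed = 5)
  b <- simulate_cohort(simulation_params(n_mrna = 200, n_mirna = 120, n_cpg = 200,
                                         n_14q32 = 30), seed = 5)
  expect_identical(a$mrna$values, b$mrna$values)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$methylation$values, b$methylation$values)
  c_ <- simulate_cohort(simulation_params(n_mrna = 200, n_mirna = 120, n_cpg = 200,
                                          n_14q32 = 30), seed = 6)
  expect_false(identical(a$mrna$values, c_$mrna$values))
  expect_error(simulate_cohort(simulation_params(class_sizes = c(1, 2, 3))),
               "six")
})

test_that("14q32 silencing is graded: class medians decrease with grade", {
  co <- simulate_cohort(simulation_params(), seed = 1)
  norm <- upper_quartile_normalize(filter_detected_mirnas(co$mirna))
  is14 <- norm$annotation$is_14q32
  cls_median <- vapply(paste0("Mir", 1:4), function(cl) {
    cols <- co$truth_mir$sample_ids[co$truth_mir$labels == cl]
    median(norm$values[is14, cols])
  }, numeric(1))
  expect_true(all(diff(cls_median) < 0))
  # zero silencing removes the class differences entirely
  co0 <- simulate_cohort(simulation_params(silencing_per_grade = 0), seed = 1)
  norm0 <- upper_quartile_normalize(filter_detected_mirnas(co0$mirna))
  is14_0 <- norm0$annotation$is_14q32
  grp <- as.character(co0$truth_mir$labels)
  means <- vapply(split(seq_len(102), grp), function(ix) {
    mean(norm0$values[is14_0, ix])
  }, numeric(1))
  sds <- vapply(split(seq_len(102), grp), function(ix) {
    sd(colMeans(norm0$values[is14_0, ix, drop = FALSE]))
  }, numeric(1))
  p <- stats::t.test(colMeans(norm0$values[is14_0, grp == "Mir1", drop = FALSE]),
                     colMeans(norm0$values[is14_0, grp != "Mir1", drop = FALSE]))$p.value
  expect_gt(p, 0.01)
})

test_that("adjusted Rand index agrees with pair-counting brute force", {
  # identical partitions up to renaming
  a <- label_vector(paste0("s", 1:6), c(1, 1, 2, 2, 3, 3))
  b <- label_vector(paste0("s", 1:6), c("z", "z", "x", "x", "y", "y"))
  expect_equal(adjusted_rand_index(a, b), 1)
  # one-class coarsening has ARI 0
  expect_equal(adjusted_rand_index(
    label_vector(paste0("s", 1:10), rep(1:2, 5)),
    label_vector(paste0("s", 1:10), rep(1, 10))), 0)
  # 2x2 worked example against the brute-force pair counter
  x <- c(1, 1, 1, 2, 2, 2, 2, 1)
  y <- c(1, 1, 2, 2, 2, 1, 2, 1)
  expect_equal(adjusted_rand_index(x, y), ari_bruteforce(x, y), tolerance = 1e-12)
  # property: random partitions match brute force
  withr::with_seed(71, {
    for (i in 1:20) {
      x <- sample(1:3, 12, TRUE)
      y <- sample(1:4, 12, TRUE)
      expect_equal(adjusted_rand_index(x, y), ari_bruteforce(x, y), tolerance = 1e-12)
    }
  })
  # matching is by sample id, not position
  perm <- sample(6)
  b2 <- label_vector(b$sample_ids[perm], b$labels[perm])
  expect_equal(adjusted_rand_index(a, b2), 1)
  expect_error(adjusted_rand_index(a, label_vector("q1", "x")), "different samples")
})

test_that("confound covariates are bounded and linked to the matrices", {
  co <- mini_cohort(seed = 3)
  cf <- co$confounds
  expect_true(all(cf$muscle_fraction >= 0 & cf$muscle_fraction < 1))
  expect_true(all(cf$hematopoietic_fraction >= 0 & cf$hematopoietic_fraction < 1))
  expect_true(all(cf$library_depth > 0.4 & cf$library_depth < 2.5))
  # muscle contamination raises the muscle module in proportion to fraction
  mus <- colMeans(co$mrna$values[co$modules$muscle, ])
  expect_gt(cor(mus, cf$muscle_fraction), 0.8)
  # library depth drives raw miRNA totals
  expect_gt(cor(colSums(co$mirna$values), cf$library_depth), 0.7)
})
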