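test_that("merging the silenced miRNA subtypes follows the stated mapping", {
  lab <- label_vector(paste0("s", 1:4), c("Mir1", "Mir2", "Mir3", "Mir4"))
  merged <- merge_mirna_classes(lab)
  expect_equal(as.character(merged$labels),
               c("14q32_high", "14q32_low", "14q32_low", "14q32_low"))
  all1 <- merge_mirna_classes(label_vector(paste0("s", 1:3), rep("Mir1", 3)))
  expect_true(all(all1$labels == "14q32_high"))
  expect_length(merge_mirna_classes(label_vector(character(0), character(0))), 0)
  expect_error(merge_mirna_classes(label_vector("s1", "MirX")), "MirX")
})

test_that("linearly separable data trains to perfect accuracy, deterministically", {
  set.seed(60)
  n <- 30
  y <- factor(rep(c("E1", "E2"), each = n / 2))
  v <- named_mat(rnorm(500 * n), 500, n, fprefix = "g")
  v[1:60, y == "E2"] <- v[1:60, y == "E2"] + 3
  m <- toy_matrix(v, "mrna")
  lab <- label_vector(colnames(v), y)
  model <- train_surrogate(m, lab, "mrna:E", n_top = 50)
  pred <- predict(model, m)
  expect_equal(as.character(pred$labels), as.character(y))
  model2 <- train_surrogate(m, lab, "mrna:E", n_top = 50)
  expect_identical(model$weights, model2$weights)
  # prediction is invariant to feature order
  shuf <- m
  ord <- sample(nrow(v))
  shuf$values <- shuf$values[ord, ]
  expect_equal(as.character(predict(model, shuf)$labels), as.character(y))
  expect_error(train_surrogate(m, label_vector(colnames(v),
    factor(c("E1", rep("E2", n - 1)))), "mrna:E"), "at least 2")
})

test_that("three-class one-vs-rest surrogate resolves planted classes", {
  set.seed(61)
  n <- 36
  y <- factor(rep(c("M1", "M2", "M3"), each = 12))
  v <- named_mat(rnorm(600 * n), 600, n, fprefix = "g")
  v[1:40, y == "M2"] <- v[1:40, y == "M2"] + 2.5
  v[41:80, y == "M3"] <- v[41:80, y == "M3"] + 2.5
  m <- toy_matrix(v, "mrna")
  model <- train_surrogate(m, label_vector(colnames(v), y), "methylation:M",
                           n_top = 40)
  expect_equal(as.character(predict(model, m)$labels), as.character(y))
  expect_equal(nrow(model$weights), 3)
})

test_that("cross-validated accuracy is exact on separable data and null on noise", {
  set.seed(62)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  v <- named_mat(rnorm(300 * n), 300, n, fprefix = "g")
  v[1:50, y == "b"] <- v[1:50, y == "b"] + 4
  m <- toy_matrix(v, "mrna")
  lab <- label_vector(colnames(v), y)
  cv <- repeated_cv_accuracy(m, lab, "mrna:E", folds = 5, repeats = 2,
                             n_top = 40, seed = 3)
  expect_equal(cv$mean_accuracy, 1)
  # permuted labels: accuracy near the majority rate (binomial error)
  yperm <- withr::with_seed(9, sample(y))
  cvp <- repeated_cv_accuracy(m, label_vector(colnames(v), yperm), "mrna:E",
                              folds = 5, repeats = 2, n_top = 40, seed = 3)
  expect_lt(cvp$mean_accuracy, 0.75)
  expect_true(cv$mean_accuracy >= 0 && cv$mean_accuracy <= 1)
})

test_that("multi-omics class assignment implements the recursive partitioning", {
  ids <- paste0("s", 1:5)
  e <- label_vector(ids, c("E2", "E1", "E2", "E1", "E1"))
  m <- label_vector(ids, c("M3", "M2", "M1", "M2", "M1"))
  mir <- label_vector(ids, c("14q32_low", "14q32_low", "14q32_high",
                             "14q32_high", "14q32_high"))
  out <- assign_multiomics_class(e, m, mir)
  expect_equal(as.character(out$labels), c("C6", "C5", "C3", "C4", "C1/2"))
  # M3 dominates regardless of the other calls
  out2 <- assign_multiomics_class(
    label_vector("x", "E1"), label_vector("x", "M3"), label_vector("x", "14q32_high"))
  expect_equal(as.character(out2$labels), "C6")
  expect_error(assign_multiomics_class(e, m, label_vector(ids[1:4], rep("14q32_low", 4))),
               "different samples")
  expect_error(assign_multiomics_class(
    label_vector("x", "E9"), label_vector("x", "M1"), label_vector("x", "14q32_low")),
    "unrecognized")
})

test_that("composed surrogate recovers planted multi-omics classes on held-out samples", {
  co <- simulate_cohort(simulation_params(), seed = 1)
  # every sample is predicted while held out once (3 stratified folds), so
  # per-class recall is measured on whole classes
  cls <- as.character(co$truth_multiomics$labels)
  fold <- integer(length(cls))
  for (ix in split(seq_along(cls), cls)) fold[ix] <- rep_len(1:3, length(ix))
  subset_lv <- function(lv, ix) {
    label_vector(lv$sample_ids[ix], lv$labels[ix], lv$scheme_name)
  }
  pv <- character(length(cls))
  for (fo in 1:3) {
    train_i <- which(fold != fo)
    test_i <- which(fold == fo)
    tr <- co$mrna
    tr$values <- tr$values[, train_i]
    held <- co$mrna$values[, test_i]
    me <- train_surrogate(tr, subset_lv(co$truth_e, train_i), "mrna:E")
    mm <- train_surrogate(tr, subset_lv(co$truth_m, train_i), "methylation:M")
    mmir <- train_surrogate(tr, subset_lv(merge_mirna_classes(co$truth_mir), train_i),
                            "mirna:14q32")
    pred <- assign_multiomics_class(predict(me, held), predict(mm, held),
                                    predict(mmir, held))
    pv[test_i] <- as.character(pred$labels)[match(co$truth_multiomics$sample_ids[test_i],
                                                  pred$sample_ids)]
  }
  tv <- as.character(merge_c12(co$truth_multiomics)$labels)
  for (cl in c("C3", "C4", "C5", "C6")) {
    expect_gte(mean(pv[tv == cl] == cl), 0.8)
  }
})
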