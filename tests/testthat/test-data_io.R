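test_that("read_matrix parses TSV matrices and joins annotation", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "beta.tsv")
  writeLines(c("cpg\ts1\ts2",
               "cg1\t0.10\t0.90",
               "cg2\t0.55\t0.45",
               "cg3\t0.00\t1.00"), path)
  m <- read_matrix(path, "methylation")
  expect_s3_class(m, "omics_matrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$values["cg2", "s2"], 0.45)

  # annotation join flags exactly the listed 14q32 features
  mirp <- file.path(dir, "mir.tsv")
  annp <- file.path(dir, "ann.tsv")
  writeLines(c("mir\ta\tb", "m1\t3\t0", "m2\t0\t5", "m3\t9\t9", "m4\t1\t1",
               "m5\t2\t2"), mirp)
  writeLines(c("feature_id\tchromosome\tstart\tis_14q32",
               "m2\t14\t101000000\t1", "m4\t14\t101200000\t1",
               "m1\t3\t5000\t0"), annp)
  mm <- read_matrix(mirp, "mirna", annotation_path = annp)
  expect_equal(mm$annotation$feature_id[mm$annotation$is_14q32], c("m2", "m4"))
})

test_that("read_matrix and the validator reject malformed input", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("id\ts1\ts2", "f1\t1\t2", "f1\t3\t4"), dup)
  expect_error(read_matrix(dup, "mrna"), "f1")
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("id\ts1", "f1\tx"), bad)
  expect_error(read_matrix(bad, "mrna"), "non-numeric")
  meth <- file.path(dir, "m.tsv")
  writeLines(c("id\ts1", "cg1\t1.2"), meth)
  expect_error(read_matrix(meth, "methylation"), "\\[0, 1\\]")
})

test_that("write_outputs round-trips matrices, labels and reports", {
  dir <- withr::local_tempdir()
  set.seed(3)
  cc <- crossprod(matrix(runif(25), 5)) / 5
  cc <- (cc + t(cc)) / 2; diag(cc) <- 1
  dimnames(cc) <- list(paste0("s", 1:5), paste0("s", 1:5))
  lab <- label_vector(paste0("s", 1:4), c("a", "a", "b", "b"), "demo")
  paths <- write_outputs(list(coclass = cc, labels = lab,
                              report = list(seed = 7, k = 3)), dir)
  expect_length(paths, 3)
  back <- as.matrix(readr::read_tsv(file.path(dir, "coclass.tsv"),
                                    show_col_types = FALSE)[, -1])
  expect_lt(max(abs(back - cc)), 1e-12)
  lab_tbl <- readr::read_tsv(file.path(dir, "labels.tsv"), show_col_types = FALSE)
  expect_equal(nrow(lab_tbl), 4)
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(rep$seed, 7)
  expect_error(write_outputs(list(x = 1:3), "/nonexistent-root/xyz"), "writable|serialize")
})

test_that("miRNA detection filter keeps features with >2 counts in >2 samples", {
  counts <- named_mat(c(3, 3, 3, 0, 0,
                        3, 3, 0, 0, 0,
                        2, 2, 2, 2, 2,
                        9, 9, 9, 9, 9), 4, 5, fprefix = "m")
  counts <- t(apply(counts, 1, identity))  # keep dimnames
  m <- toy_matrix(named_mat(t(matrix(c(3, 3, 3, 0, 0,
                                       3, 3, 0, 0, 0,
                                       2, 2, 2, 2, 2,
                                       9, 9, 9, 9, 9), 5, 4)), 4, 5, fprefix = "m"),
                  "mirna")
  filt <- filter_detected_mirnas(m)
  expect_equal(rownames(filt$values), c("m01", "m04"))
  # idempotent, and the step is logged
  expect_equal(filter_detected_mirnas(filt)$values, filt$values)
  expect_true("detection_filter" %in% filt$transform_log)
  neg <- toy_matrix(named_mat(rep(5, 6), 2, 3), "mrna")
  neg$values[1, 1] <- -1
  expect_error(filter_detected_mirnas(neg), "non-negative")
})

test_that("upper-quartile normalization matches direct quartile computation", {
  set.seed(11)
  counts <- named_mat(rnbinom(40 * 6, mu = 50, size = 3), 40, 6, fprefix = "m")
  m <- toy_matrix(counts, "mirna")
  norm <- upper_quartile_normalize(m)
  # per-sample non-zero upper quartiles equal after rescaling (on count scale)
  scaled <- 2^norm$values - 1
  uqs <- apply(scaled, 2, function(x) quantile(x[x > 1e-9], 0.75, type = 7))
  expect_lt(diff(range(uqs)), 1e-6)
  # per-sample rescaling only multiplies the normalized counts by one global
  # factor (the geometric-mean reference absorbs it); structure is invariant
  m2 <- m
  m2$values[, 2] <- m2$values[, 2] * 2
  norm2 <- upper_quartile_normalize(m2)
  ratio <- (2^norm2$values - 1) / (2^norm$values - 1)
  ratio <- ratio[is.finite(ratio) & (2^norm$values - 1) > 1e-9]
  expect_lt(diff(range(ratio)), 1e-9)
  # identical count vectors normalize identically
  m3 <- m
  m3$values[, 3] <- m3$values[, 1]
  norm3 <- upper_quartile_normalize(m3)
  expect_equal(norm3$values[, 3], norm3$values[, 1], ignore_attr = TRUE)
  zero <- m
  zero$values[, 4] <- 0
  expect_error(upper_quartile_normalize(zero), colnames(zero$values)[4])
})

test_that("select_most_variant keeps the top-SD features with nested selections", {
  v <- named_mat(0, 10, 8)
  for (i in 1:10) v[i, ] <- i * seq(-1, 1, length.out = 8)  # SD proportional to i
  m <- toy_matrix(v, "mrna")
  expect_equal(select_most_variant(m, 1)$values, m$values)
  top2 <- select_most_variant(m, 0.2)
  expect_equal(nrow(top2$values), 2)
  expect_setequal(rownames(top2$values), c("f09", "f10"))
  # nesting property over a ladder of fractions
  sel_prev <- character(0)
  for (f in c(0.2, 0.4, 0.7, 1.0)) {
    sel <- rownames(select_most_variant(m, f)$values)
    expect_true(all(sel_prev %in% sel))
    sel_prev <- sel
  }
  # constant features are never selected while any feature varies
  v2 <- v; v2[1, ] <- 5
  expect_false("f01" %in% rownames(select_most_variant(toy_matrix(v2, "mrna"), 0.5)$values))
})

test_that("center_features zero-centers rows without scaling variances", {
  set.seed(8)
  m <- toy_matrix(named_mat(rnorm(30, 5, 2), 5, 6), "mrna")
  cen <- center_features(m)
  expect_lt(max(abs(rowMeans(cen$values))), 1e-12)
  expect_equal(matrixStats::rowSds(cen$values), matrixStats::rowSds(m$values),
               tolerance = 1e-12)
  # idempotence
  expect_equal(center_features(cen)$values, cen$values, tolerance = 1e-12)
  expect_equal(unname(center_features(toy_matrix(named_mat(c(1, 2, 3), 1, 3), "mrna"))$values[1, ]),
               c(-1, 0, 1))
})

test_that("pearson_distance matches direct correlation computation", {
  set.seed(2)
  v <- named_mat(rnorm(24), 8, 3)
  d <- pearson_distance(v)
  expect_equal(d[1, 2], 1 - cor(v[, 1], v[, 2]), tolerance = 1e-12)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  v2 <- cbind(v, v[, 1], -scale(v[, 1], scale = FALSE)[, 1] + mean(v[, 1]))
  colnames(v2) <- paste0("s", 1:5)
  d2 <- pearson_distance(v2)
  expect_equal(d2[1, 4], 0, tolerance = 1e-12)        # identical columns
  expect_equal(d2[1, 5], 2, tolerance = 1e-12)        # perfect anticorrelation
  v3 <- v; v3[, 2] <- 7
  expect_error(pearson_distance(v3), "s02")
})
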