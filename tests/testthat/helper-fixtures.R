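# shared fixture builders; everything is generated in code at test time

toy_matrix <- function(values, kind = "mrna", ann = NULL) {
  omics_matrix(values, kind, feature_annotation = ann)
}

# deterministic numeric matrix with dimnames
named_mat <- function(x, nr, nc, fprefix = "f", sprefix = "s") {
  matrix(x, nr, nc, dimnames = list(sprintf("%s%02d", fprefix, seq_len(nr)),
                                    sprintf("%s%02d", sprefix, seq_len(nc))))
}

# block-structured co-classification matrix from a membership vector
block_coclass <- function(membership, ids = sprintf("s%02d", seq_along(membership))) {
  m <- outer(membership, membership, function(a, b) as.numeric(a == b))
  dimnames(m) <- list(ids, ids)
  m
}

# two well-separated sample groups in feature space
blob_matrix <- function(n_features = 60, n1 = 8, n2 = 8, shift = 4, sd = 0.3,
                        seed = 42) {
  withr::with_seed(seed, {
    half <- n_features %/% 2
    base <- matrix(rnorm(n_features * (n1 + n2), 0, sd), n_features, n1 + n2)
    base[seq_len(half), seq_len(n1)] <- base[seq_len(half), seq_len(n1)] + shift
    base[(half + 1):n_features, n1 + seq_len(n2)] <-
      base[(half + 1):n_features, n1 + seq_len(n2)] + shift
    named_mat(base, n_features, n1 + n2)
  })
}

# small synthetic cohort for unit tests (fewer features, same samples/classes)
mini_cohort <- function(seed = 1) {
  simulate_cohort(simulation_params(n_mrna = 600, n_mirna = 300, n_cpg = 800,
                                    n_14q32 = 60), seed = seed)
}

# brute-force ARI from pair counting, used as the independent oracle
ari_bruteforce <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  tot <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - expected) / (maxi - expected)
}

# exhaustive PAM oracle: best medoid set over all combinations
pam_bruteforce <- function(d, k) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  costs <- apply(combs, 2, function(med) {
    sum(apply(d[, med, drop = FALSE], 1, min))
  })
  min(costs)
}
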