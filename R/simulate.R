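#' Parameters of the synthetic multi-omics cohort
#'
#' The generator's stated world: a 102-tumor cohort carrying six multi-omics
#' classes of sizes 18/19/15/19/20/11 whose structure mirrors the biology the
#' pipeline targets — a quiescent-vs-mitotic mRNA axis (differentiation and
#' proliferation gene modules), graded regional silencing of a 102-member
#' 14q32 microRNA cluster, and genome-wide CpG-island hypermethylation in
#' IDH-mutant classes with an extra dedifferentiated methylation block —
#' plus non-neoplastic contamination (muscle and hematopoietic admixture
#' that dilutes tumor signal in proportion to the contaminated fraction),
#' an array batch covariate, and a 4-fold miRNA library-depth gradient.
#'
#' Latent class attributes (mitotic, IDH-mutant, 14q32 silencing grade,
#' dedifferentiated): C1/C2 (0,0,0,0), C3 (1,0,0,0), C4 (0,1,0,0),
#' C5 (1,1,2,0), C6 (1,1,3,1). In addition `n_mir2` samples drawn from
#' C1/C2 carry silencing grade 1, reproducing the loose nesting of the real
#' cohort where the silenced miRNA classes exceed the IDH-mutant classes;
#' the four planted miRNA classes are the four grades. Every latent program
#' varies continuously between tumors (proportional heterogeneity), so class
#' margins reach toward zero as in real cohorts, while the class archetypes
#' remain the ground truth. C1 and C2 are molecularly indistinguishable by
#' construction and are merged for evaluation.
#'
#' Each silencing grade represses the two genomic segments of the 14q32
#' cluster to a grade-specific depth and additionally represses its own
#' small set of non-14q32 microRNAs, so grades differ in pattern (which a
#' correlation distance can resolve), not only in magnitude, and the class
#' median of 14q32 expression decreases strictly with grade.
#'
#' @param n_mrna,n_mirna,n_cpg Feature counts (2000 / 800 / 5000).
#' @param n_14q32 Number of miRNAs in the 14q32 cluster (102).
#' @param class_sizes Named integer vector over C1..C6 summing to the cohort
#'   size.
#' @param n_mir2 Size of the grade-1 (mild silencing) subset inside C1/C2.
#' @param n_c3_silenced Number of C3 tumors with incipient sub-grade
#'   silencing (default 0; kept for sensitivity experiments).
#' @param attribute_cv Coefficient of variation of each latent program
#'   around its class archetype (heterogeneity is proportional to activity).
#' @param attribute_floor Small activity-independent heterogeneity floor.
#' @param diff_shift,prolif_shift log2 shifts of the differentiation and
#'   proliferation gene modules along the mitotic axis.
#' @param dediff_extra,dediff_shift Extra differentiation loss and
#'   dedifferentiation-module shift in C6.
#' @param idh_shift mRNA shift of the IDH/glycolytic module.
#' @param ecm_shift log2 mRNA downshift of the extracellular-matrix module
#'   per unit 14q32 silencing grade.
#' @param silencing_per_grade Global scale of the per-grade 14q32 silencing
#'   profiles (1 = the documented depths; 0 disables silencing).
#' @param hyper_delta Hypermethylation shift (M-value scale) on 40% of CpGs
#'   in IDH-mutant samples.
#' @param dediff_meth_delta M-value shift of the dedifferentiated CpG block.
#' @param muscle_strength,hematopoietic_strength Contamination strength:
#'   scales the prevalence and upper bound of the per-sample contaminated
#'   fractions and, for muscle, the tissue-signature amplitude.
#'   1 = the default cohort; 2 = the ablation world.
#' @param batch_strength mRNA/methylation batch effect size (log2 / M).
#' @param mrna_noise_sd,meth_noise_sd Gaussian noise SDs (log2 / M-value).
#' @param nb_size Negative-binomial size (dispersion) of miRNA counts.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_mrna = 2000, n_mirna = 800, n_cpg = 5000,
                              n_14q32 = 102,
                              class_sizes = c(C1 = 18, C2 = 19, C3 = 15,
                                              C4 = 19, C5 = 20, C6 = 11),
                              n_mir2 = 10, n_c3_silenced = 0,
                              attribute_cv = 0.25, attribute_floor = 0.08,
                              diff_shift = 1.8, prolif_shift = 1.8,
                              dediff_extra = 0.6, dediff_shift = 0.7,
                              idh_shift = 0.65, ecm_shift = 0.2,
                              silencing_per_grade = 1.0,
                              hyper_delta = 1.1, dediff_meth_delta = 1.6,
                              muscle_strength = 1.0,
                              hematopoietic_strength = 0.8,
                              batch_strength = 0.3,
                              mrna_noise_sd = 0.8, meth_noise_sd = 0.5,
                              nb_size = 5) {
  p <- as.list(environment())
  if (any(p$class_sizes < 0) || length(p$class_sizes) != 6) {
    stop("class_sizes must be six non-negative counts", call. = FALSE)
  }
  sizes_ok <- c("diff_shift", "prolif_shift", "dediff_extra", "dediff_shift",
                "idh_shift", "ecm_shift", "silencing_per_grade", "hyper_delta",
                "dediff_meth_delta", "muscle_strength", "hematopoietic_strength",
                "batch_strength")
  if (any(unlist(p[sizes_ok]) < 0)) stop("effect sizes must be >= 0", call. = FALSE)
  structure(p, class = "simulation_params")
}

#' Simulate a linked multi-omics chondrosarcoma-like cohort
#'
#' Generates mRNA log intensities, raw miRNA counts and methylation beta
#' values over a shared sample set with planted subtype structure, ground
#' truth per-omics and multi-omics labels, and confound covariates.
#' Bitwise reproducible for a fixed `params`/`seed`.
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer seed.
#' @return A `synthetic_cohort`: list with `mrna`, `mirna`, `methylation`
#'   ([omics_matrix()] triple), `truth_multiomics`, `truth_e`, `truth_m`,
#'   `truth_mir` ([label_vector()]s), `confounds` (tibble with
#'   `muscle_fraction`, `hematopoietic_fraction`, `batch`, `library_depth`),
#'   `modules` (feature id sets of the planted gene modules), `params`,
#'   `seed`.
#' @export
simulate_cohort <- function(params = simulation_params(), seed = 1L) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  n <- sum(p$class_sizes)
  # independent RNG streams per section: a change to one omics' parameters
  # leaves the others' random draws untouched
  sub_seed <- function(offset) as.integer((seed * 97L + offset) %% 2147483647L)
  sample_ids <- sprintf("CS%03d", seq_len(n))
  cls <- rep(names(p$class_sizes), p$class_sizes)

  mitotic <- as.numeric(cls %in% c("C3", "C5", "C6"))
  idh_mut <- as.numeric(cls %in% c("C4", "C5", "C6"))
  dediff <- as.numeric(cls == "C6")
  grade <- numeric(n)
  grade[cls == "C5"] <- 2
  grade[cls == "C6"] <- 3
  # loose nesting: a fixed-size subset of the quiescent IDH-wt classes
  # carries mild (grade 1) 14q32 silencing, as in the real cohort where the
  # silenced miRNA classes exceed the IDH-mutant classes
  half <- p$n_mir2 %/% 2
  mir2_idx <- c(which(cls == "C1")[seq_len(half)],
                which(cls == "C2")[seq_len(p$n_mir2 - half)])
  grade[mir2_idx] <- 1
  # a couple of mitotic IDH-wt tumors carry incipient (sub-grade) 14q32
  # silencing: molecularly discordant cases whose omics point in different
  # directions, as real cohorts contain
  grade[which(cls == "C3")[seq_len(p$n_c3_silenced)]] <- 1.2
  # continuous tumor-to-tumor heterogeneity around the class archetypes:
  # each latent program varies in proportion to its activity (plus a small
  # floor), so per-class margins reach down to zero at the class boundaries
  # as in real cohorts while inactive programs stay quiet; class labels
  # (the truth) remain the archetypes
  withr::local_seed(sub_seed(2L))
  het <- function(x, cv = p$attribute_cv) {
    x * (1 + stats::rnorm(n, 0, cv)) + p$attribute_floor * stats::rnorm(n)
  }
  mitotic_eff <- het(mitotic)
  idh_eff <- het(idh_mut)
  dediff_eff <- het(dediff, 0.8 * p$attribute_cv)
  grade_eff <- pmax(0, het(grade, 0.3 * p$attribute_cv))

  # confound covariates; contamination acts as an admixture: the observed
  # profile is purity * tumor + fraction * tissue, so heavy contamination
  # dilutes class identity rather than adding an orthogonal signal
  withr::local_seed(sub_seed(1L))
  muscle <- pmin(0.25 + 0.13 * p$muscle_strength,
                 stats::rbeta(n, 0.25 * p$muscle_strength, 2.5 / p$muscle_strength))
  hemat <- pmin(0.19 + 0.13 * p$hematopoietic_strength,
                stats::rbeta(n, 0.2 * p$hematopoietic_strength, 3.5 / p$hematopoietic_strength))
  purity <- pmax(0.05, 1 - muscle - hemat)
  purity_meth <- pmax(0.05, 1 - hemat)   # muscle barely affects the methylome
  batch <- rep_len(c(1L, 2L), n)

  ## ---- mRNA ----
  withr::local_seed(sub_seed(3L))
  # module sizes scale with the gene count (fractions match 2000 genes:
  # 200/200/150/150/100/200/150/300)
  mod_sizes <- round(p$n_mrna * c(differentiation = 0.100, proliferation = 0.100,
                                  idh_glycolytic = 0.075, ecm = 0.075,
                                  dediff = 0.050, muscle = 0.100,
                                  hematopoietic = 0.075, batch = 0.150))
  ends <- cumsum(mod_sizes)
  mods <- Map(function(a, b) seq.int(a, b), ends - mod_sizes + 1L, ends)
  gid <- sprintf("gene_%04d", seq_len(p$n_mrna))
  base_g <- stats::rnorm(p$n_mrna, 7, 1.5)
  mrna <- matrix(stats::rnorm(p$n_mrna * n, 0, p$mrna_noise_sd), p$n_mrna, n,
                 dimnames = list(gid, sample_ids)) + base_g
  load_of <- function(k) 0.4 + 0.8 * stats::rexp(k)   # heavy-tailed effect sizes
  add <- function(m, rows, per_sample) {
    m[rows, ] <- m[rows, ] + outer(load_of(length(rows)), per_sample)
    m
  }
  mrna <- add(mrna, mods$differentiation,
              -purity * (p$diff_shift * mitotic_eff + p$dediff_extra * dediff_eff))
  mrna <- add(mrna, mods$proliferation, purity * p$prolif_shift * mitotic_eff)
  mrna <- add(mrna, mods$idh_glycolytic, purity * p$idh_shift * idh_eff)
  mrna <- add(mrna, mods$ecm, -purity * p$ecm_shift * grade_eff)
  mrna <- add(mrna, mods$dediff, purity * p$dediff_shift * dediff_eff)
  mrna <- add(mrna, mods$muscle, 2.4 * p$muscle_strength * muscle)
  mrna <- add(mrna, mods$hematopoietic, 2.0 * hemat)
  mrna <- add(mrna, mods$batch, p$batch_strength * (batch == 2L))
  mrna_ann <- tibble::tibble(feature_id = gid,
                             chromosome = sample(c(1:22), p$n_mrna, TRUE),
                             start = round(stats::runif(p$n_mrna, 1e5, 2e8)),
                             is_14q32 = FALSE)

  ## ---- miRNA ----
  withr::local_seed(sub_seed(4L))
  depth <- 2^stats::runif(n, -1, 1)
  # Each silenced grade carries a pattern-distinct profile: two segments of
  # the 14q32 cluster are repressed to grade-specific depths (regional
  # silencing progresses along the locus) and each grade additionally
  # represses its own small set of non-14q32 microRNAs, the deepest grade
  # most strongly. Depths are chosen so the class median of 14q32
  # expression decreases strictly with grade.
  mir_id <- sprintf("mir_%04d", seq_len(p$n_mirna))
  is14 <- seq_len(p$n_mirna) <= p$n_14q32
  base_mu <- stats::rlnorm(p$n_mirna, meanlog = log(40), sdlog = 1.3)
  base_mu[is14] <- stats::rlnorm(p$n_14q32, meanlog = log(200), sdlog = 0.8)
  n_a <- round(0.6 * p$n_14q32)                   # proximal segment
  seg_a <- seq_len(n_a)
  seg_b <- (n_a + 1):p$n_14q32
  extra <- lapply(c(25, 25, 30), function(k) integer(k))
  extra[[1]] <- p$n_14q32 + 1:25
  extra[[2]] <- p$n_14q32 + 26:50
  extra[[3]] <- p$n_14q32 + 51:80
  # rows: grades 1..3; columns: segment A, segment B, extra module (log2)
  prof <- rbind(c(1.5, 0.4, 1.5),
                c(1.6, 2.4, 1.4),
                c(2.6, 1.0, 2.2)) * p$silencing_per_grade
  prof0 <- rbind(c(0, 0, 0), prof)        # grade-0 row for interpolation
  mir_load <- 0.4 + 0.8 * stats::rexp(p$n_mirna)   # per-miRNA silencing depth
  lfc <- matrix(0, p$n_mirna, n)
  for (s in seq_len(n)) {
    g <- min(grade_eff[s], 3)
    lo <- floor(g); hi <- ceiling(g); fr <- g - lo
    pr <- (1 - fr) * prof0[lo + 1, ] + fr * prof0[hi + 1, ]
    lfc[seg_a, s] <- -pr[1] * mir_load[seg_a]
    lfc[seg_b, s] <- -pr[2] * mir_load[seg_b]
    # the extra module of the nearest nonzero grade, dosage-scaled
    gx <- if (fr > 0.5 || lo == 0) hi else lo
    if (gx >= 1) lfc[extra[[gx]], s] <- -pr[3] * mir_load[extra[[gx]]]
  }
  mu <- (base_mu * 2^lfc) * rep(depth, each = p$n_mirna)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = p$nb_size),
                   p$n_mirna, n, dimnames = list(mir_id, sample_ids))
  mir_ann <- tibble::tibble(
    feature_id = mir_id,
    chromosome = ifelse(is14, 14L, sample(c(1:13, 15:22), p$n_mirna, TRUE)),
    start = ifelse(is14, 101e6 + seq_len(p$n_mirna) * 1e3,
                   round(stats::runif(p$n_mirna, 1e5, 2e8))),
    is_14q32 = is14
  )

  ## ---- methylation (simulated on the M-value scale) ----
  withr::local_seed(sub_seed(5L))
  cg_id <- sprintf("cg_%05d", seq_len(p$n_cpg))
  n_hyper <- round(0.4 * p$n_cpg)
  hyper_idx <- seq_len(n_hyper)
  dediff_idx <- n_hyper + seq_len(round(0.1 * p$n_cpg))
  hemat_idx <- max(dediff_idx) + seq_len(round(0.1 * p$n_cpg))
  meth_batch_idx <- max(hemat_idx) + seq_len(round(0.06 * p$n_cpg))
  base_c <- stats::rnorm(p$n_cpg, -1, 1.5)
  mval <- matrix(stats::rnorm(p$n_cpg * n, 0, p$meth_noise_sd), p$n_cpg, n,
                 dimnames = list(cg_id, sample_ids)) + base_c
  idh_meth_eff <- idh_mut * (1 + stats::rnorm(n, 0, 0.06)) +
    0.04 * stats::rnorm(n)                 # tighter dose spread than mRNA
  mval <- add(mval, hyper_idx, purity_meth * p$hyper_delta * idh_meth_eff)
  mval <- add(mval, dediff_idx, purity_meth * p$dediff_meth_delta * dediff_eff)
  mval <- add(mval, hemat_idx, 1.0 * hemat)
  mval <- add(mval, meth_batch_idx, 0.6 * p$batch_strength * (batch == 2L))
  beta <- stats::plogis(mval)
  meth_ann <- tibble::tibble(feature_id = cg_id,
                             chromosome = sample(c(1:22), p$n_cpg, TRUE),
                             start = round(stats::runif(p$n_cpg, 1e5, 2e8)),
                             is_14q32 = FALSE)

  truth_mir_lab <- paste0("Mir", round(grade) + 1)
  structure(list(
    mrna = omics_matrix(mrna, "mrna", mrna_ann),
    mirna = omics_matrix(counts, "mirna", mir_ann),
    methylation = omics_matrix(beta, "methylation", meth_ann),
    truth_multiomics = label_vector(sample_ids, factor(cls), "multiomics:C"),
    truth_e = label_vector(sample_ids,
                           factor(ifelse(mitotic == 1, "E2", "E1")), "mrna:E"),
    truth_m = label_vector(sample_ids, factor(dplyr::case_when(
      dediff == 1 ~ "M3", idh_mut == 1 ~ "M2", TRUE ~ "M1")), "methylation:M"),
    truth_mir = label_vector(sample_ids,
                             factor(truth_mir_lab,
                                    levels = paste0("Mir", 1:4)), "mirna:Mir"),
    confounds = tibble::tibble(sample_id = sample_ids,
                               muscle_fraction = muscle,
                               hematopoietic_fraction = hemat,
                               batch = batch, library_depth = depth),
    modules = lapply(mods, function(i) gid[i]),
    params = p, seed = as.integer(seed)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (seed %d)\n",
              length(x$truth_multiomics$sample_ids), x$seed))
  cat(sprintf("  mrna %d x %d, mirna %d x %d, methylation %d x %d\n",
              nrow(x$mrna$values), ncol(x$mrna$values),
              nrow(x$mirna$values), ncol(x$mirna$values),
              nrow(x$methylation$values), ncol(x$methylation$values)))
  invisible(x)
}

#' Merge the C1/C2 classes of a multi-omics truth
#'
#' C1 and C2 are indistinguishable from the three molecular levels; this
#' helper collapses them for evaluation.
#'
#' @param labels A [label_vector()] with classes among C1..C6.
#' @return A [label_vector()] where C1 and C2 become `"C1/2"`.
#' @export
merge_c12 <- function(labels) {
  lv <- as.character(labels$labels)
  lv[lv %in% c("C1", "C2")] <- "C1/2"
  label_vector(labels$sample_ids, factor(lv), labels$scheme_name)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions (up
#' to class renaming), expectation 0 under independent random labelings.
#' Label vectors are matched by sample id.
#'
#' @param a,b [label_vector()]s over the same samples, or plain vectors of
#'   equal length.
#' @return The ARI, a real number `<= 1`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (inherits(a, "label_vector") && inherits(b, "label_vector")) {
    if (!setequal(a$sample_ids, b$sample_ids)) {
      stop("label vectors cover different samples", call. = FALSE)
    }
    bv <- b$labels[match(a$sample_ids, b$sample_ids)]
    av <- a$labels
  } else {
    if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
    av <- a; bv <- b
  }
  tab <- table(av, bv)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}
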