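#' Pipeline configuration
#'
#' Assembles the full configuration of [run_pipeline()] with the reference
#' defaults: ICA on the 50% most-variant features for mRNA and methylation
#' and on all detected miRNAs; 20% of features removed per flagged
#' component; consensus clustering with 1000 feature-resampling iterations
#' on the 20% most-variant features (50% for miRNA), k in 2..9; PAM
#' consensus with dispersion-based K selection for the integration; and the
#' three mRNA surrogate classifiers evaluated by 10x10 stratified
#' cross-validation.
#'
#' @param seed Integer seed; mandatory, drives every stage through
#'   documented per-stage offsets.
#' @param inputs Either a `synthetic_cohort` or a named list of file paths
#'   (`mrna`, `mirna`, `methylation`, optionally `mirna_annotation`).
#' @param out_dir Optional output directory for artifacts and the JSON run
#'   report.
#' @param ica Per-stage settings: `m_max`, `fractions` (named per omics),
#'   `removal_fraction`, `unwanted` (named list of component indices, or
#'   `"auto"` to flag components by correlation with the confound
#'   covariates), `auto_threshold`.
#' @param consensus `n_iterations`, `k_range`, `feature_subsample`,
#'   `variant_fractions` (named per omics).
#' @param integration `n_iterations`, `sample_subsample`, `k_rule`.
#' @param surrogate `cost`, `folds`, `repeats`, `n_top`, `fdr`,
#'   `select_once`, `run_cv`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, inputs, out_dir = NULL,
                            ica = list(), consensus = list(),
                            integration = list(), surrogate = list()) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("an integer `seed` is mandatory (no silent nondeterminism)", call. = FALSE)
  }
  ica <- utils::modifyList(list(
    m_max = 10,
    fractions = c(mrna = 0.5, mirna = 1.0, methylation = 0.5),
    removal_fraction = 0.2, unwanted = "auto", auto_threshold = 0.6), ica)
  consensus <- utils::modifyList(list(
    n_iterations = 1000, k_range = 2:9, feature_subsample = 0.8,
    variant_fractions = c(mrna = 0.2, mirna = 0.5, methylation = 0.2)), consensus)
  integration <- utils::modifyList(list(
    n_iterations = 1000, sample_subsample = 0.8, k_rule = "argmax"), integration)
  surrogate <- utils::modifyList(list(
    cost = 1, folds = 10, repeats = 10, n_top = 200, fdr = 0.05,
    select_once = FALSE, run_cv = TRUE), surrogate)
  frac_ok <- c(ica$fractions, ica$removal_fraction, consensus$variant_fractions,
               consensus$feature_subsample, integration$sample_subsample)
  if (any(frac_ok <= 0 | frac_ok > 1)) {
    stop("all fractions must lie in (0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), inputs = inputs, out_dir = out_dir,
                 ica = ica, consensus = consensus, integration = integration,
                 surrogate = surrogate),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path Path to a JSON file mirroring the arguments of
#'   [pipeline_config()]; `inputs` must be a named list of file paths.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

# per-stage seed offsets so stages are independently reproducible
.stage_seed <- function(seed, stage) {
  offsets <- c(ica = 11L, consensus_mrna = 21L, consensus_mirna = 22L,
               consensus_methylation = 23L, integration = 31L, surrogate = 41L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full subtyping workflow
#'
#' Executes, per omics: preprocessing (miRNA detection filter and
#' upper-quartile normalization), ICA with data-driven component-count
#' selection, removal of features associated with flagged non-neoplastic or
#' technical components, and feature-resampled consensus clustering with
#' cophenetic K selection. Then integrates the per-omics co-classification
#' matrices (average, PAM consensus, dispersion K selection) and, if
#' requested, trains and cross-validates the three mRNA surrogate
#' classifiers and derives the multi-omics class of every sample from their
#' predictions.
#'
#' Any stage failure aborts with the stage name and cause. The run is
#' idempotent for a fixed configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: list with `omics` (per-omics list of
#'   `decomposition`, `unwanted`, `consensus`), `integration`
#'   (`similarity`, `consensus`), `surrogate` (models, CV table, predicted
#'   multi-omics classes) and `report` (plain list, also written as JSON when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  inputs <- config$inputs
  matrices <- stage("load_inputs", {
    if (inherits(inputs, "synthetic_cohort")) {
      list(mrna = inputs$mrna, mirna = inputs$mirna,
           methylation = inputs$methylation,
           confounds = inputs$confounds)
    } else {
      need <- c("mrna", "mirna", "methylation")
      miss <- setdiff(need, names(inputs))
      if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
      list(mrna = read_matrix(inputs$mrna, "mrna"),
           mirna = read_matrix(inputs$mirna, "mirna",
                               annotation_path = inputs$mirna_annotation),
           methylation = read_matrix(inputs$methylation, "methylation"),
           confounds = NULL)
    }
  })

  omics_results <- list()
  report_omics <- list()
  for (om in c("mrna", "mirna", "methylation")) {
    mat <- matrices[[om]]
    if (om == "mirna") {
      mat <- stage("mirna_preprocess",
                   upper_quartile_normalize(filter_detected_mirnas(mat)))
    }
    res <- stage(paste0("ica_", om), {
      sel <- if (config$ica$fractions[[om]] < 1) {
        select_most_variant(mat, config$ica$fractions[[om]])
      } else mat
      sel <- center_features(sel)
      curve <- component_count_curve(sel, config$ica$m_max,
                                     seed = .stage_seed(config$seed, "ica"))
      m <- select_component_count(curve)
      decomp <- fit_ica(sel, m, seed = .stage_seed(config$seed, "ica"))
      decomp$selection_curve <- curve
      unwanted <- config$ica$unwanted
      unwanted <- if (identical(unwanted, "auto")) {
        flag_confounded_components(decomp, matrices$confounds,
                                   threshold = config$ica$auto_threshold)
      } else {
        as.integer(unwanted[[om]] %||% integer(0))
      }
      cleaned <- remove_confounded_features(sel, decomp, unwanted,
                                            fraction = config$ica$removal_fraction)
      list(decomposition = decomp, unwanted = unwanted, cleaned = cleaned)
    })
    cons <- stage(paste0("consensus_", om), {
      run_consensus(res$cleaned,
                    k_range = config$consensus$k_range,
                    n_iterations = config$consensus$n_iterations,
                    variant_fraction = config$consensus$variant_fractions[[om]],
                    feature_subsample = config$consensus$feature_subsample,
                    seed = .stage_seed(config$seed, paste0("consensus_", om)))
    })
    omics_results[[om]] <- list(decomposition = res$decomposition,
                                unwanted = res$unwanted, consensus = cons)
    report_omics[[om]] <- list(
      n_features_input = nrow(mat$values),
      n_features_after_removal = nrow(res$cleaned$values),
      n_components = res$decomposition$n_components,
      unwanted_components = res$unwanted,
      selection_curve = as.list(res$decomposition$selection_curve),
      selected_k = cons$selected_k,
      k_curve = as.list(cons$k_curve)
    )
  }

  integration <- stage("integration", {
    sim <- average_coclassification(lapply(omics_results, `[[`, "consensus"))
    cons <- run_pam_consensus(sim,
                              k_range = config$consensus$k_range,
                              n_iterations = config$integration$n_iterations,
                              sample_subsample = config$integration$sample_subsample,
                              seed = .stage_seed(config$seed, "integration"),
                              k_rule = config$integration$k_rule)
    list(similarity = sim, consensus = cons)
  })

  surrogate <- stage("surrogate", {
    mrna <- matrices$mrna
    sc <- config$surrogate
    # the recursive-partitioning diagram is defined on the two-class
    # expression, three-class methylation and merged four-class miRNA
    # systems, so the surrogate schemes use those cuts (the selected-K
    # classifications remain available in the consensus results)
    schemes <- list(
      "mrna:E" = relabel_scheme_at(omics_results$mrna$consensus, 2L, "E"),
      "methylation:M" = relabel_scheme_at(omics_results$methylation$consensus, 3L, "M"),
      "mirna:14q32" = merge_mirna_classes(
        relabel_scheme_at(omics_results$mirna$consensus, 4L, "Mir"))
    )
    models <- purrr::imap(schemes, function(lab, sch) {
      # consensus occasionally emits singleton classes on small cohorts;
      # they cannot be learned and are excluded from training
      keep_cls <- names(which(table(lab$labels) >= 2))
      keep <- as.character(lab$labels) %in% keep_cls
      sub_m <- mrna
      sub_m$values <- sub_m$values[, lab$sample_ids[keep], drop = FALSE]
      train_surrogate(sub_m,
                      label_vector(lab$sample_ids[keep],
                                   factor(as.character(lab$labels)[keep]), sch),
                      sch, cost = sc$cost, n_top = sc$n_top, fdr = sc$fdr)
    })
    cv <- if (isTRUE(sc$run_cv)) {
      purrr::imap_dfr(schemes, function(lab, sch) {
        repeated_cv_accuracy(mrna, lab, sch, folds = sc$folds,
                             repeats = sc$repeats,
                             seed = .stage_seed(config$seed, "surrogate"),
                             cost = sc$cost, n_top = sc$n_top, fdr = sc$fdr,
                             select_once = sc$select_once)
      })
    } else NULL
    preds <- purrr::map2(models, names(models),
                         function(mod, sch) predict(mod, mrna))
    multi <- assign_multiomics_class(preds[["mrna:E"]],
                                     preds[["methylation:M"]],
                                     preds[["mirna:14q32"]])
    list(models = models, cv = cv, predictions = preds, multiomics = multi)
  })

  report <- list(
    seed = config$seed,
    omics = report_omics,
    integration = list(selected_k = integration$consensus$selected_k,
                       dispersion_curve = as.list(integration$consensus$k_curve)),
    surrogate_cv = if (!is.null(surrogate$cv)) as.list(surrogate$cv) else NULL,
    package_version = as.character(utils::packageVersion("chondroclass")),
    r_version = R.version.string
  )
  result <- structure(list(omics = omics_results, integration = integration,
                           surrogate = surrogate, report = report),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    objs <- list(report = report,
                 multiomics_similarity = integration$similarity$similarity,
                 multiomics_labels = integration$consensus$labels[[
                   as.character(integration$consensus$selected_k)]],
                 surrogate_multiomics = surrogate$multiomics)
    for (om in names(omics_results)) {
      cc <- omics_results[[om]]$consensus
      objs[[paste0(om, "_coclassification_k", cc$selected_k)]] <-
        cc$coclassification[[as.character(cc$selected_k)]]
      objs[[paste0(om, "_labels")]] <- cc$labels[[as.character(cc$selected_k)]]
    }
    write_outputs(objs, config$out_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (om in names(x$omics)) {
    cat(sprintf("  %s: %d components, selected K = %d\n", om,
                x$omics[[om]]$decomposition$n_components,
                x$omics[[om]]$consensus$selected_k))
  }
  cat(sprintf("  integration: selected K = %d\n",
              x$integration$consensus$selected_k))
  invisible(x)
}

#' Flag components correlated with known confound covariates
#'
#' Marks every independent component whose sample projection correlates with
#' any numeric confound covariate (muscle fraction, hematopoietic fraction,
#' batch, library depth) beyond a threshold — the automated stand-in for the
#' manual annotation of non-neoplastic and technical components.
#'
#' @param decomp A `component_decomposition`.
#' @param confounds Data frame with `sample_id` and numeric covariate
#'   columns, or `NULL` (returns no flags).
#' @param threshold Absolute Pearson correlation cutoff, default 0.6.
#' @return Integer vector of flagged component indices.
#' @export
flag_confounded_components <- function(decomp, confounds, threshold = 0.6) {
  if (is.null(confounds)) return(integer(0))
  proj <- decomp$sample_projections
  cov <- confounds[match(colnames(proj), confounds$sample_id), , drop = FALSE]
  num <- cov[vapply(cov, is.numeric, logical(1))]
  flags <- integer(0)
  for (k in seq_len(nrow(proj))) {
    r <- vapply(num, function(x) abs(stats::cor(proj[k, ], x)), numeric(1))
    if (any(r > threshold)) flags <- c(flags, k)
  }
  flags
}

# rename consensus classes at the selected K to a scheme prefix (E1, E2, ...)
relabel_scheme <- function(consensus, prefix) {
  relabel_scheme_at(consensus, consensus$selected_k, prefix)
}

relabel_scheme_at <- function(consensus, k, prefix) {
  lab <- consensus$labels[[as.character(k)]]
  label_vector(lab$sample_ids,
               factor(paste0(prefix, as.integer(lab$labels))),
               paste0(consensus$scheme_prefix, ":", prefix))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
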