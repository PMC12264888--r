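#' Pipeline run configuration
#'
#' Collects every tunable of the analysis with defaults matching the
#' conventional settings: 20 latent variables computed, 5 retained; VIP
#' threshold 1.5 with top 50 features for connectivity models and top 30
#' otherwise; rescaled |beta| threshold 0.2 with support required in at
#' least 2 modalities for unique calls; consensus at >= 4 models with a
#' core set at >= 6. The configuration is hash-stamped into every output.
#'
#' @param modalities modality tags to analyse.
#' @param n_components latent variables computed (default 20).
#' @param n_retained latent variables retained for VIP/regression
#'   (default 5).
#' @param vip_threshold VIP cut (default 1.5).
#' @param beta_threshold rescaled |beta| cut (default 0.2).
#' @param min_models consensus threshold (default 4).
#' @param min_models_core core-consensus threshold (default 6).
#' @param min_modalities unique-call support (default 2).
#' @param min_variant minimum number of subjects whose feature value
#'   must deviate from the feature's median for the feature to enter a
#'   model (default 5). This is the usual minimum-lesion-affection
#'   criterion generalized to any feature: zero-inflated regions damaged
#'   in only a couple of subjects have no estimable variance inside
#'   leave-one-out folds and destabilize standardized predictions. The
#'   criterion uses X only, so applying it once on the full data leaks
#'   nothing about the responses.
#' @param selection_modes VIP-restricted CV protocols to run.
#' @param seed seed recorded in outputs.
#' @return a `run_config` list with a `hash` field.
#' @export
run_config <- function(modalities = modality_registry()$modality,
                       n_components = 20, n_retained = 5,
                       vip_threshold = 1.5, beta_threshold = 0.2,
                       min_models = 4, min_models_core = 6,
                       min_modalities = 2, min_variant = 5,
                       selection_modes = c("nested", "paper"),
                       seed = 1L) {
  if (n_retained > n_components)
    stopf("n_retained (%d) must not exceed n_components (%d)",
          n_retained, n_components)
  if (vip_threshold <= 0 || beta_threshold <= 0)
    stopf("thresholds must be positive")
  cfg <- list(modalities = modalities,
              n_components = as.integer(n_components),
              n_retained = as.integer(n_retained),
              vip_threshold = vip_threshold,
              beta_threshold = beta_threshold,
              min_models = as.integer(min_models),
              min_models_core = as.integer(min_models_core),
              min_modalities = as.integer(min_modalities),
              min_variant = as.integer(min_variant),
              selection_modes = match.arg(selection_modes,
                                          c("nested", "paper"),
                                          several.ok = TRUE),
              seed = as.integer(seed))
  cfg$hash <- fnv1a_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full shared/unique decomposition pipeline
#'
#' Chains [run_all_modalities()], [consensus_shared()] (at both the
#' consensus and core thresholds), [call_unique_regions()] and
#' [residual_variance_analysis()] (shared predictors = the top 4 core
#' regions by model count, ties broken by mean VIP rank). When the
#' cohort carries planted ground truth, a recovery overlay marks which
#' planted regions were found.
#'
#' @param cohort a `synthetic_cohort` or assembled dataset.
#' @param config a [run_config()].
#' @return object of class `pipeline_report`.
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  runs <- run_all_modalities(cohort, config)
  regions <- if (inherits(cohort, "synthetic_cohort")) cohort$spec$regions
             else cohort$regions %||% region_table(
               n_regions = ncol(cohort$modalities$lesion$values %||%
                                  as.matrix(cohort$modalities$lesion)))
  selections <- lapply(runs$runs, `[[`, "selection")
  shared4 <- consensus_shared(selections, regions,
                              min_models = config$min_models)
  shared_core <- consensus_shared(selections, regions,
                                  min_models = config$min_models_core)
  models <- lapply(runs$runs, `[[`, "model")
  uniq <- call_unique_regions(models, regions,
                              beta_threshold = config$beta_threshold,
                              min_modalities = config$min_modalities,
                              n_components = config$n_retained,
                              shared_set = shared4)
  top_shared <- top_consensus_regions(shared_core, shared4, runs, 4)
  vd <- residual_variance_analysis(cohort, top_shared, uniq)
  overlay <- NULL
  if (inherits(cohort, "synthetic_cohort")) {
    gt <- cohort$ground_truth
    nm <- regions$name[match(gt$shared_regions, regions$region_id)]
    overlay <- list(
      shared_planted = nm,
      shared_recovered = intersect(nm, shared4$regions),
      unique_planted = lapply(gt$unique_regions, function(ids)
        regions$name[match(ids, regions$region_id)]),
      unique_recovered = lapply(names(gt$unique_regions), function(st) {
        nms <- regions$name[match(gt$unique_regions[[st]], regions$region_id)]
        intersect(nms, uniq$map$region[uniq$map$subtest == st])
      })
    )
    names(overlay$unique_recovered) <- names(gt$unique_regions)
  }
  structure(list(runs = runs, shared = shared4, shared_core = shared_core,
                 unique = uniq, variance = vd, top_shared = top_shared,
                 overlay = overlay, config = config, regions = regions),
            class = "pipeline_report")
}

# top-k consensus regions by model count, ties by mean VIP rank
top_consensus_regions <- function(shared_core, shared4, runs, k = 4) {
  counts <- shared_core$counts
  pool <- counts[counts$count >= 1, ]
  if (nrow(pool) == 0) pool <- shared4$counts
  mean_rank <- vapply(pool$region, function(rg) {
    rk <- vapply(runs$runs, function(r) {
      i <- match(rg, r$selection$ranking$feature)
      if (is.na(i)) nrow(r$selection$ranking) else i
    }, numeric(1))
    mean(rk)
  }, numeric(1))
  pool <- pool[order(-pool$count, mean_rank), ]
  head(pool$region, k)
}

#' Write the pipeline's tables to a directory
#'
#' Emits per-modality `vip_ranking.tsv`, `cv_predictions.tsv` and
#' `explained_covariance.tsv`, plus run-level `shared_consensus.tsv`,
#' `unique_regions.tsv`, `variance_decomposition.tsv` and a
#' `summary.json` stamped with the config hash and seed.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @export
write_report_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  for (tag in names(report$runs$runs)) {
    r <- report$runs$runs[[tag]]
    sub <- file.path(dir, tag)
    dir.create(sub, showWarnings = FALSE)
    data.table::fwrite(r$selection$ranking, file.path(sub, "vip_ranking.tsv"),
                       sep = "\t")
    cvp <- data.frame(subject = rownames(r$cv$observed) %||%
                        seq_len(nrow(r$cv$observed)),
                      r$cv$observed,
                      setNames(as.data.frame(r$cv$predicted),
                               paste0("pred_", colnames(r$cv$predicted))))
    data.table::fwrite(cvp, file.path(sub, "cv_predictions.tsv"), sep = "\t")
    data.table::fwrite(r$explained,
                       file.path(sub, "explained_covariance.tsv"), sep = "\t")
  }
  fw(report$shared$counts, "shared_consensus.tsv")
  fw(report$unique$map, "unique_regions.tsv")
  fw(report$variance$table, "variance_decomposition.tsv")
  cv_r <- do.call(rbind, lapply(names(report$runs$runs), function(tag) {
    r <- report$runs$runs[[tag]]
    data.frame(modality = tag, subtest = names(r$cv$r), r = r$cv$r,
               p = r$cv$p_value, row.names = NULL)
  }))
  fw(cv_r, "cv_correlations.tsv")
  summary <- list(config = unclass(report$config),
                  seed = report$config$seed,
                  hash = report$config$hash,
                  components_to_half_cov = report$runs$components_table,
                  top_shared = report$top_shared,
                  n_unique = nrow(report$unique$map))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Render a markdown report of a pipeline run
#'
#' Sections: subtest loading profiles, explained covariance per
#' modality, the cross-modality VIP consensus, cross-validated
#' prediction accuracy, the shared/unique variance decomposition, and
#' (for synthetic cohorts) the ground-truth recovery overlay.
#'
#' @param report a `pipeline_report`.
#' @param path output `.md` file.
#' @export
report_markdown <- function(report, path) {
  ln <- c(sprintf("# Multimodal PLS lesion-symptom mapping report"),
          sprintf("_config %s, seed %d_", report$config$hash,
                  report$config$seed), "",
          "## Subtest loading profiles")
  prof <- t(vapply(report$runs$runs, `[[`, numeric(4), "y_profile"))
  ln <- c(ln, md_table(data.frame(modality = rownames(prof),
                                  round(prof, 3), check.names = FALSE)))
  ln <- c(ln, "", "## Latent variables to half the brain-behaviour covariance",
          md_table(report$runs$components_table))
  ln <- c(ln, "", sprintf("## VIP consensus (>= %d models)",
                          report$shared$min_models),
          md_table(head(report$shared$counts[report$shared$counts$count > 0, ], 20)))
  cv_r <- do.call(rbind, lapply(names(report$runs$runs), function(tag) {
    r <- report$runs$runs[[tag]]
    data.frame(modality = tag, t(round(r$cv$r, 3)), check.names = FALSE)
  }))
  ln <- c(ln, "", "## LOOCV prediction accuracy (Pearson r)", md_table(cv_r))
  ln <- c(ln, "", "## Unique regions per subtest",
          if (nrow(report$unique$map)) md_table(report$unique$map)
          else "_none called_")
  vt <- report$variance$table
  vt$shared_r2 <- round(vt$shared_r2, 3)
  vt$unique_delta_r2 <- round(vt$unique_delta_r2, 3)
  ln <- c(ln, "", "## Shared + unique variance decomposition",
          sprintf("_shared predictors: %s_",
                  paste(report$top_shared, collapse = ", ")),
          md_table(vt))
  if (!is.null(report$overlay)) {
    ov <- report$overlay
    ln <- c(ln, "", "## Ground-truth recovery",
            sprintf("* shared planted: %s", paste(ov$shared_planted, collapse = ", ")),
            sprintf("* shared recovered: %s",
                    paste(ov$shared_recovered, collapse = ", ")))
    for (st in names(ov$unique_planted))
      ln <- c(ln, sprintf("* %s unique: %d/%d recovered", st,
                          length(ov$unique_recovered[[st]]),
                          length(ov$unique_planted[[st]])))
  }
  writeLines(ln, path)
  invisible(path)
}

md_table <- function(df) {
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, rows)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$runs$components_table)
  print(x$variance)
  invisible(x)
}
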