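#' Leave-one-out cross-validated PLS prediction
#'
#' For each subject, refits the PLS model on the remaining `n - 1`
#' subjects (re-estimating centering and scaling inside the fold) and
#' predicts the held-out subject. Model accuracy per response is the
#' Pearson correlation between the n out-of-fold predictions and the
#' observations, with a two-sided p-value from the exact t transform
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df.
#'
#' @param X subjects x features matrix.
#' @param Y subjects x responses matrix.
#' @param n_components latent variables per fold (capped at
#'   `min(n - 2, p)`).
#' @param scale. unit-variance scaling inside each fold (default TRUE).
#' @return object of class `cv_result`: `predicted`, `observed`,
#'   `r`, `p_value`, `p_adjusted` (Benjamini-Hochberg across responses,
#'   supplementary), `n_components_used` per fold, and `flags` naming
#'   responses with undefined r (constant observations).
#' @export
loocv_predict <- function(X, Y, n_components = 5, scale. = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 4) stopf("LOOCV needs at least 4 subjects")
  k <- ncol(Y)
  pred <- matrix(NA_real_, n, k, dimnames = dimnames(Y))
  used <- integer(n)
  for (i in seq_len(n)) {
    a <- min(n_components, n - 2, ncol(X))
    fit <- fit_plsr(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                    n_components = a, scale. = scale.)
    pred[i, ] <- predict(fit, X[i, , drop = FALSE])
    used[i] <- fit$n_components
  }
  summarize_cv(pred, Y, used)
}

summarize_cv <- function(pred, obs, used = NA_integer_) {
  n <- nrow(obs); k <- ncol(obs)
  r <- p <- rep(NA_real_, k)
  flags <- character(0)
  for (j in seq_len(k)) {
    if (sd(obs[, j]) <= .Machine$double.eps^0.5 ||
        sd(pred[, j]) <= .Machine$double.eps^0.5) {
      flags <- c(flags, colnames(obs)[j] %||% as.character(j))
      next
    }
    r[j] <- cor(obs[, j], pred[, j])
    tstat <- r[j] * sqrt((n - 2) / max(1 - r[j]^2, 1e-15))
    p[j] <- 2 * pt(-abs(tstat), df = n - 2)
  }
  names(r) <- names(p) <- colnames(obs)
  structure(list(predicted = pred, observed = obs, r = r, p_value = p,
                 p_adjusted = p.adjust(p, method = "BH"),
                 n_components_used = used, n = n, flags = flags),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> n = %d\n", x$n))
  print(round(rbind(r = x$r, p = x$p_value), 4))
  if (length(x$flags)) cat("undefined r for:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Select the highest-VIP features of a fitted model
#'
#' Ranks features by VIP (descending, ties broken by feature index for
#' determinism) and retains the top `n_top` among those with
#' `VIP > vip_threshold`. Defaults follow the modality class: top 50 for
#' the structural/functional connectivity models, top 30 for all other
#' modalities, threshold 1.5. An empty retained set is allowed and
#' reported.
#'
#' @param model a `plsr_model`.
#' @param modality modality tag (determines the default `n_top`);
#'   `NULL` falls back to 30.
#' @param n_top maximum retained features (default by modality class).
#' @param vip_threshold minimum VIP (default 1.5).
#' @param n_components components for the VIP summary (default: all
#'   fitted).
#' @return object of class `vip_selection` with the full `ranking`
#'   data.frame and the `retained` feature labels.
#' @export
select_vip_regions <- function(model, modality = NULL, n_top = NULL,
                               vip_threshold = 1.5,
                               n_components = model$n_components) {
  if (is.null(n_top)) {
    reg <- modality_registry()
    cls <- if (!is.null(modality) && modality %in% reg$modality)
      reg$vip_class[reg$modality == modality] else "other"
    n_top <- if (cls == "connectivity") 50L else 30L
  }
  v <- vip_scores(model, n_components = n_components)
  ordv <- order(-as.numeric(v), seq_along(v))
  ranking <- data.frame(
    feature = model$feature_labels %||% as.character(seq_along(v)),
    vip = as.numeric(v),
    stringsAsFactors = FALSE
  )[ordv, ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  keep <- ranking$vip > vip_threshold
  retained <- head(ranking$feature[keep], n_top)
  structure(list(modality = modality, ranking = ranking,
                 retained = retained, n_top = n_top,
                 vip_threshold = vip_threshold,
                 n_components = n_components),
            class = "vip_selection")
}

#' @export
print.vip_selection <- function(x, ...) {
  cat(sprintf("<vip_selection> %s: %d features with VIP > %.2f (top %d)\n",
              x$modality %||% "?", length(x$retained), x$vip_threshold, x$n_top))
  invisible(x)
}

#' VIP-restricted cross-validated prediction
#'
#' Regresses the responses on the highest-VIP features only, with two
#' selection protocols:
#'
#' * `"paper"`: features are selected once on the full data set, then
#'   LOOCV runs on the restricted matrix (the conventional procedure;
#'   optimistic because selection sees the held-out subjects);
#' * `"nested"`: selection is repeated inside every training fold, so
#'   the held-out subject never influences it (leakage-free; the default
#'   headline).
#'
#' @param X subjects x features matrix.
#' @param Y subjects x responses matrix.
#' @param mode `"nested"` or `"paper"`.
#' @param modality modality tag for default selection size.
#' @param n_components_fit components fitted for the selection model;
#'   defaults to `n_components_cv`, which is sufficient because the VIP
#'   summary only uses the first `n_components_cv` components (fitting
#'   more leaves that prefix unchanged).
#' @param n_components_cv components for the restricted regression
#'   (default 5).
#' @param n_top,vip_threshold passed to [select_vip_regions()].
#' @return a `cv_result` with an additional `selection` element (the
#'   full-data selection in paper mode; the per-fold selection counts in
#'   nested mode). An empty selection yields a result flagged
#'   `not_evaluable`.
#' @export
vip_restricted_cv <- function(X, Y, mode = c("nested", "paper"),
                              modality = NULL,
                              n_components_fit = NULL,
                              n_components_cv = 5,
                              n_top = NULL, vip_threshold = 1.5) {
  mode <- match.arg(mode)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 4) stopf("LOOCV needs at least 4 subjects")
  a_fit <- n_components_fit %||% n_components_cv

  if (mode == "paper") {
    full <- fit_plsr(X, Y, n_components = min(a_fit, n - 1, ncol(X)))
    sel <- select_vip_regions(full, modality = modality, n_top = n_top,
                              vip_threshold = vip_threshold,
                              n_components = min(n_components_cv,
                                                 full$n_components))
    cols <- match(sel$retained, colnames(X) %||% as.character(seq_len(ncol(X))))
    if (length(cols) == 0) {
      res <- structure(list(predicted = NULL, observed = Y, r = NULL,
                            not_evaluable = TRUE, selection = sel),
                       class = "cv_result")
      return(res)
    }
    res <- loocv_predict(X[, cols, drop = FALSE], Y,
                         n_components = min(n_components_cv, length(cols)))
    res$selection <- sel
    res$mode <- "paper"
    return(res)
  }

  pred <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
  n_sel <- integer(n)
  sel_counts <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; Yi <- Y[-i, , drop = FALSE]
    fit <- fit_plsr(Xi, Yi, n_components = min(a_fit, n - 2, ncol(X)))
    sel <- select_vip_regions(fit, modality = modality, n_top = n_top,
                              vip_threshold = vip_threshold,
                              n_components = min(n_components_cv,
                                                 fit$n_components))
    cols <- match(sel$retained, colnames(X) %||% as.character(seq_len(ncol(X))))
    n_sel[i] <- length(cols)
    if (length(cols) == 0) next
    for (f in sel$retained)
      assign(f, (get0(f, sel_counts, ifnotfound = 0L)) + 1L, sel_counts)
    sub <- fit_plsr(Xi[, cols, drop = FALSE], Yi,
                    n_components = min(n_components_cv, length(cols), n - 2))
    pred[i, ] <- predict(sub, X[i, cols, drop = FALSE])
  }
  if (all(is.na(pred))) {
    return(structure(list(predicted = pred, observed = Y, r = NULL,
                          not_evaluable = TRUE,
                          selection = list(per_fold_sizes = n_sel)),
                     class = "cv_result"))
  }
  ok <- rowSums(is.na(pred)) == 0
  res <- summarize_cv(pred[ok, , drop = FALSE], Y[ok, , drop = FALSE], n_sel)
  res$selection <- list(
    per_fold_sizes = n_sel,
    selection_frequency = sort(unlist(as.list(sel_counts)), decreasing = TRUE)
  )
  res$mode <- "nested"
  res
}

#' Fit, validate and rank every modality of a cohort
#'
#' Constructs one independent PLS model per modality: the full-data fit
#' (for loadings, explained covariance and VIP), a plain LOOCV of the
#' retained components, the VIP selection, and the VIP-restricted LOOCV
#' in the configured selection mode(s). Also tabulates, per modality,
#' the smallest number of latent variables explaining at least half of
#' the brain-behaviour covariance.
#'
#' @param cohort a `synthetic_cohort`, or a list with `modalities` and
#'   `behaviour` as returned by [assemble_dataset()]/[read_cohort()].
#' @param config a [run_config()].
#' @return object of class `modality_runs`: per-modality list of
#'   `model`, `vip`, `selection`, `cv`, `restricted_cv` (per mode), and
#'   a `components_table`.
#' @export
run_all_modalities <- function(cohort, config = run_config()) {
  mods <- cohort$modalities
  Y <- behaviour_scores(cohort)
  runs <- list()
  for (tag in config$modalities) {
    if (!tag %in% names(mods)) {
      warnf("modality '%s' missing from cohort; skipped", tag)
      next
    }
    X <- mods[[tag]]$values %||% as.matrix(mods[[tag]])
    X <- drop_invariant_features(X, config$min_variant %||% 5)
    a_full <- min(config$n_components, nrow(X) - 1, ncol(X))
    model <- fit_plsr(X, Y, n_components = a_full)
    a_ret <- min(config$n_retained, model$n_components)
    sel <- select_vip_regions(model, modality = tag,
                              vip_threshold = config$vip_threshold,
                              n_components = a_ret)
    cv <- loocv_predict(X, Y, n_components = a_ret)
    restricted <- lapply(config$selection_modes, function(mode)
      vip_restricted_cv(X, Y, mode = mode, modality = tag,
                        n_components_cv = a_ret,
                        vip_threshold = config$vip_threshold))
    names(restricted) <- config$selection_modes
    runs[[tag]] <- list(modality = tag, model = model,
                        vip = vip_scores(model, n_components = a_ret),
                        selection = sel, cv = cv,
                        restricted_cv = restricted,
                        y_profile = y_loading_profile(model, a_ret),
                        explained = explained_covariance(model))
  }
  comp_tab <- data.frame(
    modality = names(runs),
    components_to_half_cov = vapply(runs, function(r)
      components_to_half_cov(r$model), integer(1)),
    row.names = NULL
  )
  structure(list(runs = runs, components_table = comp_tab,
                 config = config), class = "modality_runs")
}

#' Drop features that vary in too few subjects
#'
#' Minimum-affection filter: keeps features whose value deviates from
#' the feature median in at least `min_variant` subjects. Zero-inflated
#' lesion features damaged in only a couple of subjects have no
#' estimable variance inside cross-validation folds; the filter uses X
#' only and is safe to apply before any response modelling.
#'
#' @param X subjects x features matrix.
#' @param min_variant minimum deviating subjects (default 5).
#' @return the filtered matrix (possibly all columns, never zero
#'   columns: if the filter would drop everything it is skipped with a
#'   warning).
#' @export
drop_invariant_features <- function(X, min_variant = 5) {
  if (min_variant <= 1) return(X)
  med <- apply(X, 2, median)
  n_dev <- colSums(abs(sweep(X, 2, med)) > 1e-9)
  keep <- n_dev >= min_variant
  if (!any(keep)) {
    warnf("minimum-affection filter would drop all features; skipped")
    return(X)
  }
  X[, keep, drop = FALSE]
}

behaviour_scores <- function(cohort) {
  b <- cohort$behaviour
  if (inherits(b, "behaviour_matrix")) return(b$scores)
  df <- as_behaviour_df(b)
  as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
}
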