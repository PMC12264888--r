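#' Map an edge-level VIP selection onto regions
#'
#' Connectivity models select edges; figures and consensus counting work
#' at region level. A region counts as implicated when at least
#' `min_incident` selected edges touch it. This incident-edge
#' aggregation rule is a package choice (the region-level summaries of
#' connectivity models admit several conventions).
#'
#' @param retained character vector of `"a|b"` edge labels.
#' @param regions a [region_table()].
#' @param min_incident minimum incident selected edges (default 2).
#' @return character vector of region names.
#' @export
edge_selection_to_regions <- function(retained, regions, min_incident = 2) {
  if (length(retained) == 0) return(character(0))
  ends <- strsplit(retained, "|", fixed = TRUE)
  cnt <- table(unlist(ends))
  nm <- names(cnt)[cnt >= min_incident]
  intersect(regions$name, nm)
}

#' Cross-modality consensus of VIP-selected regions
#'
#' Counts, for every region, in how many modality-specific models it
#' passed VIP selection (edge selections are first aggregated to regions
#' with [edge_selection_to_regions()]); the consensus set keeps regions
#' appearing in at least `min_models` models. Raising the threshold can
#' only shrink the set.
#'
#' @param selections named list of `vip_selection` objects (one per
#'   modality).
#' @param regions a [region_table()].
#' @param min_models consensus threshold (default 4; a stricter core
#'   set conventionally uses 6).
#' @param min_incident edge-aggregation threshold.
#' @return object of class `shared_region_set`: data.frame `counts`
#'   (region, count, sorted), logical `flags` (region x modality), the
#'   consensus `regions`, and the threshold.
#' @export
consensus_shared <- function(selections, regions, min_models = 4,
                             min_incident = 2) {
  if (length(selections) < 2)
    stopf("need selections from at least 2 modality models")
  reg <- modality_registry()
  flags <- matrix(FALSE, nrow(regions), length(selections),
                  dimnames = list(regions$name, names(selections)))
  for (tag in names(selections)) {
    sel <- selections[[tag]]
    kind <- reg$feature_kind[match(sel$modality %||% tag, reg$modality)]
    picked <- if (identical(kind, "pairwise"))
      edge_selection_to_regions(sel$retained, regions, min_incident)
    else intersect(sel$retained, regions$name)
    flags[picked, tag] <- TRUE
  }
  count <- rowSums(flags)
  counts <- data.frame(region = rownames(flags), count = as.integer(count),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$count, counts$region), ]
  rownames(counts) <- NULL
  structure(list(counts = counts, flags = flags,
                 regions = counts$region[counts$count >= min_models],
                 min_models = min_models, n_models = length(selections)),
            class = "shared_region_set")
}

#' @export
print.shared_region_set <- function(x, ...) {
  cat(sprintf("<shared_region_set> %d region(s) in >= %d of %d models\n",
              length(x$regions), x$min_models, x$n_models))
  print(head(x$counts, 10))
  invisible(x)
}

#' Call regions uniquely associated with one subtest
#'
#' Within each modality model, takes the absolute standardized beta
#' coefficients per region and subtest (edge betas aggregated to regions
#' by the maximum over incident edges), min-max rescales them to
#' `[0, 1]` within the modality (jointly over the four subtest columns,
#' so magnitudes stay comparable across subtests and modalities;
#' `rescale_scope = "subtest"` rescales each column separately), and
#' applies the threshold (default
#' 0.2). A region is modality-unique for a subtest when it exceeds the
#' threshold for exactly that subtest and none of the other three; the
#' final map keeps regions called for the same subtest in at least
#' `min_modalities` models (default 2, guarding against spurious
#' single-modality findings). Uniqueness is decided on magnitudes, not
#' signs: damage may raise one feature (MD) and lower another (FA, CBF)
#' while implicating the same region.
#'
#' Regions whose calls conflict across modalities (different subtests
#' each reaching `min_modalities`) are dropped and reported, as is any
#' overlap with a supplied shared-consensus set.
#'
#' @param models named list of fitted `plsr_model` objects per modality.
#' @param regions a [region_table()].
#' @param beta_threshold threshold on the rescaled |beta| (default 0.2).
#' @param min_modalities minimum supporting models (default 2).
#' @param n_components components for the beta matrices (default 5,
#'   capped per model).
#' @param rescale_first rescale |beta| to `[0, 1]` before thresholding
#'   (default). `FALSE` thresholds the raw standardized |beta| at
#'   `beta_threshold` first and is provided for comparison.
#' @param rescale_scope `"modality"` (default: one min-max over the full
#'   beta matrix of a modality) or `"subtest"` (per subtest column).
#' @param shared_set optional `shared_region_set`; its consensus regions
#'   are excluded from unique calls (exclusions reported).
#' @return object of class `unique_region_map`: data.frame `map`
#'   (region, subtest, n_modalities, modalities), per-modality call
#'   matrix, and `conflicts`/`excluded_shared` reports.
#' @export
call_unique_regions <- function(models, regions, beta_threshold = 0.2,
                                min_modalities = 2, n_components = 5,
                                rescale_first = TRUE,
                                rescale_scope = c("modality", "subtest"),
                                shared_set = NULL) {
  rescale_scope <- match.arg(rescale_scope)
  reg <- modality_registry()
  subtests <- NULL
  calls <- list()   # per modality: region x subtest logical
  for (tag in names(models)) {
    model <- models[[tag]]
    a <- min(n_components, model$n_components)
    B <- tryCatch(coef(model, n_components = a, standardized = TRUE),
                  error = function(e) NULL)
    if (is.null(B) || max(abs(B)) <= 1e-12) {
      warnf("modality '%s' has an all-zero beta matrix; skipped", tag)
      next
    }
    subtests <- subtests %||% colnames(B)
    kind <- reg$feature_kind[match(tag, reg$modality)]
    if (identical(kind, "pairwise")) {
      Babs <- aggregate_edge_betas(abs(B), regions)
    } else {
      Babs <- abs(B)[match(regions$name, rownames(B)), , drop = FALSE]
      rownames(Babs) <- regions$name
      Babs[is.na(Babs)] <- 0
    }
    if (!rescale_first) {
      U <- Babs                       # threshold the raw standardized |beta|
    } else if (rescale_scope == "modality") {
      rng <- max(Babs) - min(Babs)
      U <- if (rng <= 1e-15) Babs * 0 else (Babs - min(Babs)) / rng
    } else {
      U <- apply(Babs, 2, function(b) {
        rng <- max(b) - min(b)
        if (rng <= 1e-15) rep(0, length(b)) else (b - min(b)) / rng
      })
    }
    pass <- U >= beta_threshold
    calls[[tag]] <- pass & rowSums(pass) == 1
  }
  if (length(calls) == 0)
    stopf("no usable beta matrices across modalities")
  support <- array(0L, c(nrow(regions), length(subtests)),
                   dimnames = list(regions$name, subtests))
  mods_by <- array("", dim(support), dimnames = dimnames(support))
  for (tag in names(calls)) {
    cl <- calls[[tag]]
    support <- support + cl
    mods_by[cl] <- paste(mods_by[cl], tag)
  }
  best <- apply(support, 1, which.max)
  bestn <- support[cbind(seq_len(nrow(support)), best)]
  second <- vapply(seq_len(nrow(support)), function(i)
    max(support[i, -best[i]]), numeric(1))
  eligible <- bestn >= min_modalities
  conflicts <- rownames(support)[eligible & second >= min_modalities]
  keep <- eligible & second < min_modalities
  excluded_shared <- character(0)
  if (!is.null(shared_set)) {
    excluded_shared <- intersect(rownames(support)[keep], shared_set$regions)
    keep[rownames(support) %in% excluded_shared] <- FALSE
  }
  map <- data.frame(
    region = rownames(support)[keep],
    subtest = subtests[best[keep]],
    n_modalities = as.integer(bestn[keep]),
    modalities = trimws(mods_by[cbind(which(keep), best[keep])]),
    stringsAsFactors = FALSE
  )
  map <- map[order(map$subtest, -map$n_modalities, map$region), ]
  rownames(map) <- NULL
  structure(list(map = map, support = support, conflicts = conflicts,
                 excluded_shared = excluded_shared,
                 beta_threshold = beta_threshold,
                 min_modalities = min_modalities,
                 rescale_first = rescale_first,
                 rescale_scope = rescale_scope),
            class = "unique_region_map")
}

# max |beta| over edges incident to each region
aggregate_edge_betas <- function(Babs, regions) {
  ends <- strsplit(rownames(Babs), "|", fixed = TRUE)
  e1 <- vapply(ends, `[`, "", 1); e2 <- vapply(ends, `[`, "", 2)
  out <- matrix(0, nrow(regions), ncol(Babs),
                dimnames = list(regions$name, colnames(Babs)))
  for (j in seq_len(ncol(Babs))) {
    v <- numeric(nrow(regions)); names(v) <- regions$name
    a1 <- tapply(Babs[, j], e1, max)
    a2 <- tapply(Babs[, j], e2, max)
    v[names(a1)] <- pmax(v[names(a1)], a1)
    v[names(a2)] <- pmax(v[names(a2)], a2)
    out[, j] <- v
  }
  out
}

#' @export
print.unique_region_map <- function(x, ...) {
  cat(sprintf("<unique_region_map> %d region(s), |beta| >= %.2f in >= %d models\n",
              nrow(x$map), x$beta_threshold, x$min_modalities))
  print(head(x$map, 12))
  invisible(x)
}

#' Shared-plus-unique residual variance decomposition
#'
#' Two-stage regression mirroring the shared/unique dissociation:
#' stage 1 regresses each subtest score on the proportional lesion
#' (percent damage / 100) of the shared regions (ordinary least
#' squares) and records R-squared; stage 2 regresses the stage-1
#' residuals on the MD values of that subtest's unique regions,
#' recording the additional R-squared and per-predictor two-sided
#' p-values. Near-singular shared predictor blocks (condition number
#' > 1e8) fall back to a pseudoinverse fit with a warning.
#'
#' @param cohort a `synthetic_cohort` or assembled dataset (needs the
#'   `lesion` and `md` modalities and behaviour).
#' @param shared_regions character region names (conventionally the top
#'   4 consensus regions).
#' @param unique_map a `unique_region_map` (or its `map` data.frame).
#' @param max_predictors cap on stage-2 predictors per subtest (default
#'   10, taking the regions with the strongest cross-modality support
#'   first); an uncapped regression with predictor counts near the
#'   subject count would saturate R-squared meaninglessly.
#' @return object of class `variance_decomposition`: data.frame with
#'   per-subtest shared R2, unique delta-R2, predictor counts; plus
#'   per-subtest predictor p-value tables.
#' @export
residual_variance_analysis <- function(cohort, shared_regions, unique_map,
                                       max_predictors = 10) {
  mods <- cohort$modalities
  if (!all(c("lesion", "md") %in% names(mods)))
    stopf("cohort must include the lesion and md modalities")
  Y <- behaviour_scores(cohort)
  lesion <- mods$lesion$values %||% as.matrix(mods$lesion)
  md <- mods$md$values %||% as.matrix(mods$md)
  shared_regions <- intersect(shared_regions, colnames(lesion))
  if (length(shared_regions) == 0)
    stopf("no shared regions present in the lesion modality")
  map <- if (inherits(unique_map, "unique_region_map")) unique_map$map else unique_map
  Xs <- lesion[, shared_regions, drop = FALSE] / 100

  rows <- list(); pvals <- list()
  for (st in colnames(Y)) {
    y <- Y[, st]
    st_r2 <- .safe_r2(Xs, y)
    resid1 <- st_r2$residuals
    sub_map <- map[map$subtest == st, , drop = FALSE]
    if ("n_modalities" %in% names(sub_map))
      sub_map <- sub_map[order(-sub_map$n_modalities, sub_map$region), ]
    ur <- head(intersect(sub_map$region, colnames(md)), max_predictors)
    if (length(ur) > 0) {
      Xu <- md[, ur, drop = FALSE]
      st2 <- .safe_r2(Xu, resid1)
      d_r2 <- st2$r2
      pv <- st2$p_values
    } else {
      d_r2 <- 0                      # empty predictor set explains nothing
      pv <- setNames(numeric(0), character(0))
    }
    rows[[st]] <- data.frame(subtest = st, shared_r2 = st_r2$r2,
                             unique_delta_r2 = d_r2,
                             n_shared = length(shared_regions),
                             n_unique = length(ur),
                             stringsAsFactors = FALSE)
    pvals[[st]] <- pv
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, p_values = pvals,
                 shared_regions = shared_regions),
            class = "variance_decomposition")
}

# OLS R^2 with pseudoinverse fallback for ill-conditioned designs
.safe_r2 <- function(X, y) {
  X <- as.matrix(X)
  M <- cbind(`(Intercept)` = 1, X)
  kap <- kappa(M, exact = FALSE)
  n <- length(y)
  if (is.finite(kap) && kap <= 1e8) {
    df <- data.frame(.y = y, X, check.names = FALSE)
    fit <- lm(.y ~ ., data = df)
    sm <- summary(fit)
    cf <- coef(sm)
    pv <- cf[-1, 4]
    names(pv) <- rownames(cf)[-1]
    return(list(r2 = sm$r.squared, residuals = residuals(fit), p_values = pv))
  }
  warnf("ill-conditioned design (kappa = %.3g); using pseudoinverse fit", kap)
  b <- MASS::ginv(M) %*% y
  res <- y - M %*% b
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(r2 = r2, residuals = drop(res),
       p_values = setNames(rep(NA_real_, ncol(X)), colnames(X)))
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("<variance_decomposition>\n")
  print(transform(x$table, shared_r2 = round(shared_r2, 3),
                  unique_delta_r2 = round(unique_delta_r2, 3)))
  invisible(x)
}
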