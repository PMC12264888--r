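#' Healthy baselines and damage links of the derived modalities
#'
#' Each regional modality is a monotone link of regional damage:
#' `value = base + delta * damage_fraction + noise`, clamped to
#' `[lo, hi]`. FA, CBF, VBM volumes, pALF and the task-fMRI contrast
#' decrease with damage; MD (in 10^-3 mm^2/s) increases. `delta` is the
#' full-damage change, so `|delta|` is the healthy dynamic range used to
#' scale the noise SD.
#'
#' @return data.frame with columns `modality`, `base`, `delta`, `lo`, `hi`.
#' @export
modality_baselines <- function() {
  data.frame(
    modality = c("vbm_gm", "vbm_wm", "fmri", "palf", "fa", "md", "cbf"),
    base  = c(0.48, 0.40, 1.20, 0.55, 0.45, 0.70, 50),
    delta = c(-0.33, -0.28, -1.20, -0.35, -0.30, 0.80, -35),
    lo    = c(0, 0, -1, 0, 0, 0.3, 0),
    hi    = c(1, 1, 3, 1, 0.70, 2.5, 90),
    stringsAsFactors = FALSE
  )
}

#' Derive the non-lesion modalities from regional damage
#'
#' Builds the remaining 10 modality matrices from the lesion matrix:
#' i3mT1 as the damage fraction plus probabilistic blur; the regional
#' scalar modalities through their damage links
#' ([modality_baselines()]); and the structural/functional connectomes
#' by attenuating a fixed healthy connectome, each edge scaled by
#' `(1 - 0.95 d_i)(1 - 0.95 d_j)` in its endpoints' damage fractions so
#' that an edge touching a fully damaged region keeps at most 5% of its
#' healthy weight (disconnection). Gaussian noise is scaled to
#' `spec$noise$modality_frac` of each modality's dynamic range.
#'
#' @param spec a [cohort_spec()].
#' @param lesion the lesion `modality_matrix` (percent damage).
#' @param severity unused placeholder for future severity-specific links.
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return named list of 10 `modality_matrix` objects.
#' @export
derive_modalities <- function(spec, lesion, severity = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- lesion$values / 100                     # damage fraction, n x R
  n <- nrow(D); R <- ncol(D)
  frac <- spec$noise$modality_frac
  out <- list()

  blur <- spec$noise$i3m_blur
  i3 <- clamp(D + if (blur > 0) rnorm(length(D), 0, blur) else 0, 0, 1)
  dimnames(i3) <- dimnames(D)
  out$i3mT1 <- modality_matrix("i3mT1", i3)

  bl <- modality_baselines()
  for (r in seq_len(nrow(bl))) {
    rng <- abs(bl$delta[r])
    V <- bl$base[r] + bl$delta[r] * D +
      if (frac > 0) rnorm(length(D), 0, frac * rng) else 0
    V <- clamp(V, bl$lo[r], bl$hi[r])
    dimnames(V) <- dimnames(D)
    out[[bl$modality[r]]] <- modality_matrix(bl$modality[r], V)
  }

  hb <- healthy_connectome_bases(spec$regions)
  att <- 1 - 0.95 * D                          # per-region attenuation
  E1 <- att[, hb$pairs[, 1], drop = FALSE] * att[, hb$pairs[, 2], drop = FALSE]
  sc <- matrix(hb$sc, n, length(hb$sc), byrow = TRUE) * E1
  if (frac > 0) sc <- sc * (1 + rnorm(length(sc), 0, frac))
  sc <- pmax(sc, 0)
  fc <- matrix(hb$fc, n, length(hb$fc), byrow = TRUE) * E1
  if (frac > 0) fc <- fc + rnorm(length(fc), 0, frac * 0.6)
  fc <- clamp(fc, -1, 1)
  dimnames(sc) <- dimnames(fc) <- list(rownames(D), hb$labels)
  out$sc <- modality_matrix("sc", sc)
  out$fc <- modality_matrix("fc", fc)
  out
}

# Deterministic healthy connectome baselines: streamline counts (sc) and
# functional correlations (fc) decay with within-hemisphere positional
# distance, with strong homotopic cross-hemisphere edges.
healthy_connectome_bases <- function(regions) {
  ord <- order(regions$index)
  rg <- regions[ord, ]
  R <- nrow(rg)
  pos <- ave(seq_len(R), rg$hemisphere, FUN = seq_along)  # within-hemi position
  pr <- upper_pairs(R)
  same <- rg$hemisphere[pr[, 1]] == rg$hemisphere[pr[, 2]]
  homo <- rg$homotope_id[pr[, 1]] == rg$region_id[pr[, 2]]
  d <- abs(pos[pr[, 1]] - pos[pr[, 2]])
  sc <- ifelse(same, 5 + 400 * exp(-d / 5),
               ifelse(homo, 250, 30 * exp(-d / 10)))
  fc <- ifelse(same, 0.10 + 0.70 * exp(-d / 8),
               ifelse(homo, 0.60, 0.05 + 0.15 * exp(-d / 10)))
  labels <- paste(rg$name[pr[, 1]], rg$name[pr[, 2]], sep = "|")
  list(pairs = pr, sc = sc, fc = fc, labels = labels, regions = rg)
}

#' Plant shared and subtest-unique effects into a cohort
#'
#' Adds the ground-truth structure the recovery analyses look for:
#'
#' * **shared**: a standard-normal per-subject factor adds extra damage
#'   (20 percentage points per unit) to the shared regions in every
#'   lesion-linked channel (lesion, i3mT1, the regional scalar links,
#'   and extra attenuation of incident connectome edges) and lowers all
#'   four subtest scores by `effect_sizes$shared` target-SD units;
#' * **unique**: per subtest, an independent standard-normal factor
#'   perturbs that subtest's unique regions in three modality channels
#'   (MD up, FA down, CBF down - structural integrity loss) and lowers
#'   only that subtest's score by its `effect_sizes$unique` slope,
#'   acting on the residual left by the shared/severity component.
#'
#' Scores are re-clipped to `[0, max]` after perturbation. The returned
#' cohort records the planted sets and latent factors as ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param behaviour a `behaviour_matrix` from [generate_behaviour()].
#' @param modalities named list of all 11 `modality_matrix` objects
#'   (including `lesion`).
#' @param seed RNG seed; `NULL` continues the current stream.
#' @return an object of class `synthetic_cohort`.
#' @export
plant_effects <- function(spec, behaviour, modalities, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  uniq_all <- unlist(spec$unique_regions, use.names = FALSE)
  if (length(intersect(spec$shared_regions, uniq_all)) > 0)
    stopf("shared and unique region sets overlap")
  n <- nrow(behaviour$scores)
  regions <- spec$regions
  ord <- order(regions$index)
  col_of <- function(ids) match(ids, regions$region_id[ord])
  tg <- spec$subtest_targets
  scores <- behaviour$scores

  # ---- shared factor -------------------------------------------------
  delta_sh <- rnorm(n)
  extra_pct <- 20 * delta_sh                   # extra percent damage
  sh_cols <- col_of(spec$shared_regions)
  bump <- function(M, cols, add, lo, hi) {
    M[, cols] <- clamp(M[, cols] + add, lo, hi)
    M
  }
  modalities$lesion$values <- bump(modalities$lesion$values, sh_cols,
                                   extra_pct, 0, 100)
  modalities$i3mT1$values <- bump(modalities$i3mT1$values, sh_cols,
                                  extra_pct / 100, 0, 1)
  bl <- modality_baselines()
  for (r in seq_len(nrow(bl))) {
    m <- bl$modality[r]
    modalities[[m]]$values <- bump(modalities[[m]]$values, sh_cols,
                                   bl$delta[r] * extra_pct / 100,
                                   bl$lo[r], bl$hi[r])
  }
  # extra disconnection of edges incident to shared regions
  att_extra <- 1 - 0.95 * pmax(extra_pct, 0) / 100
  for (m in c("sc", "fc")) {
    pr <- upper_pairs(nrow(regions))
    n_inc <- (pr[, 1] %in% sh_cols) + (pr[, 2] %in% sh_cols)
    touched <- which(n_inc > 0)
    if (length(touched)) {
      fac <- outer(att_extra, n_inc[touched], "^")
      modalities[[m]]$values[, touched] <- modalities[[m]]$values[, touched] * fac
    }
  }
  for (k in seq_len(nrow(tg)))
    scores[, k] <- clamp(scores[, k] -
                           spec$effect_sizes$shared * tg$sd[k] * delta_sh,
                         0, tg$max[k])

  # ---- unique factors ------------------------------------------------
  deltas_u <- matrix(rnorm(n * nrow(tg)), n, nrow(tg),
                     dimnames = list(NULL, tg$subtest))
  gains <- list(md = 0.5, fa = -0.18, cbf = -20)
  for (k in seq_len(nrow(tg))) {
    st <- tg$subtest[k]
    ucols <- col_of(spec$unique_regions[[st]])
    if (length(ucols) == 0) next
    for (m in names(gains)) {
      r <- match(m, bl$modality)
      modalities[[m]]$values <- bump(modalities[[m]]$values, ucols,
                                     gains[[m]] * deltas_u[, k],
                                     bl$lo[r], bl$hi[r])
    }
    es <- spec$effect_sizes$unique[[st]]
    scores[, k] <- clamp(scores[, k] - es * tg$sd[k] * deltas_u[, k],
                         0, tg$max[k])
  }

  behaviour$scores <- scores
  structure(list(
    behaviour = behaviour,
    modalities = modalities,
    ground_truth = list(
      shared_regions = spec$shared_regions,
      unique_regions = spec$unique_regions,
      territory = spec$territory,
      severity = behaviour$severity,
      shared_factor = delta_sh,
      unique_factors = deltas_u
    ),
    spec = spec
  ), class = "synthetic_cohort")
}

#' Generate a complete synthetic multimodal cohort
#'
#' Runs the full generator chain under a single seed: calibrated
#' behaviour scores and latent severity, territory-clustered lesions,
#' the 10 derived modalities, and the planted shared/unique effects.
#' Identical seeds give bitwise-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return a `synthetic_cohort`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  behaviour <- generate_behaviour(spec, seed = spec$seed)
  lesion <- generate_lesions(spec, behaviour$severity)
  others <- derive_modalities(spec, lesion, behaviour$severity)
  plant_effects(spec, behaviour, c(list(lesion = lesion), others))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d modalities, %d regions\n",
              nrow(x$behaviour$scores), length(x$modalities),
              nrow(x$spec$regions)))
  invisible(x)
}
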