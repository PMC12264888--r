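#' WAB-R subtest metadata and default cohort calibration targets
#'
#' The four Western Aphasia Battery-Revised subtests modelled throughout:
#' spontaneous speech (0-20), naming (0-10), repetition (0-10) and
#' auditory comprehension (0-10). Default means/SDs and pairwise
#' correlations describe a chronic left-hemisphere stroke aphasia cohort
#' (n = 86) and are the calibration targets of the synthetic generator.
#'
#' @return data.frame with columns `subtest`, `short`, `mean`, `sd`, `max`.
#' @export
subtest_targets_default <- function() {
  data.frame(
    subtest = c("spontaneous_speech", "naming", "repetition",
                "auditory_comprehension"),
    short = c("SS", "N", "R", "AC"),
    mean = c(11.4, 5.4, 5.2, 7.7),
    sd   = c(4.9, 3.0, 2.9, 1.8),
    max  = c(20, 10, 10, 10),
    stringsAsFactors = FALSE
  )
}

#' @rdname subtest_targets_default
#' @export
subtest_correlations_default <- function() {
  nm <- subtest_targets_default()$subtest
  R <- diag(4)
  dimnames(R) <- list(nm, nm)
  R["spontaneous_speech", "naming"]                 <- 0.84
  R["spontaneous_speech", "repetition"]             <- 0.84
  R["spontaneous_speech", "auditory_comprehension"] <- 0.68
  R["naming", "repetition"]                         <- 0.83
  R["naming", "auditory_comprehension"]             <- 0.74
  R["repetition", "auditory_comprehension"]         <- 0.63
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

#' WAB Aphasia Quotient from the four subtest scores
#'
#' `AQ = 2 * (SS + N + R + AC)`, the standard WAB-R scoring rule,
#' mapping the subtest scales (20 + 10 + 10 + 10) onto 0-100. Aphasia is
#' conventionally defined as AQ <= 93.8.
#'
#' @param ss,naming,repetition,comprehension subtest scores (vectorized).
#' @return numeric AQ in `[0, 100]`.
#' @export
aq_score <- function(ss, naming, repetition, comprehension) {
  tg <- subtest_targets_default()
  vals <- list(ss, naming, repetition, comprehension)
  for (k in 1:4) {
    v <- vals[[k]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > tg$max[k]))
      stopf("%s scores must lie in [0, %g]", tg$subtest[k], tg$max[k])
  }
  2 * (ss + naming + repetition + comprehension)
}

#' Specification of a synthetic multimodal cohort
#'
#' Bundles everything the generator needs: cohort size, region table,
#' behavioural calibration targets, the lesion territory (an ordered run
#' of regions emulating a middle-cerebral-artery perfusion territory
#' along which damage spreads), planted shared regions (extra damage
#' variance coupled to all four subtests), planted subtest-unique
#' regions (perturbing one subtest's residual through the MD/FA/CBF
#' channels), standardized effect sizes, and per-modality noise levels.
#'
#' Defaults: n = 86 subjects; 384 homotopic regions; a 60-region
#' contiguous left-hemisphere territory; 4 shared regions inside it;
#' 3 unique regions per subtest outside it (spontaneous speech
#' left-lateralized, auditory comprehension the most bilateral); noise
#' at 25% of each modality's healthy dynamic range.
#'
#' @param n_subjects cohort size (default 86).
#' @param regions a [region_table()].
#' @param subtest_targets data.frame as [subtest_targets_default()].
#' @param subtest_correlations 4x4 target correlation matrix.
#' @param territory ordered integer vector of region ids.
#' @param shared_regions region ids (subset of territory).
#' @param unique_regions named list (one entry per subtest) of region ids.
#' @param effect_sizes list with `shared` (scalar standardized slope) and
#'   `unique` (named per-subtest standardized slopes).
#' @param noise list of noise controls: `modality_frac` (fraction of each
#'   modality's dynamic range, default 0.25), `lesion_sd` (percent-damage
#'   jitter), `extent_sd` (jitter of the damage extent on the 0-1 scale),
#'   `outside_rate` (per-region probability of incidental damage outside
#'   the territory), `i3m_blur` (SD of the probabilistic-mask blur).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 86,
                        regions = region_table(),
                        subtest_targets = subtest_targets_default(),
                        subtest_correlations = subtest_correlations_default(),
                        territory = NULL,
                        shared_regions = NULL,
                        unique_regions = NULL,
                        effect_sizes = list(
                          shared = 0.5,
                          unique = c(spontaneous_speech = 0.15,
                                     naming = 0.35,
                                     repetition = 0.35,
                                     auditory_comprehension = 0.55)),
                        noise = list(),
                        seed = 1L) {
  validate_region_table(regions)
  m <- nrow(regions) / 2L
  left_ids <- regions$region_id[regions$hemisphere == "left"]
  right_ids <- regions$region_id[regions$hemisphere == "right"]
  tlen <- min(60L, max(4L, floor(m / 2)))
  territory <- territory %||% left_ids[seq_len(tlen)]
  tlen <- length(territory)
  if (tlen < 1) stopf("territory must be non-empty")
  shared_regions <- shared_regions %||%
    territory[unique(pmax(1, round(seq(0.2, 0.95, length.out = 4) * tlen)))]
  if (is.null(unique_regions)) {
    lp <- setdiff(left_ids, territory)       # left pool, beyond territory
    rp <- setdiff(right_ids, regions$homotope_id[match(territory, regions$region_id)])
    pick <- function(pool, k, used) head(setdiff(pool, used), k)
    used <- shared_regions
    u_ss <- pick(lp, 3, used); used <- c(used, u_ss)
    u_n  <- c(pick(lp, 2, used), pick(rp, 1, used)); used <- c(used, u_n)
    u_r  <- c(pick(lp, 2, used), pick(rp, 1, used)); used <- c(used, u_r)
    u_ac <- c(pick(lp, 1, used), pick(rp, 2, used)); used <- c(used, u_ac)
    unique_regions <- list(spontaneous_speech = u_ss, naming = u_n,
                           repetition = u_r, auditory_comprehension = u_ac)
  }
  defaults <- list(modality_frac = 0.25, lesion_sd = 4, extent_sd = 0.05,
                   outside_rate = 0.02, i3m_blur = 0.05)
  noise <- modifyList(defaults, noise)
  spec <- structure(list(
    n_subjects = as.integer(n_subjects),
    regions = regions,
    subtest_targets = subtest_targets,
    subtest_correlations = subtest_correlations,
    territory = territory,
    shared_regions = shared_regions,
    unique_regions = unique_regions,
    effect_sizes = effect_sizes,
    noise = noise,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#' @param spec a `cohort_spec`.
#' @return the spec, invisibly; errors on violated invariants.
#' @export
validate_cohort_spec <- function(spec) {
  tg <- spec$subtest_targets
  if (nrow(tg) != 4 || any(tg$sd <= 0) || any(tg$max <= 0))
    stopf("subtest_targets must give positive sd and max for 4 subtests")
  if (any(tg$mean < 0) || any(tg$mean > tg$max))
    stopf("subtest target means must lie within [0, max]")
  R <- spec$subtest_correlations
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stopf("subtest correlation target must be symmetric with unit diagonal")
  if (any(abs(R) > 1)) stopf("correlations must lie in [-1, 1]")
  ids <- spec$regions$region_id
  if (!all(spec$territory %in% ids)) stopf("territory contains unknown region ids")
  if (!all(spec$shared_regions %in% ids))
    stopf("shared_regions contains unknown region ids")
  uniq_all <- unlist(spec$unique_regions, use.names = FALSE)
  if (!all(uniq_all %in% ids)) stopf("unique_regions contains unknown region ids")
  if (anyDuplicated(uniq_all))
    stopf("unique region sets must be disjoint across subtests")
  if (length(intersect(spec$shared_regions, uniq_all)) > 0)
    stopf("shared and unique region sets must be disjoint")
  if (spec$n_subjects < 3) stopf("n_subjects must be >= 3")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n = %d, %d regions, territory %d, shared %d, unique %s, seed %d\n",
              x$n_subjects, nrow(x$regions), length(x$territory),
              length(x$shared_regions),
              paste(lengths(x$unique_regions), collapse = "/"), x$seed))
  invisible(x)
}
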