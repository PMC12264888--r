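#' Generate spatially clustered lesion damage
#'
#' Emulates middle-cerebral-artery-territory strokes at region level:
#' for each subject a seed position is drawn inside the ordered
#' territory and damage spreads outward along the territory order with a
#' linear ramp edge, so that adjacent territory regions receive
#' positively correlated damage. The damage extent is `pnorm(severity)`
#' (plus extent noise), so a minimally severe subject has an empty
#' lesion and a maximally severe subject has every territory region
#' damaged at >= 90%. Regions outside the territory receive occasional
#' low-grade incidental damage at rate `spec$noise$outside_rate`
#' (suppressed when the lesion noise SD is 0).
#'
#' @param spec a [cohort_spec()].
#' @param severity numeric vector of latent severities (standardized;
#'   from [generate_behaviour()]).
#' @param seed RNG seed; `NULL` continues the current RNG stream.
#' @return a `modality_matrix` with modality `"lesion"` (percent damage
#'   per region, in `[0, 100]`).
#' @export
generate_lesions <- function(spec, severity, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(severity)
  regions <- spec$regions
  ord <- order(regions$index)
  tpos <- match(spec$territory, regions$region_id[ord])  # column positions
  tlen <- length(tpos)
  edge_width <- 3                      # regions over which damage ramps off
  margin <- 8                          # overshoot so full-extent damage saturates
  u <- pnorm(severity)
  if (spec$noise$extent_sd > 0)
    u <- clamp(u + rnorm(n, 0, spec$noise$extent_sd), 0, 1)
  D <- matrix(0, n, nrow(regions))
  seed_pos <- ceiling(runif(n) * tlen)
  radius <- u * (tlen - 1 + margin)
  dist <- abs(outer(seed_pos, seq_len(tlen), "-"))       # n x tlen
  dmg <- 100 * clamp((radius - dist) / edge_width, 0, 1)
  if (spec$noise$lesion_sd > 0) {
    dmg <- dmg + rnorm(length(dmg), 0, spec$noise$lesion_sd) * (dmg > 0)
    dmg <- clamp(dmg, 0, 100)
    # incidental damage outside the territory
    out_cols <- setdiff(seq_len(nrow(regions)), tpos)
    hit <- matrix(runif(n * length(out_cols)) < spec$noise$outside_rate,
                  n, length(out_cols))
    D[, out_cols][hit] <- runif(sum(hit), 0, 15)
  }
  D[, tpos] <- dmg
  colnames(D) <- regions$name[ord]
  rownames(D) <- sprintf("sub-%03d", seq_len(n))
  modality_matrix("lesion", D)
}

#' Paint regional damage back into a lesion probability volume
#'
#' Produces a toy probabilistic lesion volume on the fixture parcellation
#' grid: every voxel of region r gets the value `damage_r / 100`. By
#' construction [region_damage_from_mask()] recovers the input exactly,
#' which makes this the round-trip companion of the extractor.
#'
#' @param damage named damage vector (percent, as one row of the lesion
#'   modality).
#' @param parcellation labelled volume from [build_parcellation_volume()].
#' @param regions the matching [region_table()].
#' @return numeric array of voxelwise damage probabilities in `[0, 1]`.
#' @export
lesion_volume_from_damage <- function(damage, parcellation, regions) {
  parcellation <- read_volume(parcellation)
  ord <- order(regions$index)
  idx <- match(as.integer(parcellation), regions$region_id[ord])
  vol <- array(0, dim(parcellation))
  filled <- !is.na(idx)
  vol[filled] <- damage[idx[filled]] / 100
  vol
}
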