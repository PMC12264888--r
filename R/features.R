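#' Neuroimaging modalities handled by the pipeline
#'
#' Eleven region-level modalities: regional scalars (lesion percent
#' damage, probabilistic i3mT1 lesion likelihood, VBM grey/white matter
#' volume, task-fMRI contrast, pALF, FA, MD, CBF) and pairwise
#' connectomes (structural `sc`, functional `fc`).
#'
#' @format a data.frame with columns `modality`, `feature_kind`
#'   (`regional`/`pairwise`) and `vip_class` (`connectivity`/`other`,
#'   which drives the default top-N VIP selection size).
#' @export
modality_registry <- function() {
  data.frame(
    modality = c("lesion", "i3mT1", "sc", "fc", "palf", "vbm_gm", "vbm_wm",
                 "fmri", "fa", "md", "cbf"),
    feature_kind = c("regional", "regional", "pairwise", "pairwise",
                     "regional", "regional", "regional", "regional",
                     "regional", "regional", "regional"),
    vip_class = c("other", "other", "connectivity", "connectivity",
                  "other", "other", "other", "other", "other", "other",
                  "other"),
    stringsAsFactors = FALSE
  )
}

#' Subjects-by-features matrix for one modality
#'
#' @param modality tag from [modality_registry()].
#' @param values numeric matrix, subjects in rows (rownames = subject
#'   ids), features in columns (colnames = region or region-pair labels).
#' @param feature_kind `"regional"` or `"pairwise"`; defaults to the
#'   registry entry for `modality`.
#' @return an object of class `modality_matrix`.
#' @export
modality_matrix <- function(modality, values, feature_kind = NULL) {
  reg <- modality_registry()
  if (!modality %in% reg$modality)
    stopf("unknown modality '%s'", modality)
  feature_kind <- feature_kind %||% reg$feature_kind[reg$modality == modality]
  if (!is.matrix(values)) values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values)))
    stopf("modality '%s' contains missing or non-finite values", modality)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sub-%03d", seq_len(nrow(values)))
  structure(list(modality = modality, values = values,
                 feature_kind = feature_kind),
            class = "modality_matrix")
}

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("<modality_matrix> %s (%s): %d subjects x %d features\n",
              x$modality, x$feature_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Regional percent damage from a lesion mask
#'
#' Overlays a (binary or probabilistic) lesion volume on a labelled
#' parcellation and returns, per region, 100 x (sum of mask values over
#' the region's voxels) / (region voxel count). Binary masks yield the
#' percentage of damaged voxels; probabilistic masks yield the expected
#' damage percentage.
#'
#' @param mask 3-D array (or NIfTI file path) with values in `[0, 1]`.
#' @param parcellation integer 3-D array (or NIfTI file path) of region
#'   labels on the same grid; 0 is background.
#' @param regions a [region_table()].
#' @return named numeric vector (one entry per region, ordered by region
#'   `index`) of damage percentages in `[0, 100]`.
#' @export
region_damage_from_mask <- function(mask, parcellation, regions) {
  mask <- read_volume(mask)
  parcellation <- read_volume(parcellation)
  validate_region_table(regions)
  if (!identical(dim(mask), dim(parcellation)))
    stopf("mask grid %s does not match parcellation grid %s",
          paste(dim(mask), collapse = "x"),
          paste(dim(parcellation), collapse = "x"))
  if (min(mask) < -1e-9 || max(mask) > 1 + 1e-9)
    stopf("mask values must lie in [0, 1]")
  ord <- order(regions$index)
  f <- factor(as.integer(round(parcellation)), levels = regions$region_id[ord])
  counts <- tabulate(f, nbins = nrow(regions))
  if (any(counts == 0))
    stopf("region_id(s) absent from parcellation volume: %s",
          paste(regions$region_id[ord][counts == 0], collapse = ", "))
  sums <- vapply(split(as.numeric(mask), f), sum, numeric(1))
  out <- 100 * sums / counts
  names(out) <- regions$name[ord]
  out
}

#' Vectorize a symmetric connectome matrix
#'
#' Extracts the strict upper triangle in row-major region-index order,
#' i.e. pairs (1,2), (1,3), ..., (1,n), (2,3), ... The diagonal is
#' ignored. Nominally symmetric input (e.g. probabilistic tractography)
#' is symmetrized as `(A + t(A))/2`; asymmetry beyond `tol` (relative to
#' the largest magnitude entry) is an error.
#'
#' @param matrix square numeric matrix.
#' @param tol relative symmetry tolerance (default `1e-6`).
#' @param labels optional region names for pair labels.
#' @return numeric vector of length `n(n-1)/2` with attributes `pairs`
#'   (2-column index matrix mapping positions back to `(i, j)`) and
#'   optionally pair names `"a|b"`.
#' @export
vectorize_connectome <- function(matrix, tol = 1e-6, labels = NULL) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stopf("connectome must be a square matrix")
  asym <- max(abs(matrix - t(matrix)))
  scale <- max(abs(matrix), 1e-300)
  if (asym > tol * scale)
    stopf("connectome asymmetric beyond tolerance: max |A - t(A)| = %g", asym)
  A <- (matrix + t(matrix)) / 2
  n <- nrow(A)
  pr <- upper_pairs(n)
  v <- A[pr]
  if (!is.null(labels)) names(v) <- paste(labels[pr[, 1]], labels[pr[, 2]], sep = "|")
  attr(v, "pairs") <- pr
  attr(v, "n_regions") <- n
  v
}

#' Row-major strict upper-triangle index pairs
#' @param n matrix dimension.
#' @return integer matrix with columns `i < j`, ordered by `i` then `j`.
#' @export
upper_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Rebuild a symmetric matrix from its vectorized upper triangle
#'
#' Inverse of [vectorize_connectome()] off the diagonal; the diagonal is
#' set to `diag_value`.
#'
#' @param values vector of length `n(n-1)/2` (row-major upper triangle).
#' @param n matrix dimension; taken from the vector's attribute if absent.
#' @param diag_value diagonal fill (default 0).
#' @return an `n x n` symmetric matrix.
#' @export
devectorize_connectome <- function(values, n = NULL, diag_value = 0) {
  n <- n %||% attr(values, "n_regions")
  if (is.null(n)) stopf("matrix dimension n must be supplied")
  if (length(values) != n * (n - 1) / 2)
    stopf("expected %d values for n = %d, got %d", n * (n - 1) / 2, n, length(values))
  A <- base::matrix(diag_value, n, n)
  pr <- upper_pairs(n)
  A[pr] <- values
  A[pr[, 2:1]] <- values
  A
}

#' Normalize regional volumes by total intracranial volume
#'
#' @param volumes numeric vector of regional volumes.
#' @param tiv total intracranial volume, strictly positive, same units.
#' @return `volumes / tiv`.
#' @export
tiv_normalize <- function(volumes, tiv) {
  if (!is.numeric(tiv) || length(tiv) != 1 || !is.finite(tiv) || tiv <= 0)
    stopf("tiv must be a single positive number")
  volumes / tiv
}

#' Partial amplitude of low-frequency fluctuations
#'
#' Per region, the sum of discrete-spectrum amplitudes over a frequency
#' band divided by the summed amplitude over all positive frequencies.
#' The default band 0.01-0.08 Hz is the conventional low-frequency
#' window of resting-state fMRI.
#'
#' @param roi_timeseries numeric matrix, time points x regions.
#' @param sampling_interval seconds between samples (TR).
#' @param band length-2 numeric `[low, high]` in Hz.
#' @return named numeric vector of band-amplitude ratios in `[0, 1]`.
#' @export
palf_ratio <- function(roi_timeseries, sampling_interval, band = c(0.01, 0.08)) {
  ts <- as.matrix(roi_timeseries)
  nt <- nrow(ts)
  if (nt < 2) stopf("need at least 2 time points")
  nyquist <- 1 / (2 * sampling_interval)
  if (band[1] < 0 || band[2] <= band[1] || band[2] > nyquist + 1e-12)
    stopf("band must satisfy 0 <= low < high <= Nyquist (%.4g Hz)", nyquist)
  amp <- Mod(mvfft(ts))
  k <- seq_len(floor(nt / 2))          # positive frequencies, DC excluded
  freqs <- k / (nt * sampling_interval)
  amp <- amp[k + 1L, , drop = FALSE]
  inband <- freqs >= band[1] & freqs <= band[2]
  tot <- colSums(amp)
  out <- colSums(amp[inband, , drop = FALSE]) / pmax(tot, 1e-300)
  names(out) <- colnames(ts)
  out
}

#' Align modalities and behaviour on a common subject set
#'
#' Intersects subject ids across all modality matrices and the behaviour
#' table, reorders every block identically (behaviour order restricted to
#' the intersection), and reports dropped subjects. Subjects missing any
#' modality are dropped everywhere, mirroring a complete-case
#' multimodal cohort definition.
#'
#' @param modalities named list of `modality_matrix` objects (or plain
#'   matrices with subject rownames).
#' @param behaviour a `behaviour_matrix` or data.frame with a
#'   `subject_id` column.
#' @return list with elements `modalities`, `behaviour` and `report`
#'   (dropped subject ids per input).
#' @export
assemble_dataset <- function(modalities, behaviour) {
  beh <- as_behaviour_df(behaviour)
  ids_list <- c(list(behaviour = beh$subject_id),
                lapply(modalities, function(m) {
                  v <- if (inherits(m, "modality_matrix")) m$values else as.matrix(m)
                  rownames(v)
                }))
  for (nm in names(ids_list)) {
    if (is.null(ids_list[[nm]])) stopf("input '%s' has no subject ids", nm)
    if (anyDuplicated(ids_list[[nm]]))
      stopf("duplicate subject ids in '%s'", nm)
  }
  common <- Reduce(intersect, ids_list)
  if (length(common) == 0) stopf("no subjects shared across inputs")
  keep <- beh$subject_id[beh$subject_id %in% common]   # behaviour order
  if (length(keep) < 3)
    stopf("fewer than 3 subjects remain after alignment (%d)", length(keep))
  dropped <- lapply(ids_list, function(ids) setdiff(ids, keep))
  out_mod <- lapply(modalities, function(m) {
    if (inherits(m, "modality_matrix")) {
      m$values <- m$values[keep, , drop = FALSE]
      m
    } else as.matrix(m)[keep, , drop = FALSE]
  })
  beh <- beh[match(keep, beh$subject_id), , drop = FALSE]
  rownames(beh) <- NULL
  list(modalities = out_mod, behaviour = beh,
       report = list(subjects = keep, dropped = dropped))
}

as_behaviour_df <- function(behaviour) {
  if (inherits(behaviour, "behaviour_matrix")) {
    df <- data.frame(subject_id = rownames(behaviour$scores),
                     behaviour$scores, check.names = FALSE)
    return(df)
  }
  df <- as.data.frame(behaviour)
  if (!"subject_id" %in% names(df))
    stopf("behaviour table must have a subject_id column")
  df$subject_id <- as.character(df$subject_id)
  df
}
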