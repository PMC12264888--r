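#' Homotopic region table
#'
#' Builds the region table used throughout the pipeline: `n_regions`
#' labelled parcels split equally between the hemispheres, with each left
#' region paired to its right-hemisphere homotope (mirror region). The
#' default of 384 regions (192 per hemisphere) matches homotopic
#' whole-brain atlases of the AICHA family.
#'
#' @param n_regions even total number of regions (default 384).
#' @param names optional character vector of region names; defaults to
#'   `L_R###` / `R_R###`.
#' @return a `data.frame` of class `region_table` with columns
#'   `region_id` (integer label used in parcellation volumes), `name`,
#'   `hemisphere` (`"left"`/`"right"`), `homotope_id` and `index`
#'   (0-based column position in regional feature matrices).
#' @export
region_table <- function(n_regions = 384, names = NULL) {
  if (n_regions < 2 || n_regions %% 2 != 0)
    stopf("n_regions must be an even number >= 2, got %s", n_regions)
  m <- as.integer(n_regions / 2)
  ids <- seq_len(as.integer(n_regions))
  hemi <- rep(c("left", "right"), each = m)
  if (is.null(names))
    names <- c(sprintf("L_R%03d", seq_len(m)), sprintf("R_R%03d", seq_len(m)))
  tab <- data.frame(
    region_id   = ids,
    name        = names,
    hemisphere  = hemi,
    homotope_id = c(ids[seq_len(m)] + m, ids[seq_len(m)]),
    index       = ids - 1L,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("region_table", "data.frame")
  validate_region_table(tab)
  tab
}

#' Validate a region table
#'
#' Checks the structural invariants: two hemispheres with equal counts,
#' homotope mapping a bijection between hemispheres, and indices forming
#' a permutation of `0..n-1`.
#'
#' @param regions a `region_table`.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_region_table <- function(regions) {
  req <- c("region_id", "name", "hemisphere", "homotope_id", "index")
  if (!all(req %in% names(regions)))
    stopf("region table missing columns: %s",
          paste(setdiff(req, names(regions)), collapse = ", "))
  n <- nrow(regions)
  hcounts <- table(regions$hemisphere)
  if (length(hcounts) != 2 || hcounts[1] != hcounts[2])
    stopf("region table must have exactly 2 hemispheres with equal counts")
  if (anyDuplicated(regions$region_id))
    stopf("duplicate region_id values")
  if (!setequal(regions$index, 0:(n - 1)))
    stopf("region indices must be a permutation of 0..%d", n - 1)
  # homotope bijection across hemispheres
  mt <- match(regions$homotope_id, regions$region_id)
  if (anyNA(mt)) stopf("homotope_id refers to unknown region_id")
  if (any(regions$hemisphere[mt] == regions$hemisphere))
    stopf("homotope pairs must span hemispheres")
  if (!all(regions$homotope_id[mt] == regions$region_id))
    stopf("homotope mapping is not an involution/bijection")
  invisible(regions)
}

#' Synthetic labelled parcellation volume
#'
#' Tiles a 3-D grid with mirrored left/right blocks, one per region, so
#' every region occupies the same number of voxels and the right-hemisphere
#' block of a region is the x-mirror of its left homotope. This is a
#' synthetic stand-in used for tests and examples; real parcellation
#' volumes are read with [read_volume()] and used identically.
#'
#' @param regions a `region_table`.
#' @param dim integer length-3 grid size (default `c(48, 48, 48)`); the
#'   x extent must be even and the per-hemisphere region count must tile
#'   the half grid exactly.
#' @return an integer 3-D array of region labels (0 = background; here
#'   every voxel is labelled).
#' @export
build_parcellation_volume <- function(regions, dim = c(48L, 48L, 48L)) {
  validate_region_table(regions)
  if (length(dim) != 3 || dim[1] %% 2 != 0)
    stopf("dim must be length 3 with even x extent")
  m <- nrow(regions) / 2L
  half <- dim[1] / 2L
  fac <- .block_grid(m, c(half, dim[2], dim[3]))
  bx <- half / fac[1]; by <- dim[2] / fac[2]; bz <- dim[3] / fac[3]
  vol <- array(0L, dim)
  left_ids  <- regions$region_id[regions$hemisphere == "left"]
  # pair left region k with its homotope on the mirrored block
  homo <- regions$homotope_id[match(left_ids, regions$region_id)]
  k <- 0L
  for (iz in seq_len(fac[3])) for (iy in seq_len(fac[2])) for (ix in seq_len(fac[1])) {
    k <- k + 1L
    xs <- ((ix - 1L) * bx + 1L):(ix * bx)
    ys <- ((iy - 1L) * by + 1L):(iy * by)
    zs <- ((iz - 1L) * bz + 1L):(iz * bz)
    vol[xs, ys, zs] <- left_ids[k]
    vol[dim[1] + 1L - xs, ys, zs] <- homo[k]
  }
  vol
}

# smallest factor triple (nx, ny, nz) of m whose parts divide the half-grid
.block_grid <- function(m, half_dim) {
  for (nx in 1:m) {
    if (m %% nx != 0 || half_dim[1] %% nx != 0) next
    rest <- m / nx
    for (ny in 1:rest) {
      if (rest %% ny != 0 || half_dim[2] %% ny != 0) next
      nz <- rest / ny
      if (half_dim[3] %% nz == 0) return(c(nx, ny, nz))
    }
  }
  stopf("cannot tile a %s half-grid with %d equal regions",
        paste(half_dim, collapse = "x"), m)
}
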