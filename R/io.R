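# File I/O: NIfTI volumes, TSV feature/behaviour tables, cohort folders.

#' Read a volume from a NIfTI file or pass an array through
#' @param x array, or path to a `.nii`/`.nii.gz` file.
#' @return a plain numeric array.
#' @export
read_volume <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stopf("volume file not found: %s", x)
    return(as.array(RNifti::readNifti(x)))
  }
  if (!is.array(x)) stopf("expected an array or a NIfTI file path")
  x
}

#' Write a volume to NIfTI
#' @param vol numeric array.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Write / read a regional feature matrix as TSV
#'
#' Layout: first column `subject_id`, remaining columns one per feature
#' (header = region or region-pair names).
#'
#' @param m `modality_matrix` or plain matrix with subject rownames.
#' @param path TSV path.
#' @export
write_modality_tsv <- function(m, path) {
  v <- if (inherits(m, "modality_matrix")) m$values else as.matrix(m)
  dt <- data.table::data.table(subject_id = rownames(v))
  dt <- cbind(dt, data.table::as.data.table(v))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_modality_tsv
#' @param modality modality tag to attach on read.
#' @export
read_modality_tsv <- function(path, modality) {
  dt <- data.table::fread(path, sep = "\t")
  ids <- as.character(dt[[1]])
  v <- as.matrix(dt[, -1])
  rownames(v) <- ids
  modality_matrix(modality, v)
}

#' Write / read the behaviour table as TSV
#'
#' Columns: `subject_id`, `spontaneous_speech`, `auditory_comprehension`,
#' `repetition`, `naming`.
#' @param behaviour `behaviour_matrix` or data.frame.
#' @param path TSV path.
#' @export
write_behaviour_tsv <- function(behaviour, path) {
  df <- as_behaviour_df(behaviour)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_behaviour_tsv
#' @export
read_behaviour_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write a full synthetic cohort to a directory
#'
#' One TSV per modality, a behaviour TSV and the planted ground truth as
#' JSON (`ground_truth.json`).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in cohort$modalities)
    write_modality_tsv(m, file.path(dir, paste0(m$modality, ".tsv")))
  write_behaviour_tsv(cohort$behaviour, file.path(dir, "behaviour.tsv"))
  gt <- cohort$ground_truth
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory.
#' @return list with `modalities`, `behaviour` and (if present)
#'   `ground_truth`.
#' @export
read_cohort <- function(dir) {
  reg <- modality_registry()
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tags <- sub("\\.tsv$", "", basename(files))
  mods <- list()
  for (i in seq_along(files)) {
    if (tags[i] %in% reg$modality)
      mods[[tags[i]]] <- read_modality_tsv(files[i], tags[i])
  }
  beh <- read_behaviour_tsv(file.path(dir, "behaviour.tsv"))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  list(modalities = mods, behaviour = beh, ground_truth = gt)
}
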