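#' Export a cohort's masks as NIfTI files plus a metadata table
#'
#' One `.nii.gz` file is written per distinct mask. Truth and AI contours are
#' shared across observers, so their filenames encode (patient, system,
#' organ, role); corrected contours additionally encode the observer. A
#' `delineations.csv` metadata table keys every record to its files and
#' carries correction time and confidence.
#'
#' @param cohort a `delineation_cohort`.
#' @param dir output directory (created if needed).
#' @return path of the metadata CSV, invisibly.
#' @export
export_cohort_nifti <- function(cohort, dir) {
  stopifnot(inherits(cohort, "delineation_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- new.env(parent = emptyenv())
  write_once <- function(mask, fname) {
    if (is.null(mask)) return(NA_character_)
    if (is.null(written[[fname]])) {
      write_mask_nifti(mask, file.path(dir, fname))
      written[[fname]] <- TRUE
    }
    fname
  }
  meta <- do.call(rbind, lapply(cohort$records, function(r) {
    key <- paste(r$patient_id, r$imaging_system, r$organ, sep = "_")
    data.frame(
      patient_id = r$patient_id, observer_id = r$observer_id,
      imaging_system = r$imaging_system, organ = r$organ,
      truth_file = write_once(r$truth_mask, paste0(key, "_truth.nii.gz")),
      ai_file = write_once(r$ai_mask, paste0(key, "_ai.nii.gz")),
      corrected_file = write_once(r$corrected_mask,
                                  paste0(key, "_", r$observer_id, "_corrected.nii.gz")),
      correction_time_s = r$correction_time_s, confidence = r$confidence,
      missing = isTRUE(r$missing), stringsAsFactors = FALSE)
  }))
  path <- file.path(dir, "delineations.csv")
  write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' Load delineation records from NIfTI masks and a metadata table
#'
#' Real-data entry point: the metadata CSV must have columns `patient_id`,
#' `observer_id`, `imaging_system`, `organ`, `ai_file`, `corrected_file`, and
#' optionally `truth_file`, `correction_time_s`, `confidence`, `missing`.
#' File paths are taken relative to `dir`. Rows flagged missing (or with
#' empty file fields) become explicitly-missing records.
#'
#' @param metadata_csv path to the metadata table.
#' @param dir directory containing the NIfTI masks; defaults to the CSV's
#'   directory.
#' @return a `delineation_cohort` (without config/calibration).
#' @export
read_delineations <- function(metadata_csv, dir = dirname(metadata_csv)) {
  meta <- read.csv(metadata_csv, stringsAsFactors = FALSE)
  need <- c("patient_id", "observer_id", "imaging_system", "organ")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  cache <- new.env(parent = emptyenv())
  load_mask <- function(f) {
    if (is.null(f) || is.na(f) || !nzchar(f)) return(NULL)
    if (is.null(cache[[f]])) cache[[f]] <- read_mask_nifti(file.path(dir, f))
    cache[[f]]
  }
  records <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    miss <- isTRUE(as.logical(row$missing %||% FALSE))
    list(patient_id = row$patient_id, observer_id = row$observer_id,
         imaging_system = row$imaging_system, organ = row$organ,
         truth_mask = if (miss) NULL else load_mask(row$truth_file %||% NA),
         ai_mask = if (miss) NULL else load_mask(row$ai_file %||% NA),
         corrected_mask = if (miss) NULL else load_mask(row$corrected_file %||% NA),
         correction_time_s = as.numeric(row$correction_time_s %||% NA),
         confidence = as.integer(row$confidence %||% NA),
         missing = miss)
  })
  systems <- unique(meta$imaging_system)
  structure(list(records = records,
                 scans = unique(meta[, c("patient_id", "imaging_system")]),
                 config = NULL, calibration = NULL),
            class = "delineation_cohort")
}
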