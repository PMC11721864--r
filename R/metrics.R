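#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)` by voxel count. Symmetric, in `[0, 1]`, and
#' independent of voxel spacing. Undefined (an error) when both masks are
#' empty.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return Dice coefficient (dimensionless).
#' @examples
#' v <- array(FALSE, c(6, 6, 6)); v[2:3, 2:3, 2:3] <- TRUE
#' w <- array(FALSE, c(6, 6, 6)); w[3:4, 2:3, 2:3] <- TRUE
#' dice(binary_mask(v), binary_mask(w))  # 0.5
#' @export
dice <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na == 0L && nb == 0L)
    stop("Dice coefficient is undefined for two empty masks")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' 95th-percentile Hausdorff distance of two masks (mm)
#'
#' Boundary voxels of each mask are extracted (face-adjacency rule, see
#' [mask_boundary()]); directed Euclidean distances between voxel centers
#' (spacing-scaled) are computed from every boundary voxel of A to the nearest
#' boundary voxel of B and vice versa, and the 95th percentile of the pooled
#' set of directed distances is returned, using the linear-interpolation
#' percentile (`stats::quantile` type 7). Pooling both directions makes the
#' result symmetric in its arguments by construction.
#'
#' @param a,b non-empty [binary_mask()] objects on the same grid.
#' @param probs percentile in `[0, 1]`; 0.95 gives HD95, 1 the exact
#'   (maximum) Hausdorff distance.
#' @return distance in mm.
#' @export
hd95 <- function(a, b, probs = 0.95) {
  check_same_grid(a, b)
  if (sum(a$voxels) == 0L || sum(b$voxels) == 0L)
    stop("HD95 is undefined for an empty mask")
  ba <- mask_boundary(a); bb <- mask_boundary(b)
  if (identical(a$voxels, b$voxels)) return(0)
  da <- edt_mm(bb, a$spacing_mm)[ba]  # directed A -> B
  db <- edt_mm(ba, a$spacing_mm)[bb]  # directed B -> A
  unname(quantile(c(da, db), probs = probs, type = 7, names = FALSE))
}

#' Restrict a mask to a band around a target structure
#'
#' Keeps the voxels of `mask` whose center lies within `margin_mm` of the
#' nearest foreground voxel center of `target_union` (target voxels have
#' distance 0). This mirrors the clinical rule that corrections of bladder,
#' rectum and bowel are confined to a fixed-width region around the prostate
#' and seminal vesicles.
#'
#' @param mask,target_union [binary_mask()] objects on the same grid;
#'   `target_union` must be non-empty.
#' @param margin_mm band half-width in mm (>= 0); the clinical default is a
#'   2 cm wide region, i.e. `margin_mm = 20`.
#' @return a [binary_mask()] on the same grid.
#' @export
restrict_to_region <- function(mask, target_union, margin_mm = 20) {
  check_same_grid(mask, target_union)
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L || margin_mm < 0)
    stop("`margin_mm` must be a single value >= 0")
  if (sum(target_union$voxels) == 0L)
    stop("`target_union` is empty; the correction region is undefined")
  d <- edt_mm(target_union$voxels, mask$spacing_mm)
  binary_mask(mask$voxels & (d <= margin_mm), mask$spacing_mm, mask$origin_mm)
}

#' Agreement metrics for every delineation in a cohort
#'
#' Computes DSC and HD95 between the AI autosegmented contour and the
#' observer-corrected contour of every record. Records whose masks are
#' missing (e.g. an organ outside the imaging field of view) are emitted with
#' `NA` metrics and `missing = TRUE` rather than dropped, so unbalanced
#' analyses can see them.
#'
#' @param cohort a `delineation_cohort` from [generate_cohort()] or
#'   [read_delineations()], or a plain list of delineation records.
#' @return `data.frame` with one row per record: `patient_id`, `observer_id`,
#'   `imaging_system`, `organ`, `dsc`, `hd95`, `missing`, plus
#'   `correction_time_s` and `confidence` carried through for the workflow
#'   endpoints.
#' @export
metrics_for_cohort <- function(cohort) {
  records <- if (inherits(cohort, "delineation_cohort")) cohort$records else cohort
  if (length(records) == 0L) stop("no records supplied")
  rows <- lapply(records, function(r) {
    miss <- isTRUE(r$missing) || is.null(r$ai_mask) || is.null(r$corrected_mask)
    if (miss) {
      d <- NA_real_; h <- NA_real_
    } else {
      d <- tryCatch(dice(r$ai_mask, r$corrected_mask), error = function(e)
        stop(sprintf("metric failure for patient %s, observer %s, %s, %s: %s",
                     r$patient_id, r$observer_id, r$imaging_system, r$organ,
                     conditionMessage(e)), call. = FALSE))
      h <- tryCatch(hd95(r$ai_mask, r$corrected_mask), error = function(e)
        stop(sprintf("metric failure for patient %s, observer %s, %s, %s: %s",
                     r$patient_id, r$observer_id, r$imaging_system, r$organ,
                     conditionMessage(e)), call. = FALSE))
    }
    data.frame(patient_id = r$patient_id, observer_id = r$observer_id,
               imaging_system = r$imaging_system, organ = r$organ,
               dsc = d, hd95 = h, missing = miss,
               correction_time_s = if (is.null(r$correction_time_s)) NA_real_ else r$correction_time_s,
               confidence = if (is.null(r$confidence)) NA_integer_ else r$confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_miss <- sum(out$missing)
  if (n_miss > 0)
    message(sprintf("%d record(s) emitted as missing (excluded organ/field-of-view)", n_miss))
  out
}
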