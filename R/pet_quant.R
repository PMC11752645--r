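#' ROI SUVR tables
#'
#' Container for a subjects-by-ROI matrix of standardized uptake value
#' ratios (SUVRs) for one tracer, together with the per-subject global
#' SUVR (used as the "global burden" covariate in adjusted models).
#'
#' @param suvr numeric matrix, subjects in rows (rownames = subject ids),
#'   ROIs in columns.
#' @param tracer `"amyloid"` or `"tau"`.
#' @param global_suvr optional per-subject global SUVR; computed with
#'   [compute_global_suvr()] (unweighted ROI mean) when omitted.
#' @param scan_date optional per-subject scan dates (`Date` or year
#'   fractions).
#' @return list of class `roi_suvr_table` with elements `tracer`, `suvr`,
#'   `global_suvr`, `scan_date`.
#' @export
roi_suvr_table <- function(suvr, tracer = c("amyloid", "tau"),
                           global_suvr = NULL, scan_date = NULL) {
  tracer <- match.arg(tracer)
  suvr <- as.matrix(suvr)
  if (is.null(rownames(suvr)))
    rownames(suvr) <- sprintf("S%03d", seq_len(nrow(suvr)))
  if (anyNA(suvr))
    stop("roi_suvr_table: SUVR matrix contains missing values", call. = FALSE)
  if (any(suvr <= 0))
    stop("roi_suvr_table: all SUVRs must be positive", call. = FALSE)
  if (is.null(global_suvr))
    global_suvr <- compute_global_suvr(suvr)
  structure(
    list(tracer = tracer, suvr = suvr,
         global_suvr = stats::setNames(as.numeric(global_suvr), rownames(suvr)),
         scan_date = scan_date),
    class = "roi_suvr_table"
  )
}

#' @export
print.roi_suvr_table <- function(x, ...) {
  cat(sprintf("<roi_suvr_table> tracer=%s, %d subjects x %d ROIs, global SUVR %.3f +/- %.3f\n",
              x$tracer, nrow(x$suvr), ncol(x$suvr),
              mean(x$global_suvr), stats::sd(x$global_suvr)))
  invisible(x)
}

#' Extract regional SUVRs from a labelled uptake volume
#'
#' Computes, for one subject, the mean tracer uptake in every atlas ROI
#' (voxels carrying the ROI's label code, intersected with the subject's
#' grey-matter mask) divided by the mean uptake in the reference region
#' (voxels carrying `reference_label`). The reference region is *not*
#' grey-matter-masked: cerebellar reference regions conventionally include
#' white matter.
#'
#' @param uptake numeric 3-D array of tracer uptake.
#' @param labels integer 3-D array of the same shape; `0` = background.
#' @param gm_mask logical/0-1 3-D array of the same shape; grey-matter mask
#'   applied to atlas ROIs only.
#' @param parc a [parcellation()] providing the ROI label codes.
#' @param reference_label integer label code of the reference region; must
#'   not collide with any ROI label.
#' @return numeric vector of SUVRs, one per ROI (names = ROI ids).
#' @export
extract_roi_suvr <- function(uptake, labels, gm_mask, parc, reference_label) {
  stopifnot(inherits(parc, "parcellation"))
  du <- dim(uptake)
  if (!identical(du, dim(labels)) || !identical(du, dim(gm_mask)))
    stop("extract_roi_suvr: uptake, labels and gm_mask must share a shape",
         call. = FALSE)
  if (reference_label %in% parc$label_code)
    stop("extract_roi_suvr: reference label collides with an ROI label",
         call. = FALSE)
  lab <- as.integer(labels)
  up <- as.numeric(uptake)
  gm <- as.logical(gm_mask)

  ref_idx <- lab == as.integer(reference_label)
  if (!any(ref_idx))
    stop("extract_roi_suvr: reference region is empty", call. = FALSE)
  ref_mean <- mean(up[ref_idx])

  in_roi <- gm & lab %in% parc$label_code
  # grouped means over masked ROI voxels in one pass
  sums <- rowsum(up[in_roi], group = lab[in_roi])
  counts <- rowsum(rep(1, sum(in_roi)), group = lab[in_roi])
  got <- as.integer(rownames(sums))
  missing <- setdiff(parc$label_code, got)
  if (length(missing))
    stop(sprintf("extract_roi_suvr: empty ROI after grey-matter masking (roi id %s)",
                 paste(parc$roi_id[match(missing, parc$label_code)],
                       collapse = ", ")), call. = FALSE)
  roi_mean <- (sums / counts)[match(parc$label_code, got), 1]
  stats::setNames(roi_mean / ref_mean, parc$roi_id)
}

#' Global SUVR from a regional SUVR vector or table
#'
#' The global tracer burden for a subject is the unweighted mean of the
#' regional SUVRs by default; supplying per-ROI voxel counts as `weights`
#' gives the volume-weighted mean instead. The unweighted mean is the
#' default because it is reproducible when the analysis starts from ROI
#' tables without voxel counts.
#'
#' @param x numeric vector (one subject), matrix (subjects x ROIs), or
#'   [roi_suvr_table()].
#' @param weights optional non-negative per-ROI weights (voxel counts).
#' @return numeric: global SUVR per subject.
#' @export
compute_global_suvr <- function(x, weights = NULL) {
  if (inherits(x, "roi_suvr_table")) x <- x$suvr
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (anyNA(x)) stop("compute_global_suvr: SUVR values missing", call. = FALSE)
  if (is.null(weights)) return(rowMeans(x))
  if (length(weights) != ncol(x) || any(weights < 0) || sum(weights) == 0)
    stop("compute_global_suvr: 'weights' must be non-negative, one per ROI, with positive sum",
         call. = FALSE)
  as.numeric(x %*% (weights / sum(weights)))
}

#' Amyloid positivity from the global amyloid SUVR
#'
#' Dichotomizes the global amyloid-PET SUVR at a cohort-calibration
#' cutoff. The default 1.11 is an implementer choice standing in for
#' externally established cohort cutoffs, which are configuration, not a
#' property of this method; a subject exactly at the cutoff is classified
#' positive.
#'
#' @param global_abeta numeric vector of global amyloid SUVRs.
#' @param cutoff positive SUVR cutoff (default 1.11).
#' @return data.frame with columns `global_abeta`, `cutoff`, `positive`.
#' @export
classify_abeta <- function(global_abeta, cutoff = 1.11) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("classify_abeta: 'cutoff' must be a single positive number",
         call. = FALSE)
  data.frame(
    subject_id = if (!is.null(names(global_abeta))) names(global_abeta) else
      seq_along(global_abeta),
    global_abeta = as.numeric(global_abeta),
    cutoff = cutoff,
    positive = as.numeric(global_abeta) >= cutoff,
    stringsAsFactors = FALSE
  )
}
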