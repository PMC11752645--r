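#' Cortical parcellation metadata
#'
#' A parcellation is the lookup table tying together the three ways a
#' cortical region of interest (ROI) is referenced throughout the package:
#' its dense id (1..N), its integer voxel label code in a label volume, and
#' its lobe annotation used when summarising maps.
#'
#' @param n_rois number of cortical ROIs (default 200, the resolution of
#'   the Schaefer cortical parcellation used for all regional analyses).
#' @param roi_names optional character vector of ROI names.
#' @param label_codes integer voxel label codes, one per ROI; must be
#'   unique and nonzero. Defaults to `1:n_rois`.
#' @param lobe per-ROI lobe annotation. The default assigns ids 1-50
#'   "frontal", 51-90 "parietal", 91-140 "temporal" and 141-N
#'   "occipital/other" — a deterministic synthetic stand-in for atlas lobe
#'   metadata, used by the cohort generator and map summaries.
#' @return A data.frame of class `parcellation` with columns `roi_id`,
#'   `roi_name`, `label_code`, `lobe`.
#' @export
parcellation <- function(n_rois = 200L, roi_names = NULL,
                         label_codes = seq_len(n_rois),
                         lobe = default_lobes(n_rois)) {
  n_rois <- as.integer(n_rois)
  if (is.na(n_rois) || n_rois < 1L)
    stop("parcellation: 'n_rois' must be a positive integer", call. = FALSE)
  label_codes <- as.integer(label_codes)
  if (length(label_codes) != n_rois)
    stop("parcellation: 'label_codes' must have one entry per ROI", call. = FALSE)
  if (anyDuplicated(label_codes) || any(label_codes == 0L) || anyNA(label_codes))
    stop("parcellation: label codes must be unique, nonzero and non-missing",
         call. = FALSE)
  if (is.null(roi_names))
    roi_names <- sprintf("ROI_%03d", seq_len(n_rois))
  if (length(roi_names) != n_rois || length(lobe) != n_rois)
    stop("parcellation: 'roi_names' and 'lobe' must have one entry per ROI",
         call. = FALSE)
  out <- data.frame(
    roi_id = seq_len(n_rois),
    roi_name = as.character(roi_names),
    label_code = label_codes,
    lobe = as.character(lobe),
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Default synthetic lobe assignment
#'
#' Ids 1-50 frontal, 51-90 parietal, 91-140 temporal, remainder
#' occipital/other (scaled proportionally when `n_rois != 200`).
#'
#' @param n_rois number of ROIs.
#' @return character vector of lobe labels.
#' @export
default_lobes <- function(n_rois = 200L) {
  # breakpoints defined at the 200-ROI resolution, scaled for other sizes
  frac <- c(frontal = 50, parietal = 90, temporal = 140) / 200
  cut_ids <- round(frac * n_rois)
  lobe <- rep("occipital/other", n_rois)
  id <- seq_len(n_rois)
  lobe[id <= cut_ids["temporal"]] <- "temporal"
  lobe[id <= cut_ids["parietal"]] <- "parietal"
  lobe[id <= cut_ids["frontal"]] <- "frontal"
  lobe
}

#' ROIs belonging to a lobe
#'
#' @param parc a [parcellation()].
#' @param lobe lobe label, e.g. `"frontal"`.
#' @return integer vector of ROI ids.
#' @export
lobe_rois <- function(parc, lobe) {
  stopifnot(inherits(parc, "parcellation"))
  parc$roi_id[parc$lobe %in% lobe]
}
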