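#' @name epicenters
#' @title Tau epicenter probability mapping
#' @description
#' A subject's tau "epicenters" are the regions with the highest tau-PET
#' SUVR — under the cross-sectional spreading assumption, the putative
#' earliest sites of tau accumulation. Per subject, all ROIs are rank
#' ordered by tau SUVR and the top 10% (20 of 200 ROIs) form the epicenter
#' set; at the group level each ROI's epicenter probability is the
#' fraction of the group's subjects whose set contains it. Maps are
#' computed on raw SUVRs without covariate adjustment and are invariant to
#' any strictly increasing transform of a subject's SUVR vector.
NULL

#' Rank ROIs by tau SUVR
#'
#' Descending SUVR order; ties are broken by ascending ROI id so the
#' ranking is deterministic.
#'
#' @param suvr numeric vector of one subject's regional SUVRs.
#' @return integer permutation of ROI ids (highest SUVR first).
#' @export
rank_rois <- function(suvr) {
  if (anyNA(suvr))
    stop("rank_rois: SUVR vector contains missing values", call. = FALSE)
  order(-as.numeric(suvr), seq_along(suvr))
}

#' Select the epicenter set from a ranking
#'
#' Takes the first `k = round(fraction * N)` ROIs of the ranking (never
#' fewer than 1; halves round up).
#'
#' @param ranking ROI ids from [rank_rois()].
#' @param fraction top fraction to select (default 0.10).
#' @return integer vector of epicenter ROI ids.
#' @export
select_epicenters <- function(ranking, fraction = 0.10) {
  if (fraction <= 0 || fraction > 0.5)
    stop("select_epicenters: 'fraction' must lie in (0, 0.5]", call. = FALSE)
  k <- max(1L, as.integer(floor(fraction * length(ranking) + 0.5)))
  ranking[seq_len(k)]
}

#' Group-level epicenter probability maps
#'
#' @param tau a [roi_suvr_table()] of tau SUVRs.
#' @param group per-subject group labels (aligned with the table's rows),
#'   or a subjects data.frame with `subject_id` and `group` columns.
#' @param fraction per-subject epicenter fraction (default 0.10).
#' @return named list of data.frames (one per group level), each of class
#'   `epicenter_map` with columns `roi_id`, `count`, `probability` and
#'   attributes `k`, `n_subjects`, `group`. Per group, `sum(count)` equals
#'   `k * n_subjects` exactly.
#' @export
epicenter_probability <- function(tau, group, fraction = 0.10) {
  if (is.data.frame(group))
    group <- group$group[match(rownames(tau$suvr), group$subject_id)]
  group <- factor(group)
  if (length(group) != nrow(tau$suvr))
    stop("epicenter_probability: one group label per subject required",
         call. = FALSE)
  nr <- ncol(tau$suvr)
  sets <- apply(tau$suvr, 1, function(v)
    select_epicenters(rank_rois(v), fraction))
  k <- if (is.matrix(sets)) nrow(sets) else length(sets[[1]])
  sets <- matrix(as.integer(sets), nrow = k)
  out <- lapply(levels(group), function(g) {
    cols <- which(group == g)
    counts <- tabulate(sets[, cols, drop = FALSE], nbins = nr)
    m <- data.frame(roi_id = seq_len(nr), count = counts,
                    probability = counts / length(cols))
    attr(m, "k") <- k
    attr(m, "n_subjects") <- length(cols)
    attr(m, "group") <- g
    class(m) <- c("epicenter_map", "data.frame")
    m
  })
  stats::setNames(out, levels(group))
}
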