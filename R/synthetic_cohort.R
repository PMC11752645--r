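#' @name synthetic-cohort
#' @title Synthetic veteran cohort with known ground truth
#' @description
#' Generates three-group cohorts (no TBI / mild TBI / moderate-severe TBI)
#' with configurable regional amyloid and tau effects, amyloid-tau
#' coupling slopes, covariates and TBI interview records, so that every
#' downstream estimator can be validated against injected ground truth.
#' The generative model is additive Gaussian: for subject i of group g and
#' ROI r,
#' \deqn{A_{ir} = \mu_A + a_i + \delta_A(g, r) + \epsilon_{ir}}
#' \deqn{T_{ir} = \mu_T + t_i + \delta_T(g, r) + \beta(g, r) (A_{ir} - \mu_A) + \eta_{ir}}
#' where \eqn{(a_i, t_i)} are correlated per-subject latent global levels,
#' \eqn{\delta} are the per-group regional offset templates, \eqn{\beta}
#' the regional amyloid-to-tau coupling slopes, and the residuals are iid
#' Gaussian ROI noise.
NULL

.tbi_groups <- c("no", "mild", "modsev")

#' Default regional offset templates
#'
#' Mirrors the qualitative pattern the analyses are designed to detect:
#' all groups share a temporal-lobe tau elevation (so tau epicenters fall
#' in temporal ROIs), the TBI groups carry a stepwise fronto-parietal
#' amyloid elevation (+0.04 mild, +0.08 moderate/severe SUVR), and the
#' moderate/severe group an extra frontal tau elevation (+0.06 SUVR).
#'
#' @param n_rois number of ROIs.
#' @param lobe per-ROI lobe labels (default [default_lobes()]).
#' @return list with elements `abeta` and `tau`, each an `n_rois` x 3
#'   matrix (columns "no", "mild", "modsev") of SUVR offsets.
#' @export
default_offset_template <- function(n_rois = 200L, lobe = default_lobes(n_rois)) {
  z <- matrix(0, n_rois, 3, dimnames = list(NULL, .tbi_groups))
  abeta <- tau <- z
  fp <- lobe %in% c("frontal", "parietal")
  abeta[fp, "mild"] <- 0.04
  abeta[fp, "modsev"] <- 0.08
  tau[lobe == "temporal", ] <- 0.12       # shared: temporal epicenters
  tau[lobe == "frontal", "modsev"] <- tau[lobe == "frontal", "modsev"] + 0.06
  list(abeta = abeta, tau = tau)
}

#' Default amyloid-to-tau coupling slope template
#'
#' A uniform slope of 0.3 for every ROI and group: amyloid and tau are
#' positively coupled everywhere, with no group moderation under the
#' default (a clean null for the interaction analysis).
#'
#' @param n_rois number of ROIs.
#' @param slope uniform slope value (default 0.3).
#' @return `n_rois` x 3 matrix (columns "no", "mild", "modsev").
#' @export
default_coupling_template <- function(n_rois = 200L, slope = 0.3) {
  matrix(slope, n_rois, 3, dimnames = list(NULL, .tbi_groups))
}

#' Default covariate model
#'
#' Per-group distributions for age (years), APOE e4 carrier probability,
#' MCI probability, the amyloid-to-tau scan lag (years), and the lag
#' between PET and the diagnosis date.
#'
#' @return named list of per-group parameter vectors.
#' @export
default_covariate_model <- function() {
  list(
    age_mean = c(no = 71.77, mild = 72.23, modsev = 70.69),
    age_sd = c(no = 5.34, mild = 5.01, modsev = 4.20),
    apoe_prob = c(no = 6 / 38, mild = 9 / 37, modsev = 8 / 23),
    mci_prob = c(no = 4 / 38, mild = 9 / 40, modsev = 10 / 25),
    abtau_lag_mean = c(no = 2.34, mild = 0.94, modsev = 0.76),
    abtau_lag_sd = c(no = 1.38, mild = 1.42, modsev = 1.21),
    diag_lag_mean = 0.8, diag_lag_sd = 0.6,
    tau_pet_year = 2018
  )
}

#' Default TBI event-count model
#'
#' Per-group distributions of the number of head-injury events for
#' TBI-positive subjects (empirical frequencies of 1/2/3/4/5/7 events).
#'
#' @return list with per-group `counts` and `probs`.
#' @export
default_event_count_model <- function() {
  list(
    mild = list(counts = c(1, 2, 3, 5, 7), probs = c(23, 8, 7, 1, 1) / 40),
    modsev = list(counts = c(1, 2, 3, 4, 5), probs = c(12, 7, 4, 1, 1) / 25),
    last_lag_mean = c(mild = 42.02, modsev = 35.80),
    last_lag_sd = c(mild = 18.04, modsev = 18.65)
  )
}

#' Simulation configuration
#'
#' Assembles and validates all parameters of the synthetic cohort. All
#' SUVR quantities are unitless ratios; lags and ages are in years.
#'
#' @param seed integer RNG seed; the entire cohort is reproducible from it.
#' @param group_sizes named sizes for the no / mild / moderate-severe TBI
#'   groups (each >= 2).
#' @param n_rois number of cortical ROIs (>= 20; default 200).
#' @param baseline_abeta_mean,baseline_tau_mean cohort-level baseline
#'   SUVRs (defaults 1.12 and 1.08).
#' @param subject_global_sd SD of the per-subject latent global level,
#'   per tracer `c(abeta=, tau=)`; a scalar is recycled. The tau default
#'   0.08 is the latent component only — coupling propagates amyloid
#'   variance into tau, bringing the realized global tau SD to ~0.09.
#' @param global_correlation correlation between the amyloid and tau
#'   latent globals (default 0.3), giving global-adjusted analyses
#'   realistic collinearity.
#' @param roi_noise_sd SD of independent per-ROI measurement noise
#'   (default 0.05 SUVR).
#' @param regional_offset_template list(abeta=, tau=) of `n_rois` x 3
#'   offset matrices; default [default_offset_template()].
#' @param coupling_slope_template `n_rois` x 3 matrix of amyloid-to-tau
#'   slopes; default [default_coupling_template()].
#' @param covariate_model list as from [default_covariate_model()].
#' @param missing_apoe_count per-group counts of subjects whose APOE
#'   status is set missing (default `c(no=0, mild=3, modsev=2)`).
#' @param event_count_model list as from [default_event_count_model()].
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       group_sizes = c(no = 38L, mild = 40L, modsev = 25L),
                       n_rois = 200L,
                       baseline_abeta_mean = 1.12,
                       baseline_tau_mean = 1.08,
                       subject_global_sd = c(abeta = 0.15, tau = 0.08),
                       global_correlation = 0.3,
                       roi_noise_sd = 0.05,
                       regional_offset_template = NULL,
                       coupling_slope_template = NULL,
                       covariate_model = default_covariate_model(),
                       missing_apoe_count = c(no = 0L, mild = 3L, modsev = 2L),
                       event_count_model = default_event_count_model()) {
  n_rois <- as.integer(n_rois)
  if (is.na(n_rois) || n_rois < 20L)
    stop("sim_config: 'n_rois' must be >= 20", call. = FALSE)
  if (length(group_sizes) != 3L || any(group_sizes < 2L))
    stop("sim_config: 'group_sizes' must be three sizes, all >= 2",
         call. = FALSE)
  names(group_sizes) <- .tbi_groups
  if (length(subject_global_sd) == 1L)
    subject_global_sd <- c(abeta = subject_global_sd, tau = subject_global_sd)
  names(subject_global_sd) <- c("abeta", "tau")
  if (any(subject_global_sd < 0) || roi_noise_sd < 0)
    stop("sim_config: 'subject_global_sd' and 'roi_noise_sd' must be >= 0",
         call. = FALSE)
  if (abs(global_correlation) > 1)
    stop("sim_config: 'global_correlation' must lie in [-1, 1]", call. = FALSE)
  if (is.null(regional_offset_template))
    regional_offset_template <- default_offset_template(n_rois)
  if (is.null(coupling_slope_template))
    coupling_slope_template <- default_coupling_template(n_rois)
  for (tr in c("abeta", "tau")) {
    m <- regional_offset_template[[tr]]
    if (is.null(m) || nrow(m) != n_rois || ncol(m) != 3L)
      stop(sprintf("sim_config: 'regional_offset_template$%s' must be an n_rois x 3 matrix", tr),
           call. = FALSE)
  }
  if (nrow(coupling_slope_template) != n_rois ||
      ncol(coupling_slope_template) != 3L)
    stop("sim_config: 'coupling_slope_template' must be an n_rois x 3 matrix",
         call. = FALSE)
  if (length(missing_apoe_count) == 1L)
    missing_apoe_count <- c(no = 0L, mild = 0L, modsev = 0L) + missing_apoe_count
  names(missing_apoe_count) <- .tbi_groups
  if (any(missing_apoe_count > group_sizes))
    stop("sim_config: 'missing_apoe_count' exceeds a group size", call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    group_sizes = stats::setNames(as.integer(group_sizes), .tbi_groups),
    n_rois = n_rois,
    baseline_abeta_mean = baseline_abeta_mean,
    baseline_tau_mean = baseline_tau_mean,
    subject_global_sd = subject_global_sd,
    global_correlation = global_correlation,
    roi_noise_sd = roi_noise_sd,
    regional_offset_template = regional_offset_template,
    coupling_slope_template = coupling_slope_template,
    covariate_model = covariate_model,
    missing_apoe_count = stats::setNames(as.integer(missing_apoe_count),
                                         .tbi_groups),
    event_count_model = event_count_model
  ), class = "sim_config")
}

#' Generate a synthetic cohort
#'
#' Draws covariates, latent global levels and the amyloid and tau ROI
#' SUVR tables under the additive Gaussian model described in
#' [synthetic-cohort]. Fully reproducible from `config$seed`; the
#' returned `truth` element carries the injected templates and latent
#' levels, sufficient to recompute every injected effect exactly.
#'
#' @param config a [sim_config()].
#' @return list of class `generated_cohort`: `subjects` (covariate
#'   data.frame with columns `subject_id`, `group`, `age`, `apoe`,
#'   `diagnosis`, `diag_lag`, `abtau_lag`, `tau_pet_date`,
#'   `abeta_pet_date`), `abeta` and `tau` ([roi_suvr_table()]s),
#'   `parcellation`, and `truth`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("generate_cohort: 'config' must be a sim_config", call. = FALSE)
  set.seed(config$seed)
  ns <- config$group_sizes
  n <- sum(ns)
  group <- factor(rep(.tbi_groups, ns), levels = .tbi_groups)
  ids <- sprintf("S%03d", seq_len(n))
  cm <- config$covariate_model

  gch <- as.character(group)
  age <- stats::rnorm(n, cm$age_mean[gch], cm$age_sd[gch])
  apoe <- stats::rbinom(n, 1, cm$apoe_prob[gch])
  diagnosis <- ifelse(stats::rbinom(n, 1, cm$mci_prob[gch]) == 1, "MCI", "CN")
  abtau_lag <- stats::rnorm(n, cm$abtau_lag_mean[gch], cm$abtau_lag_sd[gch])
  diag_lag <- stats::rnorm(n, cm$diag_lag_mean, cm$diag_lag_sd)
  tau_pet_date <- cm$tau_pet_year + stats::runif(n)
  # APOE missingness per group
  for (g in .tbi_groups) {
    k <- config$missing_apoe_count[[g]]
    if (k > 0) {
      idx <- which(group == g)
      apoe[sample(idx, k)] <- NA_integer_
    }
  }

  # correlated per-subject latent global levels
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  rho <- config$global_correlation
  g_abeta <- config$subject_global_sd[["abeta"]] * z1
  g_tau <- config$subject_global_sd[["tau"]] * (rho * z1 + sqrt(1 - rho^2) * z2)

  nr <- config$n_rois
  off_a <- config$regional_offset_template$abeta
  off_t <- config$regional_offset_template$tau
  slopes <- config$coupling_slope_template
  gi <- as.integer(group)

  noise_a <- matrix(stats::rnorm(n * nr, 0, config$roi_noise_sd), n, nr)
  noise_t <- matrix(stats::rnorm(n * nr, 0, config$roi_noise_sd), n, nr)
  abeta_dev <- g_abeta + t(off_a)[gi, , drop = FALSE] + noise_a
  abeta_mat <- config$baseline_abeta_mean + abeta_dev
  tau_mat <- config$baseline_tau_mean + g_tau +
    t(off_t)[gi, , drop = FALSE] + t(slopes)[gi, , drop = FALSE] * abeta_dev +
    noise_t
  dimnames(abeta_mat) <- dimnames(tau_mat) <- list(ids, seq_len(nr))

  subjects <- data.frame(
    subject_id = ids, group = group, age = age, apoe = apoe,
    diagnosis = diagnosis, diag_lag = diag_lag, abtau_lag = abtau_lag,
    tau_pet_date = tau_pet_date, abeta_pet_date = tau_pet_date - abtau_lag,
    stringsAsFactors = FALSE
  )
  structure(list(
    subjects = subjects,
    abeta = roi_suvr_table(abeta_mat, "amyloid",
                           scan_date = subjects$abeta_pet_date),
    tau = roi_suvr_table(tau_mat, "tau", scan_date = subjects$tau_pet_date),
    parcellation = parcellation(nr),
    truth = list(config = config,
                 latent = data.frame(subject_id = ids, g_abeta = g_abeta,
                                     g_tau = g_tau, stringsAsFactors = FALSE))
  ), class = "generated_cohort")
}

#' @export
print.generated_cohort <- function(x, ...) {
  cat(sprintf("<generated_cohort> %d subjects (%s), %d ROIs\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", levels(x$subjects$group),
                            table(x$subjects$group)), collapse = ", "),
              ncol(x$abeta$suvr)))
  invisible(x)
}

#' Generate TBI interview records for a cohort
#'
#' Draws per-subject head-injury event lists consistent with each
#' subject's generating group: no-TBI subjects get empty lists; mild-group
#' subjects only events whose symptom categories grade mild; and
#' moderate/severe-group subjects at least one event with a
#' moderate/severe symptom (LOC > 30 min, or AOC/amnesia > 24 h). Event
#' counts follow the configurable per-group count model, event timing the
#' configured lag distributions, and every event precedes the subject's
#' tau-PET date, so feeding the records back through
#' [classify_cohort_tbi()] recovers the generating labels exactly.
#'
#' @param subjects subject data.frame from [generate_cohort()].
#' @param config the same [sim_config()].
#' @param service_window years of military service used to assign periods
#'   (default 1964-1975).
#' @return named list (by subject id) of [tbi_events()] data.frames.
#' @export
generate_tbi_records <- function(subjects, config,
                                 service_window = c(1964, 1975)) {
  set.seed(config$seed + 1L)
  em <- config$event_count_model
  out <- vector("list", nrow(subjects))
  names(out) <- subjects$subject_id
  mild_loc <- c("na", "lt30min")
  mild_aoc <- c("na", "lt24h")
  for (i in seq_len(nrow(subjects))) {
    g <- as.character(subjects$group[i])
    if (g == "no") { out[[i]] <- tbi_events()[0, ]; next }
    k <- sample(em[[g]]$counts, 1, prob = em[[g]]$probs)
    # event lags back from the tau-PET date; latest event first
    last_lag <- max(1, stats::rnorm(1, em$last_lag_mean[[g]], em$last_lag_sd[[g]]))
    lags <- last_lag + c(0, cumsum(stats::rexp(k - 1, rate = 1 / 5)))
    years <- floor(subjects$tau_pet_date[i] - lags)
    period <- ifelse(years < service_window[1], "before",
                     ifelse(years <= service_window[2], "during", "since"))
    loc <- sample(mild_loc, k, replace = TRUE, prob = c(0.4, 0.6))
    aoc <- sample(mild_aoc, k, replace = TRUE, prob = c(0.3, 0.7))
    amn <- sample(mild_aoc, k, replace = TRUE, prob = c(0.5, 0.5))
    if (g == "modsev") {
      j <- sample.int(k, 1)
      which_sym <- sample(c("loc", "aoc", "amnesia"), 1)
      if (which_sym == "loc")
        loc[j] <- sample(c("min30_to_24h", "gt24h"), 1, prob = c(0.7, 0.3))
      else if (which_sym == "aoc") aoc[j] <- "gt24h"
      else amn[j] <- "gt24h"
    }
    age_at <- subjects$age[i] - lags
    out[[i]] <- tbi_events(period = period, year = years, age_at_event = age_at,
                           loc = loc, aoc = aoc, amnesia = amn)
  }
  out
}

#' Generate a labelled voxel phantom
#'
#' Builds a small 3-D uptake volume in which each ROI of the parcellation
#' occupies a contiguous cubic block with Gaussian uptake around its
#' nominal mean, plus a reference region around `ref_mean`, for exercising
#' [extract_roi_suvr()] end-to-end. Unassigned voxels are background
#' (label 0) and excluded from the grey-matter mask.
#'
#' @param parc a [parcellation()].
#' @param roi_means per-ROI nominal uptake values.
#' @param ref_mean nominal reference-region uptake.
#' @param noise_sd SD of iid Gaussian voxel noise (0 gives exact means).
#' @param seed RNG seed.
#' @param dim 3-D volume dimensions (default `c(40, 40, 40)`).
#' @param ref_label voxel label code for the reference region; must not
#'   collide with an ROI label (default `max(label codes) + 1`).
#' @return list: `uptake`, `labels`, `gm_mask` (3-D arrays), `ref_label`,
#'   `voxel_counts` (per-ROI).
#' @export
generate_voxel_phantom <- function(parc, roi_means, ref_mean, noise_sd = 0,
                                   seed = 1L, dim = c(40L, 40L, 40L),
                                   ref_label = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  nr <- nrow(parc)
  if (length(roi_means) != nr)
    stop("generate_voxel_phantom: need one mean per ROI", call. = FALSE)
  if (is.null(ref_label)) ref_label <- max(parc$label_code) + 1L
  if (ref_label %in% parc$label_code)
    stop("generate_voxel_phantom: reference label collides with an ROI label",
         call. = FALSE)
  n_blocks_needed <- nr + 1L
  nb <- ceiling(n_blocks_needed^(1 / 3))
  while (nb^3 < n_blocks_needed) nb <- nb + 1L
  side <- floor(min(dim) / nb)
  if (side < 1L)
    stop("generate_voxel_phantom: volume too small for this parcellation",
         call. = FALSE)
  labels <- array(0L, dim)
  codes <- c(parc$label_code, as.integer(ref_label))
  idx0 <- seq_along(codes) - 1L
  bi <- idx0 %% nb
  bj <- (idx0 %/% nb) %% nb
  bk <- idx0 %/% (nb * nb)
  for (b in seq_along(codes)) {
    xs <- bi[b] * side + seq_len(side)
    ys <- bj[b] * side + seq_len(side)
    zs <- bk[b] * side + seq_len(side)
    if (any(labels[xs, ys, zs] != 0L))
      stop("generate_voxel_phantom: overlapping label assignment", call. = FALSE)
    labels[xs, ys, zs] <- codes[b]
  }
  set.seed(seed)
  means <- stats::setNames(c(roi_means, ref_mean), codes)
  uptake <- array(0, dim)
  in_lab <- labels != 0L
  uptake[in_lab] <- means[as.character(labels[in_lab])] +
    stats::rnorm(sum(in_lab), 0, noise_sd)
  gm_mask <- array(FALSE, dim)
  gm_mask[in_lab] <- TRUE
  counts <- table(factor(labels[in_lab], levels = parc$label_code))
  list(uptake = uptake, labels = labels, gm_mask = gm_mask,
       ref_label = as.integer(ref_label),
       voxel_counts = stats::setNames(as.integer(counts), parc$roi_id))
}
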