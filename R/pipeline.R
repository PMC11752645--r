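#' Analysis configuration
#'
#' Thresholds and options shared by the pipeline stages.
#'
#' @param alpha two-tailed significance level (default 0.05).
#' @param fdr_q FDR level for regional maps (default 0.05).
#' @param epicenter_fraction per-subject epicenter fraction in (0, 0.5]
#'   (default 0.10).
#' @param abeta_cutoff global amyloid SUVR positivity cutoff (default
#'   1.11; a stand-in for externally calibrated cohort cutoffs).
#' @param seed RNG seed for the simulation stage.
#' @param combine_groups also run regional/coupling maps on the collapsed
#'   no-TBI vs any-TBI grouping (default FALSE).
#' @return validated list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, fdr_q = 0.05,
                            epicenter_fraction = 0.10, abeta_cutoff = 1.11,
                            seed = 1L, combine_groups = FALSE) {
  if (alpha <= 0 || alpha >= 1)
    stop("analysis_config: 'alpha' must lie in (0, 1)", call. = FALSE)
  if (fdr_q <= 0 || fdr_q >= 1)
    stop("analysis_config: 'fdr_q' must lie in (0, 1)", call. = FALSE)
  if (epicenter_fraction <= 0 || epicenter_fraction > 0.5)
    stop("analysis_config: 'epicenter_fraction' must lie in (0, 0.5]",
         call. = FALSE)
  if (abeta_cutoff <= 0)
    stop("analysis_config: 'abeta_cutoff' must be positive", call. = FALSE)
  structure(list(alpha = alpha, fdr_q = fdr_q,
                 epicenter_fraction = epicenter_fraction,
                 abeta_cutoff = abeta_cutoff, seed = as.integer(seed),
                 combine_groups = isTRUE(combine_groups)),
            class = "analysis_config")
}

.stage <- function(name, log_env, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  msg <- sprintf("[%s] done in %.2fs", name, proc.time()[["elapsed"]] - t0)
  log_env$log <- c(log_env$log, msg)
  if (!quiet) message(msg)
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the four analysis aims in order on a generated cohort:
#' (1) cohort/demographic statistics and global SUVR ANCOVAs, (2)
#' global-burden-adjusted regional contrast maps with FDR, (3) tau
#' epicenter probability maps, and (4) amyloid-by-TBI coupling moderation
#' maps — preceded by cohort simulation, TBI interview record generation
#' and rule-based TBI classification. Deterministic given the seed; when
#' `out_dir` is supplied every artifact is written as plain text together
#' with a checksum manifest.
#'
#' @param config an [analysis_config()].
#' @param sim a [sim_config()]; defaults to the standard synthetic cohort
#'   at `config$seed`.
#' @param out_dir optional output directory (created if needed).
#' @param quiet suppress per-stage log messages (default FALSE).
#' @return list of class `pipeline_result`: `cohort`, `tbi` (status table
#'   + reconciliation of generated records), `demographics`, `global`,
#'   `regional` (named list of contrast maps), `epicenters`, `coupling`
#'   (maps + lobe summaries), `manifest` (when written), `log`.
#' @export
run_pipeline <- function(config = analysis_config(),
                         sim = sim_config(seed = config$seed),
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"), inherits(sim, "sim_config"))
  lg <- new.env()
  lg$log <- character(0)
  pairs <- list(c("no", "mild"), c("no", "modsev"), c("mild", "modsev"))

  cohort <- .stage("simulate", lg, quiet, generate_cohort(sim))
  subjects <- cohort$subjects

  tbi <- .stage("classify-tbi", lg, quiet, {
    records <- generate_tbi_records(subjects, sim)
    status <- classify_cohort_tbi(records, stats::setNames(
      subjects$tau_pet_date, subjects$subject_id))
    status$group_recovered <- c(none = "no", mild = "mild",
                                moderate_severe = "modsev")[status$severity]
    list(records = records, status = status,
         frequency_table = tbi_frequency_table(status$frequency))
  })

  demographics <- .stage("demographics", lg, quiet, {
    by_group <- split(seq_len(nrow(subjects)), subjects$group)
    lag_groups <- lapply(by_group, function(i) subjects$abtau_lag[i])
    list(
      age = group_summary(subjects$age, subjects$group),
      abtau_lag = group_summary(subjects$abtau_lag, subjects$group),
      mci = group_summary(subjects$diagnosis, subjects$group),
      age_anova = anova_oneway(lapply(by_group, function(i) subjects$age[i]),
                               alpha = config$alpha),
      lag_anova = anova_oneway(lag_groups, alpha = config$alpha),
      lag_tukey_no_mild = tukey_hsd(lag_groups, c("mild", "no"),
                                    alpha = config$alpha),
      lag_tukey_no_modsev = tukey_hsd(lag_groups, c("modsev", "no"),
                                      alpha = config$alpha),
      mci_fisher_no_modsev = tryCatch(fisher_exact_2x2(table(
        factor(subjects$diagnosis[subjects$group %in% c("no", "modsev")],
               levels = c("MCI", "CN")),
        factor(subjects$group[subjects$group %in% c("no", "modsev")],
               levels = c("modsev", "no"))
      ), alpha = config$alpha),
      error = function(e) stat_result("odds_ratio", NA_real_))
    )
  })

  glob <- .stage("cohort_stats", lg, quiet, list(
    abeta_ancova = ancova_global(subjects, cohort$abeta, cohort$tau,
                                 "amyloid", alpha = config$alpha),
    tau_ancova = ancova_global(subjects, cohort$abeta, cohort$tau, "tau",
                               alpha = config$alpha),
    abeta_status = classify_abeta(cohort$abeta$global_suvr,
                                  config$abeta_cutoff)
  ))

  regional <- .stage("regional", lg, quiet, {
    maps <- list()
    for (pr in pairs) for (mod in c("amyloid", "tau"))
      maps[[paste(pr[1], pr[2], mod, sep = "_")]] <-
        roiwise_ancova(subjects, cohort$abeta, cohort$tau, pr, mod,
                       q_level = config$fdr_q)
    if (config$combine_groups) {
      two <- combine_tbi_groups(subjects)
      for (mod in c("amyloid", "tau"))
        maps[[paste("no_tbi", mod, sep = "_")]] <-
          roiwise_ancova(two, cohort$abeta, cohort$tau, c("no", "tbi"), mod,
                         q_level = config$fdr_q)
    }
    maps
  })

  epicenters <- .stage("epicenters", lg, quiet,
    epicenter_probability(cohort$tau, subjects,
                          fraction = config$epicenter_fraction))

  coupling <- .stage("coupling", lg, quiet, {
    maps <- list()
    for (pr in pairs)
      maps[[paste(pr[1], pr[2], sep = "_")]] <-
        roiwise_interaction(subjects, cohort$abeta, cohort$tau, pr,
                            q_level = config$fdr_q)
    list(maps = maps,
         summaries = lapply(maps, summarize_significant,
                            parc = cohort$parcellation))
  })

  result <- structure(list(
    config = config, cohort = cohort, tbi = tbi,
    demographics = demographics, global = glob, regional = regional,
    epicenters = epicenters, coupling = coupling, manifest = NULL,
    log = lg$log
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    result$manifest <- .stage("report", lg, quiet,
                              .write_bundle(result, out_dir, sim))
    result$log <- lg$log
    writeLines(result$log, file.path(out_dir, "pipeline.log"))
  }
  result
}

.write_bundle <- function(result, out_dir, sim) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(out_dir, ...)
  write_subjects(result$cohort$subjects, f("subjects.csv"))
  write_suvr_table(result$cohort$abeta, f("suvr_amyloid.tsv"))
  write_suvr_table(result$cohort$tau, f("suvr_tau.tsv"))
  write_parcellation(result$cohort$parcellation, f("parcellation.tsv"))
  write_truth_json(result$cohort$truth, f("truth.json"))
  utils::write.table(result$tbi$status, f("tbi_status.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stats_rows <- rbind(
    cbind(test = "age_anova", result$demographics$age_anova[1, 1:9]),
    cbind(test = "lag_anova", result$demographics$lag_anova[1, 1:9]),
    cbind(test = "lag_tukey_no_mild",
          result$demographics$lag_tukey_no_mild[1, 1:9]),
    cbind(test = "lag_tukey_no_modsev",
          result$demographics$lag_tukey_no_modsev[1, 1:9]),
    cbind(test = "mci_fisher_no_modsev",
          result$demographics$mci_fisher_no_modsev[1, 1:9]),
    cbind(test = "global_abeta_ancova", result$global$abeta_ancova[1, 1:9]),
    cbind(test = "global_tau_ancova", result$global$tau_ancova[1, 1:9])
  )
  write_map(stats_rows, f("stats.tsv"))
  for (nm in names(result$regional))
    write_map(result$regional[[nm]], f(paste0("regional_", nm, ".tsv")))
  for (nm in names(result$epicenters))
    write_map(result$epicenters[[nm]], f(paste0("epicenters_", nm, ".tsv")))
  for (nm in names(result$coupling$maps))
    write_map(result$coupling$maps[[nm]], f(paste0("coupling_", nm, ".tsv")))
  cfg_path <- f("config.json")
  write_config(result$config, cfg_path)

  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    bytes = as.integer(file.size(f(files))),
    md5 = unname(tools::md5sum(f(files))),
    stringsAsFactors = FALSE
  )
  attr(manifest, "config_md5") <- unname(tools::md5sum(cfg_path))
  attr(manifest, "package_version") <- as.character(utils::packageVersion("tbipet"))
  hdr <- sprintf("# tbipet %s, config md5 %s",
                 attr(manifest, "package_version"),
                 attr(manifest, "config_md5"))
  writeLines(c(hdr, "file\tbytes\tmd5",
               sprintf("%s\t%d\t%s", manifest$file, manifest$bytes,
                       manifest$md5)),
             f("manifest.tsv"))
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  n_sig <- vapply(x$regional, function(m) sum(m$significant), 0L)
  cat("<pipeline_result>\n")
  cat(sprintf("  subjects: %d | global ANCOVA F(amyloid)=%.2f p=%.3f, F(tau)=%.2f p=%.3f\n",
              nrow(x$cohort$subjects), x$global$abeta_ancova$value,
              x$global$abeta_ancova$p, x$global$tau_ancova$value,
              x$global$tau_ancova$p))
  cat("  significant ROIs per regional map:\n")
  for (nm in names(n_sig)) cat(sprintf("    %-20s %d\n", nm, n_sig[[nm]]))
  invisible(x)
}
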