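#' @name io
#' @title Reading and writing pipeline artifacts
#' @description
#' All tabular artifacts are plain text: SUVR tables and maps as
#' tab-separated values, subject covariates as CSV, parcellation metadata
#' as TSV, configuration as YAML or JSON, ground truth as JSON, volumes
#' as NIfTI-1. Numeric values are written with 17 significant digits so
#' write-then-read round-trips reproduce doubles exactly. Readers parse
#' numerics strictly (C locale, `.` decimal separator) and report the
#' offending line on failure rather than silently coercing.
NULL

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.parse_num <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & !(x %in% c("NA", "NaN", "")))
  if (length(bad))
    stop(sprintf("%s: non-numeric value '%s' in column '%s', line %d",
                 path, x[bad[1]], what, bad[1] + 1L), call. = FALSE)
  out
}

#' Write / read an ROI SUVR table as TSV
#'
#' Columns: `subject_id`, `scan_date`, `global_suvr`, then one `roi_<id>`
#' column per ROI.
#'
#' @param x a [roi_suvr_table()].
#' @param path output file.
#' @return `write_suvr_table` returns `path` invisibly; `read_suvr_table`
#'   returns a [roi_suvr_table()].
#' @export
write_suvr_table <- function(x, path) {
  stopifnot(inherits(x, "roi_suvr_table"))
  n <- nrow(x$suvr)
  scan_date <- if (is.null(x$scan_date)) rep(NA_real_, n) else x$scan_date
  header <- c("subject_id", "scan_date", "global_suvr",
              paste0("roi_", colnames(x$suvr)))
  rows <- vapply(seq_len(n), function(i)
    paste(c(rownames(x$suvr)[i], .fmt_num(scan_date[i]),
            .fmt_num(x$global_suvr[i]), .fmt_num(x$suvr[i, ])),
          collapse = "\t"), "")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' @rdname write_suvr_table
#' @param tracer tracer of the table being read.
#' @export
read_suvr_table <- function(path, tracer = c("amyloid", "tau")) {
  tracer <- match.arg(tracer)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("subject_id", "scan_date", "global_suvr")
  if (!all(need %in% names(raw)))
    stop(path, ": missing column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  roi_cols <- grep("^roi_", names(raw), value = TRUE)
  m <- vapply(roi_cols, function(cl) .parse_num(raw[[cl]], cl, path),
              numeric(nrow(raw)))
  m <- matrix(m, nrow = nrow(raw),
              dimnames = list(raw$subject_id, sub("^roi_", "", roi_cols)))
  roi_suvr_table(m, tracer,
                 global_suvr = .parse_num(raw$global_suvr, "global_suvr", path),
                 scan_date = .parse_num(raw$scan_date, "scan_date", path))
}

#' Write / read the subject covariate table as CSV
#'
#' @param subjects subject data.frame (see [generate_cohort()]).
#' @param path output file.
#' @return the path (write) or the subjects data.frame (read), with
#'   `group` restored as a factor.
#' @export
write_subjects <- function(subjects, path) {
  df <- subjects
  for (cl in names(df)) if (is.numeric(df[[cl]])) df[[cl]] <- .fmt_num(df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  num_cols <- c("age", "apoe", "diag_lag", "abtau_lag", "tau_pet_date",
                "abeta_pet_date")
  for (cl in intersect(num_cols, names(df)))
    df[[cl]] <- .parse_num(df[[cl]], cl, path)
  lev <- if (all(df$group %in% c("no", "tbi"))) c("no", "tbi") else .tbi_groups
  df$group <- factor(df$group, levels = lev)
  df
}

#' Write / read parcellation metadata as TSV
#'
#' @param parc a [parcellation()].
#' @param path output file.
#' @export
write_parcellation <- function(parc, path) {
  utils::write.table(as.data.frame(parc), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  parcellation(nrow(df), roi_names = df$roi_name,
               label_codes = df$label_code, lobe = df$lobe)
}

#' Write / read an analysis configuration as YAML or JSON
#'
#' The format is chosen from the file extension (`.yaml`/`.yml` or
#' `.json`).
#'
#' @param config a flat named list (e.g. [analysis_config()]).
#' @param path output file.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("write_config: unknown config format: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("read_config: no such file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("read_config: unknown config format: ", path, call. = FALSE)
}

#' Write the cohort ground truth as JSON
#'
#' Serializes the injected templates and per-subject latent levels of a
#' generated cohort, sufficient to recompute every injected effect.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  x <- list(
    config = truth$config[c("seed", "group_sizes", "n_rois",
                            "baseline_abeta_mean", "baseline_tau_mean",
                            "subject_global_sd", "global_correlation",
                            "roi_noise_sd")],
    regional_offset_template = lapply(truth$config$regional_offset_template,
                                      function(m) as.data.frame(m)),
    coupling_slope_template = as.data.frame(truth$config$coupling_slope_template),
    latent = truth$latent
  )
  jsonlite::write_json(x, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Write / read a 3-D volume as NIfTI-1
#'
#' Thin wrappers over RNifti. Reading a truncated or malformed file
#' raises a parse error naming the file instead of crashing.
#'
#' @param vol numeric/integer 3-D array.
#' @param path `.nii` or `.nii.gz` file path.
#' @export
write_nifti <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  if (!file.exists(path))
    stop("read_nifti: no such file: ", path, call. = FALSE)
  out <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("read_nifti: failed to parse '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  array(as.numeric(out), dim = dim(out))
}

#' Write a per-ROI map (contrast, moderation or epicenter) as TSV
#'
#' @param map a data.frame map.
#' @param path output file.
#' @export
write_map <- function(map, path) {
  df <- as.data.frame(map)
  for (cl in names(df))
    if (is.numeric(df[[cl]]) && !is.integer(df[[cl]]))
      df[[cl]] <- .fmt_num(df[[cl]])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paint per-ROI values back onto a label volume
#'
#' @param values named/per-ROI numeric vector (length = number of ROIs).
#' @param labels integer label volume.
#' @param parc a [parcellation()].
#' @return numeric array of the label volume's shape with each ROI voxel
#'   carrying its ROI value; background 0.
#' @export
map_to_volume <- function(values, labels, parc) {
  stopifnot(inherits(parc, "parcellation"))
  if (length(values) != nrow(parc))
    stop("map_to_volume: one value per ROI required", call. = FALSE)
  out <- array(0, dim(labels))
  idx <- match(as.integer(labels), parc$label_code)
  hit <- !is.na(idx)
  out[hit] <- values[idx[hit]]
  out
}
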