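#' @name cohort-stats
#' @title Group-level demographic and global-PET statistics
#' @description
#' Every test returns a one-row "tidy" data.frame with a common column
#' layout (`statistic`, `value`, `df1`, `df2`, `p`, `estimate`, `ci_low`,
#' `ci_high`, `alpha`) so results can be row-bound into a single results
#' table. Significance is two-tailed at `alpha = 0.05` throughout unless
#' overridden.
NULL

stat_result <- function(statistic, value, df1 = NA_real_, df2 = NA_real_,
                        p = NA_real_, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, alpha = 0.05) {
  data.frame(statistic = statistic, value = value, df1 = df1, df2 = df2,
             p = p, estimate = estimate, ci_low = ci_low, ci_high = ci_high,
             alpha = alpha, stringsAsFactors = FALSE)
}

# Normalize ANOVA input: list of numeric vectors, or a data.frame with
# columns mean, sd, n (one row per group). Returns list(means, sds, ns,
# ss_within) where ss_within is exact for raw input.
.anova_groups <- function(x) {
  if (is.data.frame(x)) {
    need <- c("mean", "sd", "n")
    if (!all(need %in% names(x)))
      stop("summary input needs columns 'mean', 'sd', 'n'", call. = FALSE)
    if (any(x$n < 2))
      stop("each group needs n >= 2 for variance-based tests", call. = FALSE)
    list(means = x$mean, sds = x$sd, ns = x$n,
         ss_within = sum((x$n - 1) * x$sd^2))
  } else if (is.list(x)) {
    if (any(lengths(x) < 2))
      stop("each group needs n >= 2 for variance-based tests", call. = FALSE)
    list(means = vapply(x, mean, 0), sds = vapply(x, stats::sd, 0),
         ns = lengths(x),
         ss_within = sum(vapply(x, function(v) sum((v - mean(v))^2), 0)))
  } else stop("expected a list of numeric vectors or a mean/sd/n data.frame",
              call. = FALSE)
}

#' One-way ANOVA from raw vectors or group summaries
#'
#' Classic one-way F with degrees of freedom (k-1, N-k). Accepts either a
#' list of per-group numeric vectors or a summary data.frame with columns
#' `mean`, `sd`, `n` — the summary form reconstructs the between- and
#' within-group sums of squares from the printed summaries and agrees with
#' the raw-data form exactly when the summaries are exact.
#'
#' @param x list of numeric vectors, or data.frame(mean, sd, n).
#' @param alpha significance level recorded in the result (default 0.05).
#' @return one-row data.frame (see [cohort-stats]); `value` is F. When all
#'   groups have zero within-group variance but unequal means, F is
#'   `Inf` and `p = 0` (flagged, not an error).
#' @export
anova_oneway <- function(x, alpha = 0.05) {
  g <- .anova_groups(x)
  k <- length(g$means)
  if (k < 2) stop("anova_oneway: need at least two groups", call. = FALSE)
  N <- sum(g$ns)
  grand <- sum(g$ns * g$means) / N
  ss_between <- sum(g$ns * (g$means - grand)^2)
  df1 <- k - 1
  df2 <- N - k
  ms_between <- ss_between / df1
  ms_within <- g$ss_within / df2
  f <- if (ms_within == 0) {
    if (ms_between == 0) 0 else Inf
  } else ms_between / ms_within
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  stat_result("F", f, df1, df2, p, alpha = alpha)
}

#' Tukey HSD pairwise comparison from raw vectors or group summaries
#'
#' Difference of two group means with a simultaneous confidence interval
#' based on the studentized range over all `k` groups of the design:
#' `diff +/- q(1-alpha, k, N-k)/sqrt(2) * sqrt(MSW * (1/n_i + 1/n_j))`,
#' with the adjusted p-value from the studentized-range distribution.
#'
#' @param x list of numeric vectors or data.frame(mean, sd, n); group
#'   names are taken from names/rownames.
#' @param pair length-2 vector (names or indices) selecting the
#'   comparison, reported as `pair[1] - pair[2]`.
#' @param alpha family-wise error level (default 0.05).
#' @return one-row data.frame; `estimate` is the mean difference, `value`
#'   the studentized-range statistic.
#' @export
tukey_hsd <- function(x, pair, alpha = 0.05) {
  g <- .anova_groups(x)
  k <- length(g$means)
  nm <- if (is.data.frame(x)) rownames(x) else names(x)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  idx <- if (is.numeric(pair)) as.integer(pair) else match(pair, nm)
  if (anyNA(idx) || length(idx) != 2L)
    stop("tukey_hsd: 'pair' must select two groups", call. = FALSE)
  N <- sum(g$ns)
  df2 <- N - k
  msw <- g$ss_within / df2
  if (msw == 0)
    stop("tukey_hsd: zero within-group variance in every group", call. = FALSE)
  diff <- g$means[idx[1]] - g$means[idx[2]]
  se <- sqrt(msw * (1 / g$ns[idx[1]] + 1 / g$ns[idx[2]]))
  qcrit <- stats::qtukey(1 - alpha, k, df2)
  half <- qcrit / sqrt(2) * se
  qstat <- abs(diff) / (se / sqrt(2))
  p <- stats::ptukey(qstat, k, df2, lower.tail = FALSE)
  out <- stat_result("q", qstat, k, df2, p, estimate = diff,
                     ci_low = diff - half, ci_high = diff + half,
                     alpha = alpha)
  out$contrast <- paste(nm[idx[1]], "-", nm[idx[2]])
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact hypergeometric p-value with the conditional
#' maximum-likelihood odds ratio (the maximizer of the noncentral
#' hypergeometric likelihood, as returned by [stats::fisher.test()]) and
#' the exact conditional confidence interval. Note the conditional MLE is
#' not the sample cross-product ratio `(ad)/(bc)`; both are reported.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alpha significance level; CI level is `1 - alpha`.
#' @return one-row data.frame; `estimate` is the conditional-MLE odds
#'   ratio, `value` the sample cross-product odds ratio (NA when a margin
#'   is zero).
#' @export
fisher_exact_2x2 <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L)) || any(table < 0) ||
      any(table != round(table)))
    stop("fisher_exact_2x2: need a 2x2 table of non-negative integers",
         call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("fisher_exact_2x2: zero margin, odds ratio undefined", call. = FALSE)
  ft <- stats::fisher.test(table, conf.level = 1 - alpha)
  sample_or <- if (table[1, 2] * table[2, 1] == 0) NA_real_ else
    (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  stat_result("odds_ratio", sample_or, p = ft$p.value,
              estimate = unname(ft$estimate),
              ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
              alpha = alpha)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square on an r x c contingency table (no Yates
#' continuity correction, matching the plain "Pearson's chi-square test of
#' independence"). Warns when any expected cell count falls below 1 and
#' recommends an exact test.
#'
#' @param table contingency table (matrix of counts).
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame; `value` is the chi-square statistic.
#' @export
chi_square_independence <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 1))
    warning("chi_square_independence: expected cell count < 1; consider an exact test",
            call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  stat_result("chi_square", unname(ct$statistic), df1 = unname(ct$parameter),
              p = ct$p.value, alpha = alpha)
}

#' Two-sample t-test from raw vectors or summaries
#'
#' Pooled-variance Student t by default (set `var_equal = FALSE` for
#' Welch). Accepts two numeric vectors, or two summary lists/rows with
#' `mean`, `sd`, `n`.
#'
#' @param x,y numeric vectors, or lists/one-row data.frames with elements
#'   `mean`, `sd`, `n`.
#' @param var_equal pooled variance (TRUE, default) or Welch (FALSE).
#' @param alpha significance level; CI level is `1 - alpha`.
#' @return one-row data.frame; `estimate` is `mean(x) - mean(y)`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE, alpha = 0.05) {
  summ <- function(v) {
    if (is.numeric(v) && length(v) > 1 && is.null(dim(v)))
      list(mean = mean(v), sd = stats::sd(v), n = length(v))
    else as.list(v)[c("mean", "sd", "n")]
  }
  a <- summ(x); b <- summ(y)
  if (a$n < 2 || b$n < 2)
    stop("two_sample_t: each sample needs n >= 2", call. = FALSE)
  diff <- a$mean - b$mean
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tval <- diff / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stat_result("t", tval, df1 = df, p = p, estimate = diff,
              ci_low = diff - tcrit * se, ci_high = diff + tcrit * se,
              alpha = alpha)
}

#' Global SUVR ANCOVA across TBI groups
#'
#' Least-squares model of the global tracer SUVR on the (3-level) TBI
#' group plus covariates, reporting the partial F for the group factor.
#' The amyloid model adjusts for age, cognitive diagnosis, APOE e4
#' carriage, and the lag between the PET scan and the diagnosis date; the
#' tau model additionally adjusts for the global amyloid SUVR and the lag
#' between the amyloid and tau scans. Subjects with any missing covariate
#' are dropped (listwise deletion), so APOE missingness shrinks the
#' analysed sample.
#'
#' @param subjects subject covariate data.frame (see [generate_cohort()]
#'   for the column layout: `group`, `age`, `diagnosis`, `apoe`,
#'   `diag_lag`, `abtau_lag`).
#' @param abeta,tau [roi_suvr_table()]s supplying the global SUVRs.
#' @param modality `"amyloid"` or `"tau"`: which global SUVR is the
#'   outcome.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame; `value` is the partial F for the group
#'   factor, `df2` the residual degrees of freedom, and an `n` column
#'   records the complete-case count.
#' @export
ancova_global <- function(subjects, abeta, tau,
                          modality = c("amyloid", "tau"), alpha = 0.05) {
  modality <- match.arg(modality)
  dat <- data.frame(
    y = if (modality == "amyloid") abeta$global_suvr[subjects$subject_id]
        else tau$global_suvr[subjects$subject_id],
    group = factor(subjects$group),
    age = subjects$age,
    diagnosis = factor(subjects$diagnosis),
    apoe = subjects$apoe,
    diag_lag = subjects$diag_lag
  )
  if (modality == "tau") {
    dat$global_abeta <- abeta$global_suvr[subjects$subject_id]
    dat$abtau_lag <- subjects$abtau_lag
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$group <- droplevels(dat$group)
  full <- stats::lm(y ~ ., data = dat)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("ancova_global: rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df2 <- full$df.residual
  if (df2 < 1)
    stop("ancova_global (cohort_stats): too few complete cases (",
         nrow(dat), ") for the model's ", length(stats::coef(full)),
         " coefficients", call. = FALSE)
  reduced <- stats::lm(y ~ . - group, data = dat)
  cmp <- stats::anova(reduced, full)
  out <- stat_result("F", cmp$F[2], df1 = cmp$Df[2], df2 = df2,
                     p = cmp$`Pr(>F)`[2], alpha = alpha)
  out$n <- nrow(dat)
  out
}

#' Per-group summaries of a continuous or categorical variable
#'
#' @param value vector of values (numeric or categorical).
#' @param group grouping factor.
#' @return data.frame: for numeric input, `group`, `n`, `mean`, `sd` (NAs
#'   excluded and counted in `n_missing`); for categorical input, counts
#'   and within-group percentages per level.
#' @export
group_summary <- function(value, group) {
  group <- factor(group)
  if (is.numeric(value)) {
    do.call(rbind, lapply(levels(group), function(g) {
      v <- value[group == g]
      data.frame(group = g, n = sum(!is.na(v)), n_missing = sum(is.na(v)),
                 mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  } else {
    value <- factor(value)
    do.call(rbind, lapply(levels(group), function(g) {
      v <- value[group == g & !is.na(value)]
      tab <- table(v)
      data.frame(group = g, level = names(tab), n = as.integer(tab),
                 percent = 100 * as.integer(tab) / max(1L, length(v)),
                 stringsAsFactors = FALSE)
    }))
  }
}
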