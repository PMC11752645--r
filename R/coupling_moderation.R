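#' @name coupling-moderation
#' @title Moderation of regional amyloid-tau coupling by TBI status
#' @description
#' In typical Alzheimer's disease, regional amyloid and tau PET signals
#' are positively coupled. These models ask whether a history of (more
#' severe) TBI changes that coupling region by region: for each ROI, tau
#' is regressed on regional amyloid, the two-group TBI factor, their
#' interaction, and covariates (age, APOE e4 carriage, global tau, and
#' the amyloid-to-tau scan lag). The interaction t-value is the map
#' statistic; the reference level is always the less severe group of the
#' pair, so positive t means stronger amyloid-tau coupling under (more
#' severe) TBI.
NULL

# OLS fit returning coefficient table pieces for one column of interest
.ols_t <- function(X, y, col) {
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    stop("roiwise_interaction: rank-deficient design; collinear columns: ",
         paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "),
         call. = FALSE)
  df <- length(y) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  j <- match(col, colnames(X))
  se <- sqrt(sigma2 * XtX_inv[j, j])
  c(coef = unname(fit$coefficients[j]), se = se, df = df)
}

#' ROI-wise amyloid-by-TBI interaction map on tau
#'
#' Fits, per ROI, `tau_r ~ abeta_r * group + age + apoe + global_tau +
#' abtau_lag` on the two-group subset (complete cases), with the less
#' severe group as reference. Reports the interaction coefficient (the
#' coupling-slope difference, more severe minus less severe), its t-value,
#' and BH-adjusted q-values across the map's ROIs.
#'
#' @param subjects subject covariate data.frame.
#' @param abeta,tau [roi_suvr_table()]s.
#' @param pair two group labels.
#' @param q_level FDR level (default 0.05).
#' @param adjust_global_tau include the global tau covariate (default
#'   TRUE; the interaction estimate is unaffected when injected effects
#'   are purely regional).
#' @param reference which group of the pair is dummy-coded 0; defaults to
#'   the less severe group, which fixes the sign convention (positive t =
#'   stronger coupling under more severe TBI). Overriding the reference
#'   flips the sign of every coefficient and t-value exactly.
#' @return data.frame of class `moderation_map` with columns `roi_id`,
#'   `coef`, `t`, `df`, `p`, `q`, `significant`; attributes `pair`,
#'   `reference`, `n`.
#' @export
roiwise_interaction <- function(subjects, abeta, tau, pair, q_level = 0.05,
                                adjust_global_tau = TRUE, reference = NULL) {
  pair <- .order_pair(pair)
  if (!is.null(reference)) {
    if (!reference %in% pair)
      stop("roiwise_interaction: 'reference' must be one of the pair",
           call. = FALSE)
    pair <- c(reference, setdiff(pair, reference))
  }
  sub <- subjects[subjects$group %in% pair, , drop = FALSE]
  ids <- sub$subject_id
  covs <- data.frame(group = as.integer(factor(sub$group, levels = pair)) - 1L,
                     age = sub$age, apoe = sub$apoe,
                     global_tau = tau$global_suvr[ids],
                     abtau_lag = sub$abtau_lag)
  cc <- stats::complete.cases(covs)
  covs <- covs[cc, , drop = FALSE]
  A <- abeta$suvr[ids, , drop = FALSE][cc, , drop = FALSE]
  Tm <- tau$suvr[ids, , drop = FALSE][cc, , drop = FALSE]
  n <- nrow(covs)
  nr <- ncol(Tm)
  # 1, abeta_r, group, abeta_r:group, age, apoe, [global_tau], abtau_lag
  p_coef <- 7L + adjust_global_tau
  if (n - p_coef < 1)
    stop(sprintf("roiwise_interaction: too few complete cases (n=%d) for pair %s-%s",
                 n, pair[1], pair[2]), call. = FALSE)

  res <- matrix(NA_real_, nr, 3,
                dimnames = list(NULL, c("coef", "se", "df")))
  for (r in seq_len(nr)) {
    X <- cbind(intercept = 1, abeta_r = A[, r], group = covs$group,
               `abeta_r:group` = A[, r] * covs$group,
               age = covs$age, apoe = covs$apoe)
    if (adjust_global_tau) X <- cbind(X, global_tau = covs$global_tau)
    X <- cbind(X, abtau_lag = covs$abtau_lag)
    res[r, ] <- .ols_t(X, Tm[, r], "abeta_r:group")
  }
  tval <- res[, "coef"] / res[, "se"]
  pval <- 2 * stats::pt(abs(tval), res[, "df"], lower.tail = FALSE)
  adj <- fdr_bh(pval, q_level)
  out <- data.frame(roi_id = seq_len(nr), coef = res[, "coef"], t = tval,
                    df = res[, "df"], p = pval, q = adj$q,
                    significant = adj$reject, row.names = NULL)
  attr(out, "pair") <- pair
  attr(out, "reference") <- pair[1]
  attr(out, "n") <- n
  class(out) <- c("moderation_map", "data.frame")
  out
}

#' Summarize significant moderation ROIs by lobe and sign
#'
#' @param map a `moderation_map` from [roiwise_interaction()].
#' @param parc a [parcellation()] supplying the lobe annotation.
#' @return data.frame with one row per (lobe, sign) cell among significant
#'   ROIs: `lobe`, `sign` ("positive"/"negative"), `n`, `mean_t`. Zero
#'   rows when nothing is significant.
#' @export
summarize_significant <- function(map, parc) {
  stopifnot(inherits(parc, "parcellation"))
  sig <- map[map$significant, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(lobe = character(0), sign = character(0),
                      n = integer(0), mean_t = numeric(0)))
  lobe <- parc$lobe[match(sig$roi_id, parc$roi_id)]
  sgn <- ifelse(sig$t > 0, "positive", "negative")
  agg <- stats::aggregate(sig$t, by = list(lobe = lobe, sign = sgn),
                          FUN = function(v) c(n = length(v), mean_t = mean(v)))
  data.frame(lobe = agg$lobe, sign = agg$sign,
             n = as.integer(agg$x[, "n"]), mean_t = agg$x[, "mean_t"],
             stringsAsFactors = FALSE)
}
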