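# Table-style summaries of the amyloid-tau scan lag across the three groups
lag_summaries <- data.frame(mean = c(2.34, 0.94, 0.76),
                            sd = c(1.38, 1.42, 1.21),
                            n = c(38, 40, 25),
                            row.names = c("no", "mild", "modsev"))

test_that("one-way ANOVA from printed summaries reproduces the scan-lag group effect", {
  res <- anova_oneway(lag_summaries)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 100)
  expect_lt(abs(res$value - 14.18), 0.05)
  expect_lt(res$p, 0.001)
})

test_that("ANOVA handles degenerate inputs: identical groups, zero variance", {
  x <- rnorm(10)
  res <- anova_oneway(list(x, x, x))
  expect_equal(res$value, 0)
  expect_equal(res$p, 1)
  res_inf <- anova_oneway(list(rep(1, 5), rep(2, 5)))
  expect_identical(res_inf$value, Inf)
  expect_equal(res_inf$p, 0)
  expect_error(anova_oneway(list(rnorm(5), 1.2)), "n >= 2")
})

test_that("summary-form ANOVA equals the raw-data form and independent oracles", {
  set.seed(101)
  for (i in 1:5) {
    groups <- lapply(sample(3:15, 3, replace = TRUE), rnorm)
    raw <- anova_oneway(groups)
    summ <- anova_oneway(data.frame(mean = sapply(groups, mean),
                                    sd = sapply(groups, sd),
                                    n = lengths(groups)))
    expect_equal(raw$value, summ$value, tolerance = 1e-10)
    # brute-force sums of squares
    all_v <- unlist(groups)
    ssb <- sum(lengths(groups) * (sapply(groups, mean) - mean(all_v))^2)
    ssw <- sum(sapply(groups, function(v) sum((v - mean(v))^2)))
    f_oracle <- (ssb / 2) / (ssw / (length(all_v) - 3))
    expect_equal(raw$value, f_oracle, tolerance = 1e-10)
    # fitted-model oracle
    g <- factor(rep(seq_along(groups), lengths(groups)))
    expect_equal(raw$value, anova(lm(all_v ~ g))$`F value`[1],
                 tolerance = 1e-10)
  }
})

test_that("Tukey HSD from summaries reproduces the printed pairwise lag contrasts", {
  mild <- tukey_hsd(lag_summaries, c("mild", "no"))
  expect_lt(abs(mild$estimate - (-1.40)), 0.02)
  expect_lt(abs(mild$ci_low - (-2.13)), 0.02)
  expect_lt(abs(mild$ci_high - (-0.67)), 0.02)
  modsev <- tukey_hsd(lag_summaries, c("modsev", "no"))
  expect_lt(abs(modsev$estimate - (-1.58)), 0.02)
  expect_lt(abs(modsev$ci_low - (-2.41)), 0.02)
  expect_lt(abs(modsev$ci_high - (-0.75)), 0.02)
})

test_that("Tukey HSD agrees with the fitted-model implementation and is symmetric for identical groups", {
  set.seed(7)
  groups <- list(A = rnorm(9, 1), B = rnorm(12, 1.4), C = rnorm(7, 0.8))
  mine <- tukey_hsd(groups, c("B", "A"))
  fit <- TukeyHSD(aov(y ~ g, data = data.frame(
    y = unlist(groups), g = factor(rep(names(groups), lengths(groups))))))
  expect_equal(mine$estimate, fit$g["B-A", "diff"], tolerance = 1e-8)
  expect_equal(mine$ci_low, fit$g["B-A", "lwr"], tolerance = 1e-8)
  expect_equal(mine$ci_high, fit$g["B-A", "upr"], tolerance = 1e-8)
  expect_equal(mine$p, fit$g["B-A", "p adj"], tolerance = 1e-8)

  twin <- list(A = groups$A, B = groups$A, C = groups$C)
  res <- tukey_hsd(twin, c("B", "A"))
  expect_equal(res$estimate, 0)
  expect_equal(res$ci_low, -res$ci_high)
})

test_that("studentized-range critical value matches a Monte-Carlo quantile oracle", {
  k <- 3; df <- 12; n_draws <- 5e5
  set.seed(31)
  z <- matrix(rnorm(k * n_draws), n_draws, k)
  q_draws <- (apply(z, 1, max) - apply(z, 1, min)) /
    sqrt(rchisq(n_draws, df) / df)
  expect_lt(abs(quantile(q_draws, 0.95) - qtukey(0.95, k, df)), 0.1)
})

test_that("Fisher exact reproduces the MCI enrichment odds ratio and CI", {
  tab <- matrix(c(10, 4, 15, 34), 2, 2)
  res <- fisher_exact_2x2(tab)
  expect_lt(abs(res$estimate - 5.50), 0.02)
  expect_lt(abs(res$ci_low - 1.32), 0.02)
  expect_lt(abs(res$ci_high - 27.99), 0.02)
  expect_lt(abs(res$p - 0.01), 0.005)
  # the sample cross-product ratio is deliberately distinct (5.67, surfaced)
  expect_lt(abs(res$value - 10 * 34 / (15 * 4)), 1e-12)
})

test_that("conditional-MLE odds ratio matches a brute-force likelihood grid search", {
  cond_mle_grid <- function(tab) {
    m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - m2):min(k, m1)
    loglik <- function(psi)
      lchoose(m1, tab[1, 1]) + lchoose(m2, k - tab[1, 1]) +
      tab[1, 1] * log(psi) -
      log(sum(exp(lchoose(m1, support) + lchoose(m2, k - support) +
                    support * log(psi))))
    grid <- exp(seq(log(1e-3), log(50), length.out = 40000))
    grid[which.max(vapply(grid, loglik, 0))]
  }
  tabs <- list(matrix(c(2, 1, 1, 2), 2, 2),
               matrix(c(10, 4, 15, 34), 2, 2),
               matrix(c(5, 9, 3, 8), 2, 2))
  for (tab in tabs) {
    expect_equal(fisher_exact_2x2(tab)$estimate, cond_mle_grid(tab),
                 tolerance = 5e-3)
  }
  # symmetric table: odds ratio 1
  expect_equal(fisher_exact_2x2(matrix(c(4, 4, 9, 9), 2, 2))$estimate, 1,
               tolerance = 1e-6)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2, 2)), "margin")
})

test_that("chi-square is zero for proportional rows and warns on tiny expected counts", {
  res <- chi_square_independence(matrix(c(10, 20, 20, 40), 2, 2))
  expect_equal(res$value, 0)
  expect_equal(res$df1, 1)
  expect_warning(chi_square_independence(matrix(c(1, 0, 0, 40), 2, 2)),
                 "expected cell")
})

test_that("two-sample t reproduces the TBI-to-scan lag comparison and the textbook formula", {
  res <- two_sample_t(list(mean = 42.02, sd = 18.04, n = 40),
                      list(mean = 35.80, sd = 18.65, n = 25))
  expect_lt(abs(res$p - 0.19), 0.02)
  expect_equal(res$df1, 63)
  set.seed(15)
  x <- rnorm(14, 1); y <- rnorm(9, 0.5)
  mine <- two_sample_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$value, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref$conf.int),
               tolerance = 1e-10)
  welch <- two_sample_t(x, y, var_equal = FALSE)
  ref_w <- t.test(x, y)
  expect_equal(welch$value, unname(ref_w$statistic), tolerance = 1e-10)
  expect_equal(welch$df1, unname(ref_w$parameter), tolerance = 1e-10)
})

test_that("global ANCOVAs carry the expected complete-case counts and residual df", {
  co <- default_cohort()
  ab <- ancova_global(co$subjects, co$abeta, co$tau, "amyloid")
  expect_equal(ab$n, 98)
  expect_equal(ab$df1, 2)
  expect_equal(ab$df2, 91)
  ta <- ancova_global(co$subjects, co$abeta, co$tau, "tau")
  expect_equal(ta$n, 98)
  expect_equal(ta$df2, 89)
})

test_that("global ANCOVA keeps its nominal type-I error under a simulated null", {
  set.seed(55)
  n <- 24
  subjects <- data.frame(
    subject_id = sprintf("S%03d", 1:n),
    group = factor(rep(c("no", "mild", "modsev"), each = n / 3),
                   levels = c("no", "mild", "modsev")),
    age = rnorm(n, 72, 5), apoe = rbinom(n, 1, 0.25),
    diagnosis = sample(c("CN", "MCI"), n, replace = TRUE),
    diag_lag = rnorm(n, 0.8, 0.5), abtau_lag = rnorm(n, 1.4, 1),
    stringsAsFactors = FALSE
  )
  ab <- roi_suvr_table(matrix(runif(n * 2, 1, 1.3), n,
                              dimnames = list(subjects$subject_id, 1:2)),
                       "amyloid")
  reps <- 1e4
  hits <- 0L
  for (i in seq_len(reps)) {
    ab$global_suvr[] <- rnorm(n, 1.12, 0.15)  # outcome independent of group
    hits <- hits + (ancova_global(subjects, ab, ab, "amyloid")$p < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.01)
})

test_that("ANOVA p-values are uniform under the null (Kolmogorov-Smirnov)", {
  set.seed(99)
  p <- replicate(1e4, anova_oneway(list(rnorm(8), rnorm(8), rnorm(8)))$p)
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("rank-deficient global ANCOVA names the collinear column", {
  co <- default_cohort()
  subj <- co$subjects
  subj$diag_lag <- subj$age  # force exact collinearity
  expect_error(ancova_global(subj, co$abeta, co$tau, "amyloid"),
               "collinear.*diag_lag|diag_lag.*collinear")
})
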