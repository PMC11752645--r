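test_that("noise-free degenerate config yields constant baseline SUVRs", {
  cfg <- sim_config(seed = 1, group_sizes = c(3, 3, 3), n_rois = 20,
                    subject_global_sd = 0, roi_noise_sd = 0,
                    regional_offset_template = zero_offsets(20),
                    coupling_slope_template = flat_slopes(20, 0),
                    missing_apoe_count = 0)
  co <- generate_cohort(cfg)
  expect_true(all(co$abeta$suvr == 1.12))
  expect_true(all(co$tau$suvr == 1.08))
  expect_equal(unname(co$abeta$global_suvr), rep(1.12, 9))
})

test_that("same seed regenerates the cohort bit-identically, different seed does not", {
  a <- generate_cohort(sim_config(seed = 11))
  b <- generate_cohort(sim_config(seed = 11))
  c <- generate_cohort(sim_config(seed = 12))
  expect_identical(a$abeta$suvr, b$abeta$suvr)
  expect_identical(a$tau$suvr, b$tau$suvr)
  expect_identical(a$subjects, b$subjects)
  expect_false(identical(a$tau$suvr, c$tau$suvr))
  # determinism survives serialization byte-for-byte
  f1 <- tempfile(); f2 <- tempfile()
  write_suvr_table(a$tau, f1)
  write_suvr_table(b$tau, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("injected tau offset is recovered by the group-mean oracle", {
  off <- zero_offsets(200)
  frontal <- 1:30
  off$tau[frontal, "modsev"] <- 0.10
  cfg <- sim_config(seed = 8, regional_offset_template = off,
                    coupling_slope_template = flat_slopes(200, 0))
  co <- generate_cohort(cfg)
  g <- co$subjects$group
  diff <- mean(co$tau$suvr[g == "modsev", frontal]) -
    mean(co$tau$suvr[g == "no", frontal])
  # Monte-Carlo SE of the oracle from the generating variances
  ns <- cfg$group_sizes[c("no", "modsev")]
  se <- sqrt((cfg$subject_global_sd[["tau"]]^2 +
                cfg$roi_noise_sd^2 / length(frontal)) * sum(1 / ns))
  expect_lt(abs(diff - 0.10), 3 * se)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(group_sizes = c(1, 5, 5)), "group_sizes")
  expect_error(sim_config(n_rois = 10), "n_rois")
  expect_error(sim_config(roi_noise_sd = -0.1), "roi_noise_sd")
  expect_error(sim_config(coupling_slope_template = matrix(0, 5, 3)),
               "coupling_slope_template")
  expect_error(sim_config(regional_offset_template =
                            list(abeta = matrix(0, 200, 3))),
               "regional_offset_template")
  expect_error(sim_config(missing_apoe_count = c(50, 0, 0)),
               "missing_apoe_count")
})

test_that("noise-free cohort is exactly reconstructible from truth", {
  cfg <- sim_config(seed = 3, group_sizes = c(4, 4, 4), n_rois = 40,
                    roi_noise_sd = 0, missing_apoe_count = 0)
  co <- generate_cohort(cfg)
  gi <- as.integer(co$subjects$group)
  off_t <- cfg$regional_offset_template$tau
  sl <- cfg$coupling_slope_template
  abeta_dev <- co$abeta$suvr - cfg$baseline_abeta_mean
  expected <- cfg$baseline_tau_mean + co$truth$latent$g_tau +
    t(off_t)[gi, ] + t(sl)[gi, ] * abeta_dev
  expect_equal(unname(co$tau$suvr), unname(expected), tolerance = 1e-12)
  abeta_expected <- cfg$baseline_abeta_mean + co$truth$latent$g_abeta +
    t(cfg$regional_offset_template$abeta)[gi, ]
  expect_equal(unname(co$abeta$suvr), unname(abeta_expected),
               tolerance = 1e-12)
})

test_that("TBI records respect group membership and round-trip through the classifier", {
  cfg <- sim_config(seed = 21)
  co <- generate_cohort(cfg)
  rec <- generate_tbi_records(co$subjects, cfg)
  g <- as.character(co$subjects$group)
  expect_true(all(vapply(rec[g == "no"], nrow, 0L) == 0L))
  # moderate/severe subjects carry at least one qualifying event
  worst <- vapply(rec[g == "modsev"], function(e)
    any(classify_event_severity(e) == "moderate_severe"), TRUE)
  expect_true(all(worst))
  # mild subjects carry only mild events
  mild_ok <- vapply(rec[g == "mild"], function(e)
    all(classify_event_severity(e) == "mild"), TRUE)
  expect_true(all(mild_ok))
  status <- classify_cohort_tbi(rec, stats::setNames(
    co$subjects$tau_pet_date, co$subjects$subject_id))
  recovered <- c(none = "no", mild = "mild", moderate_severe = "modsev")[status$severity]
  expect_identical(unname(recovered), g)
})

test_that("voxel phantom forces exact SUVRs in the noise-free case", {
  p <- parcellation(20, label_codes = seq(5, 100, by = 5))
  ph <- generate_voxel_phantom(p, roi_means = rep(2.0, 20), ref_mean = 2.0,
                               noise_sd = 0, seed = 1, dim = c(24, 24, 24))
  s <- extract_roi_suvr(ph$uptake, ph$labels, ph$gm_mask, p, ph$ref_label)
  expect_equal(unname(s), rep(1, 20))
  means <- rep(2.0, 20); means[7] <- 2.8
  ph2 <- generate_voxel_phantom(p, means, ref_mean = 2.0, noise_sd = 0,
                                seed = 1, dim = c(24, 24, 24))
  s2 <- extract_roi_suvr(ph2$uptake, ph2$labels, ph2$gm_mask, p, ph2$ref_label)
  expect_equal(unname(s2[7]), 1.4, tolerance = 1e-12)
  expect_error(generate_voxel_phantom(p, means, 2, ref_label = 5),
               "collides")
})

test_that("noisy phantom SUVRs match nominal within the standard-error bound", {
  p <- parcellation(20)
  means <- seq(1.5, 3.4, by = 0.1)
  ph <- generate_voxel_phantom(p, means, ref_mean = 2.0, noise_sd = 0.05,
                               seed = 4, dim = c(24, 24, 24))
  s <- extract_roi_suvr(ph$uptake, ph$labels, ph$gm_mask, p, ph$ref_label)
  # delta-method SE of a ratio of two noisy means (ROI and reference)
  n_ref <- sum(ph$labels == ph$ref_label)
  se <- sqrt((0.05 / sqrt(ph$voxel_counts) / 2.0)^2 +
               (means * 0.05 / sqrt(n_ref) / 2.0^2)^2)
  expect_true(all(abs(s - means / 2.0) < 3 * se))
})
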