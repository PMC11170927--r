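test_that("each QC rule masks exactly the spots the oracle enumerates", {
  gc <- toy_geochip(probes = 4, samples = 8)
  # one violation per rule, in different probes/samples
  gc$cv[gc$probe == "p01" & gc$sample_id == "s01"] <- 0.9   # CV rule
  gc$snr[gc$probe == "p02" & gc$sample_id == "s06"] <- 3    # SNR (batch 2)
  gc$signal[gc$probe == "p03" & gc$sample_id == "s02"] <- 50 # intensity
  # probe p04 undetected in >50% of one treatment-month group: mask 2 of 2
  idx <- gc$probe == "p04" & gc$treatment == "warmed" & gc$month == 1
  gc$signal[idx] <- 10
  orc <- oracle_qc(gc)
  out <- qc_filter(gc)
  expect_equal(is.na(out$signal), orc$masked | orc$dropped)
  rep <- attr(out, "removal_report")
  expect_equal(rep$spots_removed[rep$rule == "cv"], 1)
  expect_equal(rep$spots_removed[rep$rule == "snr"], 1)
  expect_equal(rep$spots_removed[rep$rule == "intensity"], 3)
})

test_that("a fully passing table is untouched and filtering is idempotent", {
  gc <- toy_geochip(probes = 3, samples = 8)
  once <- qc_filter(gc)
  expect_equal(once$signal, gc$signal)
  gc$cv[1] <- 0.95
  f1 <- qc_filter(gc)
  f2 <- qc_filter(f1)
  expect_equal(f1$signal, f2$signal)
})

test_that("SNR thresholds are batch-specific", {
  gc <- toy_geochip(probes = 1, samples = 8, snr = 5)
  out <- qc_filter(gc)
  expect_true(all(is.na(out$signal[out$batch == 1])))  # 5 < 7
  expect_true(all(!is.na(out$signal[out$batch == 2]))) # 5 >= 3.5
  gc$batch <- 9L
  expect_error(qc_filter(gc), "unknown batch")
})

test_that("normalization equalizes standard means and logs last", {
  d <- study_design(seed = 17)
  ann <- default_gene_annotations(n_probes = 20, n_standard = 10)
  gc <- gen_probe_signals(d, annotations = ann, noise_sd = 0.2)
  # arrays already equal in standard means: all step-1 factors 1
  gc0 <- gen_probe_signals(d, annotations = ann, noise_sd = 0,
                           batch_scale = 1)
  n0 <- normalize_geochip(gc0)
  sf0 <- attr(n0, "scale_factors")
  expect_equal(sf0$standard_scale, rep(1, nrow(sf0)), tolerance = 1e-12)
  # double one array: closed-form factor = grand mean / (2 x its mean),
  # and standard means line up again after step one
  std <- ann$probe[ann$is_standard]
  gc2 <- gc
  one <- gc2$sample_id == gc2$sample_id[1]
  gc2$signal[one] <- 2 * gc2$signal[one]
  n2 <- normalize_geochip(gc2)
  sf2 <- attr(n2, "scale_factors")
  std_means <- tapply(gc2$signal[gc2$probe %in% std],
                      gc2$sample_id[gc2$probe %in% std], mean)
  expect_equal(sf2$standard_scale[sf2$sample_id == gc2$sample_id[1]],
               as.numeric(mean(std_means) / std_means[gc2$sample_id[1]]),
               tolerance = 1e-12)
  base <- attr(normalize_geochip(gc), "scale_factors")
  expect_equal(sf2$standard_scale[sf2$sample_id == gc2$sample_id[1]] /
                 base$standard_scale[base$sample_id == gc2$sample_id[1]],
               0.5, tolerance = 0.02)
  sm <- tapply(exp(n2$log_signal[n2$probe %in% std]),
               n2$sample_id[n2$probe %in% std], mean)
  expect_lt(diff(range(sm)) / mean(sm), 1e-10)
  # the transform is a natural log of the rescaled signals
  f <- qc_filter(gc)
  n <- normalize_geochip(f)
  sf <- attr(n, "scale_factors")
  i <- which(!is.na(f$signal) & !f$probe %in% std)[1]
  expected <- log(f$signal[i] *
                    sf$standard_scale[sf$sample_id == f$sample_id[i]] *
                    sf$functional_scale[sf$sample_id == f$sample_id[i]])
  expect_equal(n$log_signal[i], expected, tolerance = 1e-12)
  # an array with no detected standards is an error
  gc3 <- gc
  gc3$signal[gc3$sample_id == gc3$sample_id[1] & gc3$probe %in% std] <- NA
  expect_error(normalize_geochip(gc3), "standard")
})

test_that("response ratios have the lnRR form and antisymmetry", {
  d <- study_design(seed = 23)
  ann <- default_gene_annotations(n_probes = 10)
  # identical groups: rr exactly 0, CI spans 0
  gc <- gen_probe_signals(d, annotations = ann, noise_sd = 0,
                          batch_scale = 1)
  raw <- gc
  raw$log_signal <- log(raw$signal)
  raw$signal <- NULL
  class(raw) <- c("geochip_normalized", class(raw)[-1])
  attr(raw, "annotations") <- ann
  rr0 <- response_ratio(raw, scope = "year")
  expect_equal(rr0$rr, rep(0, nrow(rr0)), tolerance = 1e-12)
  expect_true(all(rr0$ci_low <= 0 & rr0$ci_high >= 0))
  expect_true(all(rr0$ci_low <= rr0$rr & rr0$rr <= rr0$ci_high))
  # mean 4 vs 2 with zero variance: ln 2 with zero-width CI
  eff <- rr_effect_table(ann$probe[!ann$is_standard], 1:12, log(2))
  gc2 <- gen_probe_signals(d, annotations = ann, noise_sd = 0,
                           batch_scale = 1, true_rr_effects = eff)
  raw2 <- gc2
  raw2$log_signal <- log(raw2$signal)
  raw2$signal <- NULL
  class(raw2) <- c("geochip_normalized", class(raw2)[-1])
  attr(raw2, "annotations") <- ann
  rr2 <- response_ratio(raw2, scope = "year")
  expect_equal(rr2$rr, rep(log(2), nrow(rr2)), tolerance = 1e-12)
  expect_equal(rr2$se, rep(0, nrow(rr2)), tolerance = 1e-12)
  # swapping treatment labels negates rr and mirrors the CI
  raw3 <- raw2
  raw3$treatment <- ifelse(raw3$treatment == "warmed", "control", "warmed")
  rr3 <- response_ratio(raw3, scope = "year")
  expect_equal(rr3$rr, -rr2$rr, tolerance = 1e-12)
  expect_equal(rr3$ci_low, -rr2$ci_high, tolerance = 1e-12)
})

test_that("sub-category ratios aggregate per-sample sums before the ratio", {
  d <- study_design(seed = 29)
  ann <- default_gene_annotations(n_probes = 12)
  eff <- rr_effect_table(ann$probe[ann$gene == "amyA"], 1:12, log(3))
  gc <- gen_probe_signals(d, annotations = ann, noise_sd = 0,
                          batch_scale = 1, true_rr_effects = eff)
  raw <- gc
  raw$log_signal <- log(raw$signal)
  raw$signal <- NULL
  class(raw) <- c("geochip_normalized", class(raw)[-1])
  attr(raw, "annotations") <- ann
  rr <- response_ratio(raw, scope = "year", level = "subcategory")
  cdec <- rr[rr$unit == "C_decomposition", ]
  # hand value: summed warmed signal / summed control signal, logged
  w <- tapply(exp(raw$log_signal[raw$treatment == "warmed" &
                                   !grepl("std", raw$probe)]),
              raw$sample_id[raw$treatment == "warmed" &
                              !grepl("std", raw$probe)], sum)
  expect_gt(cdec$rr, 0)
  expect_lt(cdec$rr, log(3))  # diluted by unaffected probes in the bucket
  expect_false("standard" %in% rr$unit)
})

test_that("probes are classified into the four response categories", {
  d <- study_design(seed = 41)
  ann <- default_gene_annotations(n_probes = 40)
  cdec <- ann$probe[ann$subcategory == "C_decomposition"]
  eff <- rr_effect_table(cdec[1:16], 1:12, log(2.5))
  gc <- gen_probe_signals(d, annotations = ann, noise_sd = 0.15,
                          true_rr_effects = eff)
  f <- qc_filter(gc)
  # force detection asymmetries for the unique categories
  f$signal[f$probe == cdec[20] & f$treatment == "control"] <- NA
  f$signal[f$probe == cdec[21] & f$treatment == "warmed"] <- NA
  rr <- response_ratio(normalize_geochip(f), scope = "year")
  det <- detection_table(f, scope = "year")
  cls <- classify_probes(rr, det)
  expect_equal(cls$category[cls$probe == cdec[20]], "unique_warming")
  expect_equal(cls$category[cls$probe == cdec[21]], "unique_control")
  hit <- cls$category[cls$probe %in% cdec[1:16]]
  expect_gte(mean(hit == "increased"), 0.8)
  expect_true(all(table(cls$probe, cls$category) <= 1))
  pct <- attr(cls, "percentages")
  expect_equal(sum(pct$percent), 100, tolerance = 1e-9)
})

test_that("explicit increased/decreased definitions hold on records", {
  rec <- tibble::tibble(
    unit = c("a", "b", "c"), scope = "year",
    rr = c(0.5, -0.4, 0.1), se = c(0.1, 0.1, 0.2),
    ci_low = c(0.2, -0.6, -0.3), ci_high = c(0.8, -0.2, 0.5),
    n_w = 4, n_c = 4,
    significant = c(TRUE, TRUE, FALSE), degenerate = FALSE)
  det <- tibble::tibble(probe = c("a", "b", "c"), scope = "year",
                        detected_warmed = TRUE, detected_control = TRUE)
  cls <- classify_probes(rec, det)
  expect_equal(cls$category, c("increased", "decreased", "unchanged"))
})
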