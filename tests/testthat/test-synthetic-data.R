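test_that("study design yields a perfect warmed/control pairing", {
  d <- study_design(seed = 11)
  expect_equal(nrow(d$samples), 96)
  pairs <- d$samples |>
    tidyr::pivot_wider(names_from = treatment, values_from = sample_id)
  expect_equal(nrow(pairs), 48)
  expect_false(anyNA(pairs$warmed))
  expect_false(anyNA(pairs$control))
  expect_error(study_design(), "seed")
})

test_that("forcing generator is seed-reproducible and respects bounds", {
  d <- study_design(seed = 3)
  f1 <- gen_forcing(d)
  f2 <- gen_forcing(d)
  expect_identical(f1, f2)
  expect_true(all(f1$moisture >= 0 & f1$moisture <= 100))
  expect_true(all(f1$gpp >= 0))
  wide <- tidyr::pivot_wider(f1[c("date", "treatment", "temperature")],
                             names_from = treatment,
                             values_from = temperature)
  expect_true(all(wide$warmed - wide$control >= 0))
})

test_that("zero warming offsets give identical warmed and control series", {
  d <- study_design(seed = 5)
  f <- gen_forcing(d,
                   warming_offsets = c(early_cool = 0, warm = 0,
                                       late_cool = 0),
                   moisture_params = list(
                     base = c(early_cool = 10.7, warm = 13, late_cool = 7.5),
                     warming_factor = c(early_cool = 1, warm = 1,
                                        late_cool = 1),
                     noise_sd = 1.2, noise_rho = 0.6))
  w <- f[f$treatment == "warmed", c("temperature", "moisture", "gpp")]
  c0 <- f[f$treatment == "control", c("temperature", "moisture", "gpp")]
  expect_equal(w, c0)
})

test_that("default climate preset spans ~3.5 to ~28.1 degC monthly means", {
  d <- study_design(seed = 8)
  m <- monthly_forcing(gen_forcing(d))
  ctl <- m$temperature[m$treatment == "control"]
  expect_equal(min(ctl), 3.5, tolerance = 0.25)
  expect_equal(max(ctl), 28.1, tolerance = 0.025)
  expect_equal(which.min(ctl), 1)  # January coldest
  expect_equal(which.max(ctl), 7)  # July warmest
})

test_that("annual warming equals the season-length-weighted offset mean", {
  d <- study_design(seed = 2)
  off <- c(early_cool = 3.6, warm = 4.5, late_cool = 4.1)
  f <- gen_forcing(d, warming_offsets = off)
  wide <- tidyr::pivot_wider(f[c("date", "month", "treatment", "temperature")],
                             names_from = treatment,
                             values_from = temperature)
  season_days <- table(season_of(wide$month))
  expected <- sum(off[names(season_days)] * as.numeric(season_days)) /
    sum(season_days)
  expect_equal(mean(wide$warmed - wide$control), expected, tolerance = 1e-12)
})

test_that("forcing rejects bad configurations", {
  d <- study_design(seed = 1)
  expect_error(gen_forcing(d, climate = list(mean = 15, amplitude = -1,
                                             peak_day = 197, noise_sd = 1,
                                             noise_rho = 0.5)),
               "amplitude")
  expect_error(gen_forcing(d, warming_offsets = c(warm = 4.5)),
               "every season")
})

test_that("community generator implants the configured trait effect", {
  d <- study_design(seed = 21)
  com <- gen_community(d, n_asvs = 80,
                       warming_trait_effect = c(early_cool = 0.4, warm = 0,
                                                late_cool = 0.4))
  # exact at the level of true underlying proportions
  truth <- com$truth |>
    tidyr::pivot_wider(id_cols = c(block, month),
                       names_from = treatment, values_from = true_rrn) |>
    dplyr::mutate(season = season_of(month),
                  lr = log(warmed / control))
  expect_equal(truth$lr[truth$season != "warm"],
               rep(0.4, sum(truth$season != "warm")), tolerance = 1e-8)
  expect_equal(truth$lr[truth$season == "warm"],
               rep(0, sum(truth$season == "warm")), tolerance = 1e-12)
  # counts are a rarefied table
  counts <- as.matrix(com$counts[-1])
  expect_true(all(counts >= 0 & counts == round(counts)))
  expect_true(all(colSums(counts) == 21567))
})

test_that("null community effect gives equal true trait values in pairs", {
  d <- study_design(seed = 31)
  com <- gen_community(d, n_asvs = 40,
                       warming_trait_effect = c(early_cool = 0, warm = 0,
                                                late_cool = 0))
  wide <- com$truth |>
    tidyr::pivot_wider(id_cols = c(block, month), names_from = treatment,
                       values_from = true_rrn)
  expect_equal(wide$warmed, wide$control, tolerance = 1e-12)
})

test_that("degenerate single-value rrn distribution is flagged and forces Eq.1", {
  d <- study_design(seed = 7)
  expect_warning(
    com <- gen_community(d, n_asvs = 20,
                         warming_trait_effect = c(early_cool = 0, warm = 0,
                                                  late_cool = 0),
                         rrn_distribution = list(meanlog = log(3),
                                                 sdlog = 0, max = 15)),
    "degenerate")
  asn <- assign_rrn(com$taxonomy, com$lookup)
  vals <- purrr::map_dbl(
    setdiff(names(com$counts), "asv_id"),
    \(s) community_rrn(com$counts[[s]], asn$copy_number))
  expect_equal(vals, rep(3, length(vals)), tolerance = 1e-12)
})

test_that("tilt_to_effect hits the requested log-effect exactly", {
  set.seed(99)
  for (i in 1:200) {
    n <- stats::runif(12, 1, 10)
    p <- stats::rgamma(12, 1)
    p <- p / sum(p)
    delta <- stats::runif(1, -0.4, 0.4)
    q <- tilt_to_effect(p, n, delta)
    crrn <- function(x) 1 / sum(x / n)
    expect_equal(log(crrn(q)) - log(crrn(p)), delta, tolerance = 1e-8)
  }
  expect_error(tilt_to_effect(c(.5, .5), c(2, 2), 0.5), "exceeds")
})

test_that("paired log-ratios recover the configured effect through counts", {
  d <- study_design(seed = 55)
  com <- gen_community(d, n_asvs = 60,
                       warming_trait_effect = c(early_cool = 0.5, warm = 0,
                                                late_cool = 0.5))
  asn <- assign_rrn(com$taxonomy, com$lookup)
  traits <- trait_summaries(com$counts, asn, d)
  lr <- paired_trait_ratios(traits)
  cool <- lr$log_ratio[lr$season != "warm"]
  expect_equal(mean(cool), 0.5, tolerance = 0.05)
})

test_that("rh observation generator honours its noise contract", {
  d <- study_design(seed = 4)
  f <- gen_forcing(d)
  fc <- f[f$treatment == "control", ]
  p <- mend_params()
  noiseless <- gen_rh_observations(p, fc, noise_sd = 0, seed = 1)
  expect_equal(noiseless$r_h, noiseless$r_h_true, tolerance = 1e-12)
  expect_equal(noiseless$r_a, noiseless$r_s - noiseless$r_h,
               tolerance = 1e-12)
  o1 <- gen_rh_observations(p, fc, noise_sd = 0.1, seed = 1)
  o2 <- gen_rh_observations(p, fc, noise_sd = 0.1, seed = 2)
  expect_identical(o1, gen_rh_observations(p, fc, noise_sd = 0.1, seed = 1))
  expect_false(identical(o1$r_h, o2$r_h))
  expect_equal(o1$r_h_true, o2$r_h_true)
  # uptake capacity up, all else equal: generated Rh does not decrease
  p2 <- p
  p2["V_g"] <- 2 * p["V_g"]
  hi <- gen_rh_observations(p2, fc, noise_sd = 0, seed = 1)
  expect_gte(mean(hi$r_h), mean(noiseless$r_h))
  expect_error(gen_rh_observations(p, fc, noise_sd = -1, seed = 1),
               "noise_sd")
})

test_that("probe-signal generator has batch structure and a clean null", {
  d <- study_design(seed = 77)
  ann <- default_gene_annotations(n_probes = 30)
  gc <- gen_probe_signals(d, annotations = ann, noise_sd = 0)
  expect_true(all(gc$batch[gc$month <= 6] == 1))
  expect_true(all(gc$batch[gc$month >= 7] == 2))
  # zero effects + zero noise: warmed equals control everywhere
  wide <- gc |>
    tidyr::pivot_wider(id_cols = c(probe, block, month),
                       names_from = treatment, values_from = signal)
  expect_equal(wide$warmed, wide$control, tolerance = 1e-12)
  expect_error(gen_probe_signals(d, annotations = ann[0, ]), "probe")
  expect_error(gen_probe_signals(d, batch_split = rep(1, 6)), "batch_split")
})
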