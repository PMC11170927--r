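test_that("intrinsic CUE is linear in temperature with clamping flagged", {
  p <- mend_params(Yg_ref = 0.45, k_Yg = -0.01, T_ref = 20)
  expect_equal(as.numeric(cue_at(20, p)), 0.45)
  expect_equal(as.numeric(cue_at(30, p)), 0.35)
  expect_false(attr(cue_at(25, p), "clamped"))
  lo <- cue_at(200, p)
  expect_equal(as.numeric(lo), 0.01)
  expect_true(attr(lo, "clamped"))
})

test_that("parameter and constant constructors validate their domains", {
  expect_error(mend_params(f_INP = 1.2), "\\[0, 1\\]")
  expect_error(mend_params(V_g = -1), ">= 0")
  expect_error(mend_params(Yg_ref = 1), "\\(0, 1\\)")
  expect_error(mend_constants(nope = 1), "unknown constant")
  expect_equal(unname(mend_constants(V_P = 9)["V_P"]), 9)
})

test_that("an empty system has zero fluxes everywhere", {
  st <- mend_initial_pools()
  st[] <- 0
  fl <- mend_fluxes(st, mend_params(), temperature = 15, moisture = 25)
  expect_true(all(fl$fluxes == 0))
  expect_true(all(fl$derivatives == 0))
  expect_equal(fl$rh, 0)
})

test_that("growth respiration carries the (1 - Yg) share of uptake", {
  st <- mend_initial_pools()
  p <- mend_params(Yg_ref = 0.99, k_Yg = 0)
  fl <- mend_fluxes(st, p, temperature = 15, moisture = 25)
  expect_gt(fl$fluxes[["uptake"]], 0)
  expect_equal(fl$fluxes[["growth"]] + fl$fluxes[["growth_resp"]],
               fl$fluxes[["uptake"]], tolerance = 1e-12)
  expect_equal(fl$fluxes[["growth_resp"]], 0.01 * fl$fluxes[["uptake"]],
               tolerance = 1e-12)
  # realized efficiency equals the intrinsic value when only growth
  # respiration drains uptake
  expect_equal(fl$fluxes[["growth"]] / fl$fluxes[["uptake"]],
               as.numeric(cue_at(15, p)), tolerance = 1e-12)
})

test_that("every flux matches an independent hand evaluation", {
  st <- c(P_O = 1.3, P_H = 0.8, M = 11, Q = 0.4, D = 0.21, B_A = 0.33,
          B_D = 0.12, EP_O = 0.021, EP_H = 0.034, EM = 0.011)
  p <- mend_params()
  cs <- mend_constants()
  T <- 22.5
  W <- 17
  G <- 2.4
  fl <- mend_fluxes(st, p, T, W, G)
  # spreadsheet-style recomputation of each stated formula
  fT <- exp((47000 / 8.314) * (1 / 288.15 - 1 / (T + 273.15)))
  fTm <- exp((20000 / 8.314) * (1 / 288.15 - 1 / (T + 273.15)))
  fW <- (W / 25)^0.75
  yg <- 0.43 - 0.004 * (T - 15)
  expect_equal(fl$fluxes[["dec_PO"]],
               2.0 * fT * fW * 0.021 * 1.3 / (50 + 1.3), tolerance = 1e-12)
  expect_equal(fl$fluxes[["dec_M"]],
               0.6 * fT * fW * 0.011 * 11 / (250 + 11), tolerance = 1e-12)
  expect_equal(fl$fluxes[["ads"]], 0.02 * 0.21 * (1 - 0.4 / 1.7),
               tolerance = 1e-12)
  expect_equal(fl$fluxes[["des"]], 0.002 * 0.4, tolerance = 1e-12)
  expect_equal(fl$fluxes[["uptake"]],
               0.2 * fT * fW * 0.33 * 0.21 / (0.25 + 0.21),
               tolerance = 1e-12)
  expect_equal(fl$fluxes[["growth_resp"]],
               (1 - yg) * fl$fluxes[["uptake"]], tolerance = 1e-12)
  expect_equal(fl$fluxes[["maint"]], 0.008 * fTm * 0.33, tolerance = 1e-12)
  expect_equal(fl$fluxes[["enz_production"]],
               (1 + 0.2) * 0.005 * 0.33, tolerance = 1e-12)
  expect_equal(fl$input, 0.003 * 2.4, tolerance = 1e-12)
  # derivatives conserve mass: pool change = input - respiration
  expect_equal(sum(fl$derivatives), fl$input - fl$rh, tolerance = 1e-12)
  expect_error(mend_fluxes(st - 2, p, T, W), "negative")
  expect_error(mend_fluxes(st, p, T, 120), "moisture")
})

test_that("the compiled integrator agrees with the R flux definitions", {
  st <- mend_initial_pools()
  p <- mend_params()
  f1 <- flat_forcing(days = 1, temperature = 19, moisture = 14, gpp = 3)
  sim <- mend_simulate(p, f1, initial = st, substeps = 1)
  fl <- mend_fluxes(st, p, 19, 14, 3)
  expect_equal(unlist(sim[1, names(st)]), st + fl$derivatives,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sim$rh[1], fl$rh, tolerance = 1e-12)
})

test_that("a zero-pool zero-input run respires nothing", {
  init <- mend_initial_pools()
  init[] <- 0
  sim <- mend_simulate(mend_params(), flat_forcing(days = 200), init = init)
  expect_true(all(sim$rh == 0))
  expect_true(all(as.matrix(sim[names(init)]) == 0))
})

test_that("mass balance and non-negativity hold over multi-year runs", {
  d <- study_design(seed = 6)
  f <- gen_forcing(d)
  fw <- f[f$treatment == "warmed", ]
  f3 <- dplyr::bind_rows(fw, fw, fw)
  sim <- mend_simulate(mend_params(), f3)
  mb <- attr(sim, "mass_balance")
  expect_lt(abs(mb[["residual"]]), 1e-6 * mb[["throughput"]])
  expect_true(all(as.matrix(sim[names(mend_initial_pools())]) >= 0))
  expect_true(all(sim$rh >= 0))
})

test_that("halving the step changes cumulative respiration by < 0.5%", {
  d <- study_design(seed = 9)
  fc <- gen_forcing(d)
  fc <- fc[fc$treatment == "control", ]
  s1 <- mend_simulate(mend_params(), fc, substeps = 4)
  s2 <- mend_simulate(mend_params(), fc, substeps = 8)
  expect_lt(abs(sum(s2$rh) - sum(s1$rh)) / sum(s2$rh), 0.005)
})

test_that("doubling GPP input cannot reduce cumulative respiration", {
  d <- study_design(seed = 10)
  fc <- gen_forcing(d)
  fc <- fc[fc$treatment == "control", ]
  base <- sum(mend_simulate(mend_params(), fc)$rh)
  fc2 <- fc
  fc2$gpp <- 2 * fc2$gpp
  expect_gte(sum(mend_simulate(mend_params(), fc2)$rh), base)
})

test_that("constant forcing approaches input-respiration balance", {
  # the mineral-associated pool has a multi-decade time constant, so the
  # long-run balance is probed on a 400-year constant-forcing run
  f400 <- flat_forcing(days = 400 * 365, temperature = 16, moisture = 20,
                       gpp = 3)
  sim <- mend_simulate(mend_params(), f400)
  tail_idx <- (nrow(sim) - 364):nrow(sim)
  in_rate <- mean(sim$input[tail_idx])
  rh_rate <- mean(sim$rh[tail_idx])
  expect_equal(rh_rate / in_rate, 1, tolerance = 0.02)
})

test_that("simulation rejects invalid inputs", {
  expect_error(mend_simulate(mend_params(), flat_forcing()[, 1:2]),
               "temperature|moisture|gpp")
  f <- flat_forcing(days = 10)
  f$temperature[3] <- NA
  expect_error(mend_simulate(mend_params(), f), "missing")
})
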