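test_that("goodness-of-fit metrics match hand computations", {
  expect_equal(fit_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fit_r2(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_equal(fit_r2(c(1, 2, 3), rep(2, 3)), 0)
  expect_lt(fit_r2(c(1, 2, 3), c(9, 9, 9)), 0)  # can be negative
  expect_error(fit_r2(rep(1, 3), c(1, 2, 3)), "variance")
  expect_error(fit_r2(1:3, 1:4), "equal-length")

  expect_equal(fit_r(log(1:5), log(2 * (1:5))), 1, tolerance = 1e-12)
  expect_equal(fit_r(1:5, 5:1), -1, tolerance = 1e-12)
  expect_equal(fit_r(c(0, 1, 2), c(0, 2, 2)), sqrt(3) / 2,
               tolerance = 1e-12)
  expect_error(fit_r(c(1, 1, 1), 1:3), "variance")
})

test_that("objective weights normalize and reduce correctly", {
  sp <- objective_spec(3, 1, 1)
  expect_equal(sum(sp), 1)
  expect_equal(unname(sp[["rh"]]), 0.6)
  expect_error(objective_spec(-1, 1, 1), ">= 0")
  # R2 = 0.5, both r = 1 with default weights: J = 0.6 * 0.5
  j <- 0.6 * (1 - 0.5) + 0.2 * (1 - 1) + 0.2 * (1 - 1)
  expect_equal(j, 0.3)
})

test_that("the total objective hits its analytic anchors", {
  d <- study_design(seed = 12)
  fc <- gen_forcing(d)
  fc <- fc[fc$treatment == "control", ]
  p <- mend_params()
  obs <- gen_rh_observations(p, fc, noise_sd = 0, seed = 1)
  names(obs)[names(obs) == "r_h"] <- "r_h"
  # perfect fit on all three components: J = 0
  j0 <- total_objective(p, obs, fc)
  expect_equal(as.numeric(j0), 0, tolerance = 1e-9)
  comp <- attr(j0, "components")
  expect_equal(unname(comp["rh"]), 0, tolerance = 1e-9)
  # degenerate weights reduce J to 1 - R2 exactly
  p2 <- p
  p2["V_g"] <- 0.3
  j_rh <- total_objective(p2, obs, fc, spec = objective_spec(1, 0, 0))
  sim <- monthly_mend(mend_simulate(p2, fc))
  expect_equal(as.numeric(j_rh), 1 - fit_r2(obs$r_h, sim$rh_umol),
               tolerance = 1e-12)
})

test_that("the optimizer's fast objective equals the documented one", {
  d <- study_design(seed = 14)
  fc <- gen_forcing(d)
  fc <- fc[fc$treatment == "control", ]
  truth <- mend_params()
  obs <- gen_rh_observations(truth, fc, noise_sd = 0.05, seed = 3)
  free <- c("Yg_ref", "k_Yg", "V_g")
  fast <- warmtrait:::make_mend_objective(obs, fc, truth, free)
  set.seed(31)
  for (i in 1:5) {
    x <- c(runif(1, 0.2, 0.7), runif(1, -0.016, 0.004), runif(1, 0.02, 1))
    full <- truth
    full[free] <- x
    expect_equal(fast(x), as.numeric(total_objective(full, obs, fc)),
                 tolerance = 1e-12)
  }
})

test_that("SCE finds the minimum of a quadratic bowl", {
  bowl <- function(x) sum((x - c(0.3, -1.2))^2)
  fit <- sce_optimize(bowl, lower = c(-2, -2), upper = c(2, 2),
                      max_eval = 2000, seed = 5)
  expect_lt(max(abs(fit$par - c(0.3, -1.2))), 1e-3 * 4)
  expect_equal(fit$value, 0, tolerance = 1e-5)
  expect_equal(nrow(fit$trace), fit$n_eval)
})

test_that("SCE is deterministic and scale-invariant in the objective", {
  bowl <- function(x) sum((x - 0.5)^2)
  # tol = 0 disables the absolute-scale stopping rule, which is the one
  # part of the scheme that is not invariant to objective rescaling
  f1 <- sce_optimize(bowl, -1, 1, max_eval = 300, seed = 9, tol = 0)
  f2 <- sce_optimize(bowl, -1, 1, max_eval = 300, seed = 9, tol = 0)
  expect_identical(f1$trace, f2$trace)
  f3 <- sce_optimize(function(x) 7 * bowl(x), -1, 1, max_eval = 300,
                     seed = 9, tol = 0)
  expect_equal(f3$trace$par1, f1$trace$par1)   # same visited points
  expect_equal(f3$trace$J, 7 * f1$trace$J)
  expect_equal(f3$par, f1$par)
})

test_that("SCE certifies convergence when started at a flat optimum", {
  flat <- function(x) 0
  fit <- sce_optimize(flat, -1, 1, max_eval = 500, seed = 2,
                      init = 0)
  expect_true(fit$converged)
  expect_lt(fit$n_eval, 500)
  expect_error(sce_optimize(flat, -1, 1, max_eval = 2, seed = 1),
               "budget")
})

test_that("COFI follows the F-distribution threshold", {
  tr <- tibble::tibble(a = c(0.1, 0.2, 0.3, 0.4), J = c(1, 1.2, 1.5, 4))
  res <- cofi(tr, p = 11, n = 74)
  # frozen independent distribution oracle (scipy.stats.f.ppf(.95, 11, 63))
  f_oracle <- 1.9442118205525662
  expect_equal(res$J_cr, 1 * (1 + 11 / 63 * f_oracle), tolerance = 1e-9)
  expect_equal(res$J_opt, 1)
  expect_true(all(res$feasible$J <= res$J_cr))
  expect_true(min(tr$J) %in% res$feasible$J)  # optimum always feasible
  # J_cr decreases toward J_opt as n grows
  jcrs <- vapply(c(20, 40, 80, 160, 1000),
                 function(n) cofi(tr, p = 11, n = n)$J_cr, numeric(1))
  expect_true(all(diff(jcrs) < 0))
  expect_gt(min(jcrs), res$J_opt)
  # degenerate optimum: J_cr collapses onto the exact optima
  tr0 <- tibble::tibble(a = c(0, 1), J = c(0, 2))
  res0 <- cofi(tr0, p = 1, n = 10)
  expect_equal(res0$J_cr, 0)
  expect_equal(nrow(res0$feasible), 1)
  expect_error(cofi(tr, p = 5, n = 5), "n > p")
})

test_that("calibration recovers known CUE parameters from noisy data", {
  d <- study_design(seed = 19)
  fc <- gen_forcing(d)
  fc <- fc[fc$treatment == "control", ]
  truth <- mend_params()
  obs <- gen_rh_observations(truth, fc,
                             noise_sd = 0.05 * mean(
                               gen_rh_observations(truth, fc, 0, 1)$r_h),
                             seed = 51)
  cal <- calibrate_mend(obs, fc, base_params = truth, budget = 1500,
                        seed = 7)
  expect_lt(abs(cal$params[["Yg_ref"]] - truth[["Yg_ref"]]), 0.05)
  expect_equal(sign(cal$params[["k_Yg"]]), sign(truth[["k_Yg"]]))
  expect_true(all(c("Yg_ref", "k_Yg", "V_g", "J") %in%
                    names(cal$fit$trace)))
  # tidiers expose the fit and its uncertainty
  td <- tidy(cal)
  expect_setequal(td$term, c("Yg_ref", "k_Yg", "V_g"))
  expect_true(all(td$low <= td$estimate & td$estimate <= td$high))
  gl <- glance(cal)
  expect_gt(gl$r2_rh, 0.8)
})
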