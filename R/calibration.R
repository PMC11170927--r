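#' Coefficient of determination
#'
#' `R2 = 1 - SS_res / SS_tot` between observed and simulated series; can
#' be negative when the simulation underperforms the observed mean.
#'
#' @param observed,simulated Equal-length numeric series (n >= 3).
#' @return R-squared.
#' @examples
#' fit_r2(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
fit_r2 <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 3)
    stop("need equal-length series of at least 3 points", call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("observed series has zero variance", call. = FALSE)
  1 - sum((simulated - observed)^2) / sst
}

#' Pearson correlation between log-transformed series
#'
#' The goodness-of-fit metric for gene-abundance constraints, where only
#' relative (multiplicative) covariation is comparable between observed
#' signals and simulated enzyme concentrations.
#'
#' @param observed_log,simulated_log Equal-length log-scale series.
#' @return Pearson r in `[-1, 1]`.
#' @export
fit_r <- function(observed_log, simulated_log) {
  if (length(observed_log) != length(simulated_log) ||
      length(observed_log) < 3)
    stop("need equal-length series of at least 3 points", call. = FALSE)
  if (sd(observed_log) == 0 || sd(simulated_log) == 0)
    stop("zero variance in a series", call. = FALSE)
  cor(observed_log, simulated_log)
}

#' Multiobjective weighting specification
#'
#' Weights for the three calibration objectives: `1 - R2` on Rh and
#' `1 - r` on the log enzyme/gene series. Weights are normalized to sum
#' to one at construction.
#'
#' @param w_rh,w_enzco,w_enzch Non-negative weights; defaults 3/5, 1/5,
#'   1/5 (respiration is observed far more often than gene abundances and
#'   dominates the objective).
#' @return Named numeric vector of class `objective_spec`.
#' @export
objective_spec <- function(w_rh = 3 / 5, w_enzco = 1 / 5, w_enzch = 1 / 5) {
  w <- c(rh = w_rh, enzco = w_enzco, enzch = w_enzch)
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)
  if (sum(w) <= 0) stop("at least one positive weight", call. = FALSE)
  structure(w / sum(w), class = "objective_spec")
}

#' Weighted multiobjective value for a parameter set
#'
#' `J = w1 (1 - R2_Rh) + w2 (1 - r_EnzCo) + w3 (1 - r_EnzCh)`, computed by
#' forward-simulating the decomposition model and comparing monthly
#' aggregates against observations. Enzyme comparisons are on log scale.
#' A failed simulation returns the penalty value.
#'
#' @param params A [mend_params()] vector.
#' @param observations Tibble with `month`, `r_h` and (if enzyme weights
#'   are positive) `enzco_obs`, `enzch_obs` (see [gen_rh_observations()]).
#' @param forcing Daily single-treatment forcing tibble.
#' @param spec An [objective_spec()].
#' @param penalty Objective value substituted for failed simulations.
#' @inheritParams mend_simulate
#' @return The objective value `J` (0 = perfect on all components), with
#'   the per-component values as attribute `components`.
#' @export
total_objective <- function(params, observations, forcing,
                            spec = objective_spec(), penalty = 1e3,
                            initial = mend_initial_pools(), substeps = 4,
                            consts = mend_constants()) {
  sim <- tryCatch(
    mend_simulate(params, forcing, initial = initial, substeps = substeps,
                  consts = consts),
    error = function(e) NULL)
  if (is.null(sim)) return(structure(penalty, failed = TRUE))
  m <- monthly_mend(sim)
  idx <- match(observations$month, m$month)
  if (anyNA(idx)) stop("observations cover months absent from forcing",
                       call. = FALSE)
  comp <- c(rh = NA_real_, enzco = NA_real_, enzch = NA_real_)
  comp["rh"] <- 1 - fit_r2(observations$r_h, m$rh_umol[idx])
  if (spec[["enzco"]] > 0)
    comp["enzco"] <- 1 - fit_r(log(observations$enzco_obs),
                               log(pmax(m$enzco[idx], 1e-300)))
  if (spec[["enzch"]] > 0)
    comp["enzch"] <- 1 - fit_r(log(observations$enzch_obs),
                               log(pmax(m$enzch[idx], 1e-300)))
  used <- !is.na(comp)
  j <- sum(unclass(spec)[used] * comp[used])
  structure(j, components = comp, failed = FALSE)
}

#' Shuffled Complex Evolution (SCE-UA) global minimization
#'
#' The standard SCE-UA scheme: a population of `n_complexes * (2p + 1)`
#' points is partitioned into complexes by rank, each complex evolves by
#' competitive simplex (reflection/contraction/random replacement) steps,
#' and complexes are periodically shuffled. Deterministic given `seed`.
#' The full evaluation trace is returned for feasible-set (COFI)
#' analysis.
#'
#' @param objective Function mapping a numeric parameter vector to a
#'   scalar objective value.
#' @param lower,upper Finite bound vectors (`lower < upper`).
#' @param n_complexes Number of complexes; default `2 * ceiling(sqrt(p))`.
#' @param max_eval Evaluation budget (>= population size).
#' @param seed RNG seed.
#' @param tol Convergence: stop when the population objective range falls
#'   below `tol`.
#' @param init Optional starting point included in the initial population.
#' @return An `sce_fit` list: `par` (best), `value`, `trace` (tibble with
#'   one row per evaluation: parameters and `J`), `n_eval`, `converged`.
#' @export
sce_optimize <- function(objective, lower, upper, n_complexes = NULL,
                         max_eval = 5000, seed = 1, tol = 1e-8,
                         init = NULL) {
  p <- length(lower)
  stopifnot(length(upper) == p, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  if (is.null(n_complexes)) n_complexes <- 2 * ceiling(sqrt(p))
  npg <- 2 * p + 1           # points per complex
  nps <- p + 1               # subcomplex (simplex) size
  nspl <- p + 1              # evolution steps per complex per shuffle
  pop_size <- n_complexes * npg
  if (max_eval < pop_size)
    stop("budget smaller than the SCE population (", pop_size, ")",
         call. = FALSE)
  nm <- names(lower)

  trace_par <- matrix(NA_real_, max_eval, p)
  trace_j <- rep(NA_real_, max_eval)
  n_eval <- 0L
  eval_f <- function(x) {
    n_eval <<- n_eval + 1L
    j <- as.numeric(objective(x))
    trace_par[n_eval, ] <<- x
    trace_j[n_eval] <<- j
    j
  }

  with_seed(seed, {
    X <- matrix(runif(pop_size * p, lower, upper), pop_size, p, byrow = FALSE)
    # runif recycles bounds over rows of a column-major matrix; build by column
    X <- sapply(seq_len(p), function(j) runif(pop_size, lower[j], upper[j]))
    if (!is.null(init)) X[1, ] <- pmin(pmax(init, lower), upper)
    J <- apply(X, 1, eval_f)
    converged <- FALSE
    while (n_eval < max_eval) {
      ord <- order(J)
      X <- X[ord, , drop = FALSE]
      J <- J[ord]
      if (diff(range(J)) < tol) { converged <- TRUE; break }
      for (ic in seq_len(n_complexes)) {
        cidx <- seq(ic, pop_size, by = n_complexes)
        CX <- X[cidx, , drop = FALSE]
        CJ <- J[cidx]
        for (step in seq_len(nspl)) {
          if (n_eval >= max_eval) break
          # triangular selection probability favouring better points
          pr <- (npg + 1 - seq_len(npg)) / sum(seq_len(npg))
          sel <- sort(sample(npg, nps, prob = pr))
          sx <- CX[sel, , drop = FALSE]
          sj <- CJ[sel]
          worst <- which.max(sj)
          centroid <- colMeans(sx[-worst, , drop = FALSE])
          cand <- 2 * centroid - sx[worst, ]
          if (any(cand < lower | cand > upper))
            cand <- lower + runif(p) * (upper - lower)
          cj <- eval_f(cand)
          if (cj >= sj[worst] && n_eval < max_eval) {
            cand <- (centroid + sx[worst, ]) / 2
            cj <- eval_f(cand)
          }
          if (cj >= sj[worst] && n_eval < max_eval) {
            cand <- lower + runif(p) * (upper - lower)
            cj <- eval_f(cand)
          }
          if (cj < sj[worst]) {
            CX[sel[worst], ] <- cand
            CJ[sel[worst]] <- cj
          }
        }
        X[cidx, ] <- CX
        J[cidx] <- CJ
      }
    }
  })

  best <- which.min(trace_j[seq_len(n_eval)])
  tr <- tibble::as_tibble(trace_par[seq_len(n_eval), , drop = FALSE],
                          .name_repair = "minimal")
  names(tr) <- if (!is.null(nm)) nm else paste0("par", seq_len(p))
  tr$J <- trace_j[seq_len(n_eval)]
  structure(
    list(par = setNames(trace_par[best, ], nm), value = trace_j[best],
         trace = tr, n_eval = n_eval, converged = converged),
    class = "sce_fit")
}

#' @export
print.sce_fit <- function(x, ...) {
  cat("SCE-UA fit: J_opt =", signif(x$value, 5), "after", x$n_eval,
      "evaluations", if (x$converged) "(converged)" else "(budget)", "\n")
  print(round(x$par, 5))
  invisible(x)
}

#' Critical Objective Function Index (COFI) uncertainty
#'
#' The critical objective value
#' `J_cr = J_opt (1 + p / (n - p) F_{alpha, p, n-p})` (upper-alpha
#' F-quantile); trace entries with `J <= J_cr` form the feasible parameter
#' set, summarized by a per-parameter coefficient of variation.
#'
#' @param trace Evaluation trace tibble (parameter columns + `J`), e.g.
#'   from [sce_optimize()].
#' @param p Number of calibrated parameters.
#' @param n Number of observations (`n > p`).
#' @param alpha_sig Significance level, default 0.05.
#' @return A `cofi_result`: `J_opt`, `J_cr`, `feasible` (tibble subset),
#'   `cv` (per-parameter), `p`, `n`, `alpha_sig`.
#' @export
cofi <- function(trace, p, n, alpha_sig = 0.05) {
  if (n <= p || p < 1) stop("need n > p >= 1", call. = FALSE)
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)
  ok <- is.finite(trace$J)
  tr <- trace[ok, , drop = FALSE]
  j_opt <- min(tr$J)
  j_cr <- j_opt * (1 + p / (n - p) * qf(1 - alpha_sig, p, n - p))
  feasible <- tr[tr$J <= j_cr, , drop = FALSE]
  par_cols <- setdiff(names(tr), "J")
  cv <- vapply(feasible[par_cols], function(v) {
    m <- mean(v)
    if (m == 0) NA_real_ else sd(v) / abs(m)
  }, numeric(1))
  structure(
    list(J_opt = j_opt, J_cr = j_cr, feasible = feasible, cv = cv,
         p = p, n = n, alpha_sig = alpha_sig),
    class = "cofi_result")
}

#' @export
print.cofi_result <- function(x, ...) {
  cat("COFI: J_opt =", signif(x$J_opt, 5), " J_cr =", signif(x$J_cr, 5),
      " feasible points:", nrow(x$feasible), "\n")
  invisible(x)
}

# Lean objective closure for repeated evaluation inside the optimizer:
# identical math to total_objective(), but skips tibble construction by
# calling the compiled integrator directly and aggregating months with
# rowsum(). Pinned to total_objective() by tests.
make_mend_objective <- function(observations, forcing, base_params, free,
                                spec = objective_spec(), penalty = 1e3,
                                initial = mend_initial_pools(),
                                substeps = 4, consts = mend_constants()) {
  tt <- forcing$temperature
  ww <- forcing$moisture
  gg <- forcing$gpp
  mf <- factor(forcing$month)
  mlev <- as.integer(levels(mf))
  mi <- as.integer(mf)
  ndays <- tabulate(mi)
  oidx <- match(observations$month, mlev)
  if (anyNA(oidx)) stop("observations cover months absent from forcing",
                        call. = FALSE)
  conv <- rh_unit_conversion()
  init <- unname(initial[c("P_O", "P_H", "M", "Q", "D", "B_A", "B_D",
                           "EP_O", "EP_H", "EM")])
  csv <- unclass(consts)[1:16]
  basev <- unclass(base_params)[1:14]
  obs_rh <- observations$r_h
  sst <- sum((obs_rh - mean(obs_rh))^2)
  lco <- if (spec[["enzco"]] > 0) log(observations$enzco_obs)
  lch <- if (spec[["enzch"]] > 0) log(observations$enzch_obs)
  w <- unclass(spec)
  function(x) {
    pv <- basev
    pv[free] <- x
    res <- tryCatch(
      mend_simulate_cpp(pv, csv, init, tt, ww, gg, as.integer(substeps)),
      error = function(e) NULL)
    if (is.null(res)) return(penalty)
    rh_m <- (rowsum(res$rh, mi) / ndays)[oidx] * conv
    j <- w[["rh"]] * (sum((rh_m - obs_rh)^2) / sst)
    if (w[["enzco"]] > 0) {
      eco <- log(pmax((rowsum(res$pools[, 8], mi) / ndays)[oidx], 1e-300))
      j <- j + w[["enzco"]] * (1 - cor(lco, eco))
    }
    if (w[["enzch"]] > 0) {
      ech <- log(pmax((rowsum(res$pools[, 9], mi) / ndays)[oidx], 1e-300))
      j <- j + w[["enzch"]] * (1 - cor(lch, ech))
    }
    j
  }
}

#' Calibrate the decomposition model against observations
#'
#' Convenience wrapper binding [total_objective()], [sce_optimize()] and
#' [cofi()]: calibrates a chosen subset of parameters within bounds and
#' quantifies their uncertainty over the feasible set.
#'
#' @param observations,forcing,spec,initial,substeps,consts As in
#'   [total_objective()].
#' @param base_params Full parameter vector supplying values of
#'   non-calibrated parameters.
#' @param bounds Named list `parameter = c(low, high)` of calibrated
#'   parameters.
#' @param budget,seed,n_complexes Passed to [sce_optimize()].
#' @param n_obs Observation count for COFI; defaults to `nrow(observations)`.
#' @return A `mend_calibration` list: `params` (full best vector), `fit`
#'   (`sce_fit`), `cofi` (`cofi_result`), `objective_components`.
#' @export
calibrate_mend <- function(observations, forcing,
                           base_params = mend_params(),
                           bounds = list(Yg_ref = c(0.2, 0.7),
                                         k_Yg = c(-0.016, 0.004),
                                         V_g = c(0.02, 1)),
                           spec = objective_spec(), budget = 2000,
                           seed = 1, n_complexes = NULL,
                           n_obs = nrow(observations),
                           initial = mend_initial_pools(), substeps = 4,
                           consts = mend_constants()) {
  free <- names(bounds)
  stopifnot(all(free %in% names(base_params)))
  lower <- setNames(vapply(bounds, `[`, 0, 1), free)
  upper <- setNames(vapply(bounds, `[`, 0, 2), free)
  obj <- make_mend_objective(observations, forcing, base_params, free,
                             spec = spec, initial = initial,
                             substeps = substeps, consts = consts)
  fit <- sce_optimize(obj, lower, upper, n_complexes = n_complexes,
                      max_eval = budget, seed = seed)
  best <- base_params
  best[free] <- fit$par
  unc <- cofi(fit$trace, p = length(free), n = n_obs)
  comp <- attr(total_objective(best, observations, forcing, spec = spec,
                               initial = initial, substeps = substeps,
                               consts = consts), "components")
  structure(
    list(params = best, fit = fit, cofi = unc,
         objective_components = comp, spec = spec, bounds = bounds),
    class = "mend_calibration")
}

#' @export
print.mend_calibration <- function(x, ...) {
  cat("gMEND calibration (", length(x$bounds), " free parameters)\n", sep = "")
  print(x$fit)
  print(x$cofi)
  invisible(x)
}
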