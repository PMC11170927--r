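#' Parameters of the first-order (CENTURY/TECO-type) baseline model
#'
#' A linear multi-pool soil carbon model without explicit microbes:
#' `dX = B u(t) + xi(T, W) (A - I) diag(k) X`, with `xi` the product of a
#' Q10 temperature scalar and a saturating moisture ramp, and the respired
#' fraction of each pool's outflow `1 - colSums(A)`. The default is three
#' heterotrophic pools (litter, fast SOM, slow SOM) in series.
#'
#' @param k Pool turnover rates (1/d), one per pool.
#' @param A Transfer-coefficient matrix (`A[i, j]` = fraction of pool j's
#'   outflow transferred to pool i); column sums must be <= 1.
#' @param b Input-allocation vector (sums to 1).
#' @param q10 Q10 of the temperature scalar.
#' @param t_ref Reference temperature (degC) at which the temperature
#'   scalar is 1.
#' @param w_ref Moisture (%V) at which the moisture ramp saturates.
#' @param c_gpp GPP-to-soil C input coefficient (mg C g-1 per g C m-2 d-1),
#'   matching the microbial model's convention.
#' @param initial Initial pool sizes (mg C/g).
#' @return A `teco_params` list.
#' @export
teco_params <- function(k = c(litter = 5e-3, fast = 8e-4, slow = 5e-5),
                        A = matrix(c(0, 0.45, 0,
                                     0, 0, 0.30,
                                     0, 0, 0), 3, 3, byrow = FALSE,
                                   dimnames = list(
                                     c("litter", "fast", "slow"),
                                     c("litter", "fast", "slow"))),
                        b = c(1, 0, 0), q10 = 2, t_ref = 15, w_ref = 25,
                        c_gpp = 0.003,
                        initial = c(litter = 2, fast = 12, slow = 60)) {
  np <- length(k)
  stopifnot(nrow(A) == np, ncol(A) == np, length(b) == np,
            length(initial) == np)
  if (any(k < 0)) stop("turnover rates must be >= 0", call. = FALSE)
  if (any(A < 0 | A > 1)) stop("transfer fractions must lie in [0, 1]",
                               call. = FALSE)
  if (any(colSums(A) > 1 + 1e-12))
    stop("respired + transferred fractions exceed 1 for a pool",
         call. = FALSE)
  structure(list(k = k, A = A, b = b, q10 = q10, t_ref = t_ref,
                 w_ref = w_ref, c_gpp = c_gpp, initial = initial),
            class = "teco_params")
}

#' Forward-simulate the first-order baseline model
#'
#' @param params A [teco_params()] list.
#' @param forcing Daily single-treatment forcing tibble (`temperature`,
#'   `moisture`, `gpp`).
#' @param substeps Euler sub-steps per day (default 48; the linear system
#'   is cheap and fine sub-stepping keeps discretization error well below
#'   0.1% against closed forms).
#' @return A `teco_sim` tibble: `day`, `date`/`month` when present in the
#'   forcing, `rh` (mg C/g/d), `rh_umol`, and one column per pool.
#' @export
teco_simulate <- function(params, forcing, substeps = 48) {
  stopifnot(inherits(params, "teco_params"),
            all(c("temperature", "moisture", "gpp") %in% names(forcing)))
  if (anyNA(forcing[c("temperature", "moisture", "gpp")]))
    stop("forcing series contains missing values", call. = FALSE)
  res <- teco_simulate_cpp(unname(params$k), params$A, unname(params$b),
                           unname(params$initial), params$q10,
                           params$t_ref, params$w_ref, params$c_gpp,
                           forcing$temperature, forcing$moisture,
                           forcing$gpp, as.integer(substeps))
  pools <- tibble::as_tibble(res$pools, .name_repair = "minimal")
  names(pools) <- names(params$k)
  out <- dplyr::bind_cols(
    tibble::tibble(
      day = seq_len(nrow(pools)),
      date = if ("date" %in% names(forcing)) forcing$date else NA,
      month = if ("month" %in% names(forcing)) forcing$month else NA,
      rh = res$rh,
      rh_umol = res$rh * rh_unit_conversion()),
    pools)
  attr(out, "params") <- params
  class(out) <- c("teco_sim", class(out))
  out
}

#' Update baseline-model parameters from a named vector
#'
#' Applies a calibrated subset to a [teco_params()] object: names `k1`,
#' `k2`, ... index pool turnover rates, `q10` the temperature scalar.
#' This is the naming convention used by [mh_calibrate()] priors.
#'
#' @param params A [teco_params()] object.
#' @param theta Named numeric vector of replacements.
#' @return The updated `teco_params`.
#' @export
teco_update <- function(params, theta) {
  for (nm in names(theta)) {
    if (nm == "q10") params$q10 <- theta[[nm]]
    else if (grepl("^k[0-9]+$", nm))
      params$k[as.integer(sub("k", "", nm))] <- theta[[nm]]
    else stop("unknown calibrated parameter: ", nm, call. = FALSE)
  }
  params
}

#' Metropolis-Hastings calibration of the baseline model
#'
#' Gaussian random-walk MH with reflection at the uniform prior bounds.
#' The Gaussian residual variance is marginalized under the Jeffreys prior,
#' giving the integrated log-likelihood `-(n/2) log SSR` on monthly mean
#' Rh. Deterministic given `seed`.
#'
#' @param observed Tibble with `month` and `r_h` (umol CO2 m-2 s-1).
#' @param forcing Daily single-treatment forcing tibble.
#' @param priors Named list `parameter = c(low, high)` of uniform prior
#'   ranges; parameter names as in [teco_update()] (`k1`, `k2`, ...,
#'   `q10`).
#' @param base_params A [teco_params()] supplying fixed structure.
#' @param chain_length Total MH iterations (>= 1000), including the
#'   adaptation window.
#' @param proposal_scale Initial random-walk SD as a fraction of each prior
#'   range (default 0.1); tuned toward ~30% acceptance during the
#'   adaptation window and then frozen.
#' @param seed RNG seed.
#' @param thin Keep every `thin`-th post-adaptation draw.
#' @param burn_in Adaptation window length; default `chain_length / 5`.
#'   Draws from this window are discarded.
#' @param substeps Passed to [teco_simulate()].
#' @return An `mh_fit`: `draws` (tibble of kept draws + `log_post`),
#'   `acceptance_rate` (post-adaptation), `priors`, `map` (best kept
#'   draw), `proposal_sd` (adapted).
#' @export
mh_calibrate <- function(observed, forcing, priors,
                         base_params = teco_params(), chain_length = 5000,
                         proposal_scale = 0.1, seed = 1, thin = 5,
                         burn_in = floor(chain_length / 5),
                         substeps = 48) {
  if (chain_length < 1000) stop("chain_length must be >= 1000", call. = FALSE)
  nm <- names(priors)
  lo <- vapply(priors, `[`, 0, 1)
  hi <- vapply(priors, `[`, 0, 2)
  if (!all(is.finite(lo)) || !all(is.finite(hi)) || any(lo >= hi))
    stop("priors must be finite ranges with low < high", call. = FALSE)
  width <- hi - lo
  nobs <- nrow(observed)

  # lean likelihood: direct call into the compiled integrator
  tt <- forcing$temperature
  ww <- forcing$moisture
  gg <- forcing$gpp
  mf <- factor(forcing$month)
  mi <- as.integer(mf)
  ndays <- tabulate(mi)
  oidx <- match(observed$month, as.integer(levels(mf)))
  if (anyNA(oidx)) stop("observations cover months absent from forcing",
                        call. = FALSE)
  conv <- rh_unit_conversion()
  obs_rh <- observed$r_h
  log_lik <- function(theta) {
    pp <- teco_update(base_params, setNames(theta, nm))
    res <- teco_simulate_cpp(unname(pp$k), pp$A, unname(pp$b),
                             unname(pp$initial), pp$q10, pp$t_ref,
                             pp$w_ref, pp$c_gpp, tt, ww, gg,
                             as.integer(substeps))
    rh_m <- (rowsum(res$rh, mi) / ndays)[oidx] * conv
    ssr <- sum((obs_rh - rh_m)^2)
    # residual variance marginalized under the Jeffreys prior
    -(nobs / 2) * log(ssr + 1e-300)
  }
  reflect <- function(x) {
    for (i in seq_along(x)) {
      while (x[i] < lo[i] || x[i] > hi[i]) {
        if (x[i] < lo[i]) x[i] <- 2 * lo[i] - x[i]
        if (x[i] > hi[i]) x[i] <- 2 * hi[i] - x[i]
      }
    }
    x
  }

  n_keep <- floor((chain_length - burn_in) / thin)
  with_seed(seed, {
    theta <- lo + runif(length(nm)) * width
    ll <- log_lik(theta)
    sdv <- proposal_scale * width
    kept <- matrix(NA_real_, n_keep, length(nm))
    lp <- rep(NA_real_, n_keep)
    acc <- 0L
    acc_win <- 0L
    ki <- 0L
    for (it in seq_len(chain_length)) {
      prop <- reflect(theta + rnorm(length(nm), 0, sdv))
      llp <- log_lik(prop)
      if (log(runif(1)) < llp - ll) {
        theta <- prop
        ll <- llp
        if (it > burn_in) acc <- acc + 1L else acc_win <- acc_win + 1L
      }
      if (it <= burn_in && it %% 50 == 0) {
        # nudge the proposal toward ~30% acceptance, then freeze
        rate <- acc_win / 50
        sdv <- sdv * exp(rate - 0.3)
        sdv <- pmin(sdv, width)
        acc_win <- 0L
      }
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        ki <- ki + 1L
        kept[ki, ] <- theta
        lp[ki] <- ll
      }
    }
  })
  if (acc == 0L)
    stop("zero acceptance after the adaptation window; ",
         "check priors or shrink proposal_scale", call. = FALSE)
  draws <- tibble::as_tibble(kept[seq_len(ki), , drop = FALSE],
                             .name_repair = "minimal")
  names(draws) <- nm
  draws$log_post <- lp[seq_len(ki)]
  structure(
    list(draws = draws,
         acceptance_rate = acc / (chain_length - burn_in),
         priors = priors, map = setNames(kept[which.max(lp[seq_len(ki)]), ], nm),
         proposal_sd = setNames(sdv, nm)),
    class = "mh_fit")
}

#' @export
print.mh_fit <- function(x, ...) {
  cat("Metropolis-Hastings fit:", nrow(x$draws), "kept draws, acceptance",
      sprintf("%.1f%%", 100 * x$acceptance_rate), "\n")
  invisible(x)
}

#' Compare baseline and microbial model fits to observed respiration
#'
#' @param observed Tibble `month`, `r_h`.
#' @param teco_rh,mend_rh Simulated monthly Rh aligned to `observed$month`
#'   (numeric vectors or tibbles with `month` + `rh_umol`).
#' @return One-row tibble: `r2_teco`, `r2_mend`, `improvement`
#'   (`(R2_mend - R2_teco) / R2_teco`, signed, unclipped).
#' @export
compare_models <- function(observed, teco_rh, mend_rh) {
  align <- function(x) {
    if (is.data.frame(x)) {
      idx <- match(observed$month, x$month)
      if (anyNA(idx)) stop("simulated series misses observed months",
                           call. = FALSE)
      x$rh_umol[idx]
    } else {
      if (length(x) != nrow(observed))
        stop("misaligned series", call. = FALSE)
      x
    }
  }
  r2t <- fit_r2(observed$r_h, align(teco_rh))
  r2m <- fit_r2(observed$r_h, align(mend_rh))
  tibble::tibble(r2_teco = r2t, r2_mend = r2m,
                 improvement = (r2m - r2t) / r2t)
}
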