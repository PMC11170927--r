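#' Tidy an SCE-UA fit
#'
#' @param x An `sce_fit`.
#' @param ... Unused.
#' @return One row per calibrated parameter: `term`, `estimate`.
#' @export
tidy.sce_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.sce_fit
#' @export
glance.sce_fit <- function(x, ...) {
  tibble::tibble(J_opt = x$value, n_eval = x$n_eval,
                 converged = x$converged)
}

#' Tidy a COFI uncertainty result
#'
#' @param x A `cofi_result`.
#' @param ... Unused.
#' @return Per parameter: `term`, `estimate` (value at `J_opt`), `cv`,
#'   `low`, `high` (feasible-set range).
#' @export
tidy.cofi_result <- function(x, ...) {
  par_cols <- setdiff(names(x$feasible), "J")
  best <- x$feasible[which.min(x$feasible$J), par_cols]
  tibble::tibble(
    term = par_cols,
    estimate = as.numeric(best[1, ]),
    cv = unname(x$cv[par_cols]),
    low = vapply(x$feasible[par_cols], min, numeric(1)),
    high = vapply(x$feasible[par_cols], max, numeric(1)))
}

#' @rdname tidy.cofi_result
#' @export
glance.cofi_result <- function(x, ...) {
  tibble::tibble(J_opt = x$J_opt, J_cr = x$J_cr,
                 n_feasible = nrow(x$feasible), p = x$p, n = x$n,
                 alpha = x$alpha_sig)
}

#' Tidy a Metropolis-Hastings fit
#'
#' @param x An `mh_fit`.
#' @param conf_level Credible-interval mass, default 0.95.
#' @param ... Unused.
#' @return Per parameter: posterior `estimate` (mean), `std.error` (SD),
#'   `conf.low`, `conf.high` (equal-tail interval).
#' @export
tidy.mh_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  par_cols <- setdiff(names(x$draws), "log_post")
  purrr::map_dfr(par_cols, function(nm) {
    v <- x$draws[[nm]]
    tibble::tibble(term = nm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
}

#' @rdname tidy.mh_fit
#' @export
glance.mh_fit <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x$draws),
                 acceptance_rate = x$acceptance_rate,
                 map_log_post = max(x$draws$log_post))
}

#' Tidy a calibrated microbial-model result
#'
#' @param x A `mend_calibration`.
#' @param ... Unused.
#' @return [tidy.cofi_result()] of the embedded uncertainty analysis.
#' @export
tidy.mend_calibration <- function(x, ...) tidy(x$cofi)

#' @rdname tidy.mend_calibration
#' @export
glance.mend_calibration <- function(x, ...) {
  tibble::tibble(
    J_opt = x$fit$value,
    r2_rh = 1 - unname(x$objective_components["rh"]),
    r_enzco = 1 - unname(x$objective_components["enzco"]),
    r_enzch = 1 - unname(x$objective_components["enzch"]),
    n_eval = x$fit$n_eval)
}
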