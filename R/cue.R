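#' Daily intrinsic CUE series per treatment
#'
#' Evaluates each treatment's calibrated CUE-temperature line on its own
#' soil temperature series.
#'
#' @param params_warmed,params_control Calibrated [mend_params()] vectors.
#' @param forcing Paired forcing tibble (both treatments; see
#'   [gen_forcing()]).
#' @return Tibble `date`, `doy`, `month`, `treatment`, `temperature`,
#'   `cue`.
#' @export
cue_series <- function(params_warmed, params_control, forcing) {
  stopifnot(all(c("treatment", "temperature") %in% names(forcing)))
  if (anyNA(forcing$temperature))
    stop("forcing gap: missing temperatures", call. = FALSE)
  forcing |>
    dplyr::select(dplyr::any_of(c("date", "doy", "month")), "treatment",
                  "temperature") |>
    dplyr::mutate(cue = ifelse(
      .data$treatment == "warmed",
      as.numeric(cue_at(.data$temperature, params_warmed)),
      as.numeric(cue_at(.data$temperature, params_control))))
}

#' Temperature sensitivity of a CUE series
#'
#' Ordinary least-squares slope of CUE against temperature (the apparent
#' sensitivity when applied to realized series; recovers the generating
#' `k_Yg` exactly on clamp-free linear series).
#'
#' @param cue CUE values.
#' @param temperature Matching temperatures (variance > 0, n >= 3).
#' @return Slope (1/degC).
#' @export
sensitivity_slope <- function(cue, temperature) {
  if (length(cue) != length(temperature) || length(cue) < 3)
    stop("need equal-length series of at least 3 points", call. = FALSE)
  if (var(temperature) == 0)
    stop("zero temperature variance", call. = FALSE)
  unname(coef(lm(cue ~ temperature))[2])
}

#' Crossover temperature of two CUE-temperature lines
#'
#' Solves `Yg_w(T*) = Yg_c(T*)` for the clamp-free linear CUE functions:
#' `T* = T_ref + (Yg_ref_c - Yg_ref_w) / (k_w - k_c)`. Returns `NA` when
#' the slopes are equal (parallel lines, including the identical-parameter
#' case) or when the intersection falls outside `range`.
#'
#' @param params_warmed,params_control Calibrated [mend_params()] vectors
#'   sharing `T_ref`.
#' @param range Temperature interval (degC) within which a crossover is
#'   reported; default `c(-10, 45)`.
#' @return Crossover temperature (degC) or `NA`.
#' @examples
#' w <- mend_params(Yg_ref = 0.42, k_Yg = -0.007, T_ref = 20)
#' c0 <- mend_params(Yg_ref = 0.45, k_Yg = -0.010, T_ref = 20)
#' crossover_temperature(w, c0) # 30
#' @export
crossover_temperature <- function(params_warmed, params_control,
                                  range = c(-10, 45)) {
  if (params_warmed[["T_ref"]] != params_control[["T_ref"]])
    stop("treatments must share T_ref", call. = FALSE)
  dk <- params_warmed[["k_Yg"]] - params_control[["k_Yg"]]
  if (dk == 0) return(NA_real_)
  tstar <- params_warmed[["T_ref"]] +
    (params_control[["Yg_ref"]] - params_warmed[["Yg_ref"]]) / dk
  if (tstar < range[1] || tstar > range[2]) return(NA_real_)
  tstar
}

#' CUE temperature-sensitivity report for a calibrated pair
#'
#' Bundles the derived CUE analytics: daily series, intrinsic slopes
#' (`k_Yg` parameters), apparent slopes (regression on the realized,
#' possibly clamped series), the relative sensitivity change, the
#' crossover temperature, and the correlation of the warmed-minus-control
#' CUE difference with control-plot temperature.
#'
#' @inheritParams cue_series
#' @param range Passed to [crossover_temperature()].
#' @return A `cue_report` list: `series`, `intrinsic_slopes`,
#'   `apparent_slopes`, `relative_change_intrinsic` and
#'   `relative_change_apparent` (%, `(k_w - k_c)/|k_c| * 100`),
#'   `crossover`, `difference_correlation`.
#' @export
cue_report <- function(params_warmed, params_control, forcing,
                       range = c(-10, 45)) {
  ser <- cue_series(params_warmed, params_control, forcing)
  ctl <- ser[ser$treatment == "control", ]
  wrm <- ser[ser$treatment == "warmed", ]
  app_w <- sensitivity_slope(wrm$cue, wrm$temperature)
  app_c <- sensitivity_slope(ctl$cue, ctl$temperature)
  k_w <- params_warmed[["k_Yg"]]
  k_c <- params_control[["k_Yg"]]
  rel <- function(a, b) if (b == 0) NA_real_ else 100 * (a - b) / abs(b)
  diff <- wrm$cue - ctl$cue
  structure(
    list(series = ser,
         intrinsic_slopes = c(warmed = k_w, control = k_c),
         apparent_slopes = c(warmed = app_w, control = app_c),
         relative_change_intrinsic = rel(k_w, k_c),
         relative_change_apparent = rel(app_w, app_c),
         crossover = crossover_temperature(params_warmed, params_control,
                                           range),
         difference_correlation = if (sd(diff) == 0) NA_real_ else
           cor(diff, ctl$temperature)),
    class = "cue_report")
}

#' @export
print.cue_report <- function(x, ...) {
  cat("CUE temperature-sensitivity report\n")
  cat("  intrinsic k_Yg (warmed, control):",
      signif(x$intrinsic_slopes, 4), "\n")
  cat("  relative change (intrinsic):",
      sprintf("%.1f%%", x$relative_change_intrinsic), "\n")
  cat("  crossover temperature:",
      if (is.na(x$crossover)) "none in range" else
        sprintf("%.2f degC", x$crossover), "\n")
  invisible(x)
}
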