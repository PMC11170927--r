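#' Quality-control filtering of probe-level microarray signals
#'
#' Applies the spot- and probe-level rules used for functional-gene array
#' data: spots with replicate-pixel CV above `cv_max`, signal-to-noise
#' ratio below the batch-specific floor, or intensity below
#' `min_intensity` are set to missing; probes detected in less than
#' `min_detection` of the replicate samples of a group are then masked in
#' that group. Filtering is idempotent.
#'
#' @param gc A `geochip_matrix` long tibble (see [gen_probe_signals()]);
#'   needs columns `probe`, `sample_id`, `treatment`, `month`, `batch`,
#'   `signal`, `cv`, `snr`.
#' @param cv_max Maximum spot CV (default 0.8).
#' @param snr_min Named vector of per-batch SNR floors; default batch 1
#'   (Jan-Jun hybridizations) 7, batch 2 (Jul-Dec) 3.5.
#' @param min_intensity Minimum spot intensity (default 100).
#' @param min_detection Minimum detected fraction of replicate samples per
#'   group (default 0.5).
#' @param detection_scope Grouping within which the detection fraction is
#'   evaluated: `"treatment_month"` (default), `"treatment"` or `"global"`.
#' @return The filtered `geochip_matrix` (failing spots `NA`), with a
#'   `removal_report` attribute counting removals per rule.
#' @export
qc_filter <- function(gc, cv_max = 0.8, snr_min = c(`1` = 7, `2` = 3.5),
                      min_intensity = 100, min_detection = 0.5,
                      detection_scope = c("treatment_month", "treatment",
                                          "global")) {
  detection_scope <- match.arg(detection_scope)
  stopifnot(cv_max > 0, all(snr_min > 0), min_intensity > 0)
  if (!all(as.character(gc$batch) %in% names(snr_min)))
    stop("unknown batch label: ",
         paste(setdiff(unique(as.character(gc$batch)), names(snr_min)),
               collapse = ", "), call. = FALSE)

  ok <- !is.na(gc$signal)
  fail_cv <- ok & !is.na(gc$cv) & gc$cv > cv_max
  fail_snr <- ok & !is.na(gc$snr) & gc$snr < snr_min[as.character(gc$batch)]
  fail_int <- ok & gc$signal < min_intensity
  out <- gc
  out$signal[fail_cv | fail_snr | fail_int] <- NA_real_

  grp <- switch(detection_scope,
    treatment_month = paste(out$treatment, out$month),
    treatment = out$treatment,
    global = "all")
  key <- paste(out$probe, grp)
  det <- tapply(!is.na(out$signal), key, mean)
  fail_det <- !is.na(out$signal) & det[key] < min_detection
  out$signal[fail_det] <- NA_real_

  report <- tibble::tibble(
    rule = c("cv", "snr", "intensity", "detection"),
    spots_removed = c(sum(fail_cv), sum(fail_snr), sum(fail_int),
                      sum(fail_det)))
  attr(out, "removal_report") <- report
  attr(out, "annotations") <- attr(gc, "annotations")
  class(out) <- unique(c("geochip_matrix", class(out)))
  out
}

#' Between-array normalization and log transform
#'
#' Each array (sample) is first rescaled so its mean universal-standard
#' intensity equals the grand mean of standards across arrays, then
#' functional-probe signals are rescaled so every array's mean functional
#' intensity equals the across-array mean; the natural-log transform is
#' applied last. After step one the per-array standard means are equal to
#' numerical tolerance.
#'
#' @param gc A filtered `geochip_matrix`.
#' @param standard_probes Character vector of universal-standard probe ids;
#'   defaults to the `is_standard` probes of the attached annotations.
#' @param functional_rescale Apply the second (functional-mean) rescaling
#'   step. Default TRUE; note that with widespread true treatment effects
#'   this global step slightly biases unaffected probes toward the
#'   opposite sign (the usual compositional caveat of global array
#'   normalization).
#' @return A `geochip_normalized` long tibble with `log_signal` replacing
#'   `signal`; per-array scale factors in attribute `scale_factors`.
#' @export
normalize_geochip <- function(gc, standard_probes = NULL,
                              functional_rescale = TRUE) {
  ann <- attr(gc, "annotations")
  if (is.null(standard_probes)) {
    if (is.null(ann)) stop("no annotations attached; supply standard_probes",
                           call. = FALSE)
    standard_probes <- ann$probe[ann$is_standard]
  }
  is_std <- gc$probe %in% standard_probes

  std_means <- tapply(gc$signal[is_std], gc$sample_id[is_std],
                      mean, na.rm = TRUE)
  if (any(!is.finite(std_means)))
    stop("array with zero detected standard probes: ",
         paste(names(std_means)[!is.finite(std_means)], collapse = ", "),
         call. = FALSE)
  s1 <- mean(std_means) / std_means
  sig1 <- gc$signal * s1[gc$sample_id]

  fun_means <- tapply(sig1[!is_std], gc$sample_id[!is_std],
                      mean, na.rm = TRUE)
  s2 <- mean(fun_means) / fun_means
  if (!functional_rescale) s2[] <- 1
  sig2 <- ifelse(is_std, sig1, sig1 * s2[gc$sample_id])

  out <- gc
  out$signal <- NULL
  out$log_signal <- log(sig2)
  attr(out, "annotations") <- ann
  attr(out, "scale_factors") <- tibble::tibble(
    sample_id = names(s1), standard_scale = as.numeric(s1),
    functional_scale = as.numeric(s2[names(s1)]))
  class(out) <- unique(c("geochip_normalized",
                         setdiff(class(gc), "geochip_matrix")))
  out
}

#' Warming response ratios with 95% confidence intervals
#'
#' The log response ratio `rr = ln(mean_warmed / mean_control)` of
#' back-transformed (linear-scale) group means, with the delta-method
#' standard error `SE^2 = s_w^2/(n_w mw^2) + s_c^2/(n_c mc^2)` (the lnRR
#' effect size). At the sub-category level, probe signals are summed per
#' sample before the ratio. A record is significant when its CI excludes 0.
#'
#' @param gcn A `geochip_normalized` tibble.
#' @param scope `"season"` (default), `"month"`, or `"year"`; the grouping
#'   within which warmed and control samples are compared.
#' @param level `"probe"` (default) or `"subcategory"`.
#' @param season_table Month-to-season map for `scope = "season"`.
#' @param ci `"normal"` (default, 1.96 SE) or `"t"` (t-quantile with
#'   Welch-style df).
#' @param conf_level Confidence level, default 0.95.
#' @return Tibble of `rr_records`: `unit`, `scope`, `rr`, `se`, `ci_low`,
#'   `ci_high`, `n_w`, `n_c`, `significant`, `degenerate` (zero group
#'   mean).
#' @export
response_ratio <- function(gcn, scope = c("season", "month", "year"),
                           level = c("probe", "subcategory"),
                           season_table = default_season_table(),
                           ci = c("normal", "t"), conf_level = 0.95) {
  scope <- match.arg(scope)
  level <- match.arg(level)
  ci <- match.arg(ci)
  ann <- attr(gcn, "annotations")

  dat <- gcn |>
    dplyr::mutate(value = exp(.data$log_signal),
                  scope_cell = switch(scope,
                    season = season_of(.data$month, season_table),
                    month = as.character(.data$month),
                    year = "year"))
  if (!is.null(ann)) {
    dat <- dat |>
      dplyr::filter(!.data$probe %in% ann$probe[ann$is_standard])
  }
  if (level == "subcategory") {
    if (is.null(ann)) stop("subcategory level needs attached annotations",
                           call. = FALSE)
    dat <- dat |>
      dplyr::mutate(unit = ann$subcategory[match(.data$probe, ann$probe)]) |>
      dplyr::group_by(.data$unit, .data$scope_cell, .data$sample_id,
                      .data$treatment) |>
      dplyr::summarise(value = sum(.data$value, na.rm = TRUE),
                       .groups = "drop")
  } else {
    dat <- dat |> dplyr::rename(unit = "probe")
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- dat |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$unit, scope = .data$scope_cell) |>
    dplyr::summarise(
      n_w = sum(.data$treatment == "warmed"),
      n_c = sum(.data$treatment == "control"),
      mw = mean(.data$value[.data$treatment == "warmed"]),
      mc = mean(.data$value[.data$treatment == "control"]),
      sw2 = var(.data$value[.data$treatment == "warmed"]),
      sc2 = var(.data$value[.data$treatment == "control"]),
      .groups = "drop") |>
    dplyr::mutate(
      degenerate = .data$n_w < 2 | .data$n_c < 2 |
        !is.finite(.data$mw) | !is.finite(.data$mc) |
        .data$mw <= 0 | .data$mc <= 0,
      rr = ifelse(.data$degenerate, NA_real_, log(.data$mw / .data$mc)),
      se = ifelse(.data$degenerate, NA_real_,
                  sqrt(.data$sw2 / (.data$n_w * .data$mw^2) +
                         .data$sc2 / (.data$n_c * .data$mc^2))))
  if (ci == "t") {
    df <- pmax(1, out$n_w + out$n_c - 2)
    q <- stats::qt(1 - (1 - conf_level) / 2, df)
  } else {
    q <- z
  }
  out <- out |>
    dplyr::mutate(ci_low = .data$rr - q * .data$se,
                  ci_high = .data$rr + q * .data$se,
                  significant = !.data$degenerate &
                    (.data$ci_low > 0 | .data$ci_high < 0)) |>
    dplyr::select("unit", "scope", "rr", "se", "ci_low", "ci_high",
                  "n_w", "n_c", "significant", "degenerate")
  class(out) <- c("rr_records", class(out))
  out
}

#' Detection table for probe classification
#'
#' Whether each probe is detected (any unmasked spot) in warmed and in
#' control samples within each scope cell.
#'
#' @param gc A filtered `geochip_matrix`.
#' @inheritParams response_ratio
#' @return Tibble `probe`, `scope`, `detected_warmed`, `detected_control`.
#' @export
detection_table <- function(gc, scope = c("season", "month", "year"),
                            season_table = default_season_table()) {
  scope <- match.arg(scope)
  gc |>
    dplyr::mutate(scope_cell = switch(scope,
      season = season_of(.data$month, season_table),
      month = as.character(.data$month),
      year = "year")) |>
    dplyr::group_by(probe = .data$probe, scope = .data$scope_cell) |>
    dplyr::summarise(
      detected_warmed = any(!is.na(.data$signal[.data$treatment == "warmed"])),
      detected_control = any(!is.na(.data$signal[.data$treatment == "control"])),
      .groups = "drop")
}

#' Classify probes by their warming response
#'
#' Four categories: `unique_warming` (detected only in warmed samples),
#' `increased` (rr > 0, CI excluding 0), `decreased` (rr < 0, CI excluding
#' 0), `unique_control` (detected only in control); all other detected
#' probes are `unchanged`. Probes detected in neither treatment are
#' excluded (counted in attribute `excluded`).
#'
#' @param records Probe-level `rr_records` from [response_ratio()].
#' @param detection Output of [detection_table()] at the same scope.
#' @return Tibble `probe`, `scope`, `category`; per-scope category
#'   percentages in attribute `percentages`.
#' @export
classify_probes <- function(records, detection) {
  rec <- records |>
    dplyr::select(probe = "unit", "scope", "rr", "significant")
  out <- detection |>
    dplyr::left_join(rec, by = c("probe", "scope"))
  excluded <- sum(!out$detected_warmed & !out$detected_control)
  out <- out |>
    dplyr::filter(.data$detected_warmed | .data$detected_control) |>
    dplyr::mutate(category = dplyr::case_when(
      .data$detected_warmed & !.data$detected_control ~ "unique_warming",
      .data$detected_control & !.data$detected_warmed ~ "unique_control",
      !is.na(.data$rr) & .data$significant & .data$rr > 0 ~ "increased",
      !is.na(.data$rr) & .data$significant & .data$rr < 0 ~ "decreased",
      TRUE ~ "unchanged")) |>
    dplyr::select("probe", "scope", "category")
  pct <- out |>
    dplyr::count(.data$scope, .data$category) |>
    dplyr::group_by(.data$scope) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  attr(out, "percentages") <- pct
  attr(out, "excluded") <- excluded
  out
}
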