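#' Default functional-gene probe annotation set
#'
#' A compact annotation table emulating a functional-gene microarray's
#' C-decomposition panel: genes ordered by substrate from labile to
#' recalcitrant (starch to lignin), plus a universal-standard probe set
#' used for between-array normalization.
#'
#' @param n_probes Number of functional probes (spread across genes).
#' @param n_standard Number of universal standard probes.
#' @return Tibble `probe`, `gene`, `subcategory`, `substrate`,
#'   `substrate_order`, `is_standard`.
#' @export
default_gene_annotations <- function(n_probes = 1000, n_standard = 40) {
  genes <- tibble::tribble(
    ~gene, ~subcategory, ~substrate, ~substrate_order,
    "amyA", "C_decomposition", "starch", 1,
    "xylanase", "C_decomposition", "hemicellulose", 2,
    "cellobiase", "C_decomposition", "cellulose", 3,
    "pectinase", "C_decomposition", "pectin", 4,
    "chitinase", "C_decomposition", "chitin", 5,
    "cutinase", "C_decomposition", "cutin", 6,
    "glx", "C_decomposition", "lignin", 7,
    "mnp", "C_decomposition", "lignin", 7,
    "nifH", "N_cycling", "none", NA,
    "amoA", "N_cycling", "none", NA)
  idx <- rep(seq_len(nrow(genes)), length.out = n_probes)
  func <- genes[idx, ] |>
    dplyr::mutate(probe = sprintf("probe%05d", seq_len(n_probes)),
                  is_standard = FALSE)
  std <- tibble::tibble(
    probe = sprintf("std%03d", seq_len(n_standard)),
    gene = "universal_standard", subcategory = "standard",
    substrate = "none", substrate_order = NA_real_, is_standard = TRUE)
  dplyr::bind_rows(func, std) |>
    dplyr::select("probe", "gene", "subcategory", "substrate",
                  "substrate_order", "is_standard")
}

#' Helper: build a probe-level true-effect table
#'
#' @param probes Probe ids carrying the effect.
#' @param months Months (integers) in which the effect applies.
#' @param effect Log-scale effect added to warmed samples.
#' @return Tibble `probe`, `month`, `effect`.
#' @export
rr_effect_table <- function(probes, months, effect) {
  tidyr::expand_grid(probe = probes, month = as.integer(months)) |>
    dplyr::mutate(effect = effect)
}

#' Generate probe-level functional-gene signals with batch structure
#'
#' Lognormal probe signals for every sample of the design, hybridized in
#' two batches (January-June and July-December by default) with a
#' batch-specific intensity scale, optional warmed-vs-control effects on
#' selected probes and months, and per-spot QC fields (replicate-pixel CV,
#' signal-to-noise ratio). With `true_rr_effects = NULL` and
#' `noise_sd = 0` warmed and control signals are identical, so every
#' downstream response ratio is exactly zero.
#'
#' @param design A [study_design()].
#' @param annotations Probe annotation table; default
#'   [default_gene_annotations()].
#' @param batch_split Integer vector of length 12 mapping month to batch.
#' @param true_rr_effects `NULL` or a tibble `probe`, `month`, `effect`
#'   (see [rr_effect_table()]).
#' @param noise_sd Lognormal (sdlog) spot noise.
#' @param batch_scale Multiplicative intensity scale of batch 2 relative to
#'   batch 1 (removed again by [normalize_geochip()]).
#' @param base_meanlog,base_sdlog Lognormal parameters of per-probe base
#'   intensities.
#' @return A `geochip_matrix`: long tibble `probe`, `sample_id`, `block`,
#'   `month`, `treatment`, `batch`, `signal`, `cv`, `snr` with the
#'   annotation table attached as attribute `annotations`.
#' @export
gen_probe_signals <- function(design,
                              annotations = default_gene_annotations(),
                              batch_split = rep(1:2, each = 6),
                              true_rr_effects = NULL,
                              noise_sd = 0.3,
                              batch_scale = 1.35,
                              base_meanlog = log(2000),
                              base_sdlog = 0.6) {
  stopifnot(inherits(design, "study_design"))
  if (length(batch_split) != 12 || anyNA(batch_split))
    stop("batch_split must map every month to exactly one batch",
         call. = FALSE)
  if (nrow(annotations) < 1) stop("need at least one probe", call. = FALSE)

  samples <- design$samples |>
    dplyr::mutate(batch = batch_split[.data$month])

  with_seed(derive_seed(design$seed, "geochip"), {
    base <- ifelse(annotations$is_standard,
                   5000,
                   rlnorm(nrow(annotations), base_meanlog, base_sdlog))
    grid <- tidyr::expand_grid(probe = annotations$probe,
                               sample_id = samples$sample_id) |>
      dplyr::left_join(samples, by = "sample_id") |>
      dplyr::mutate(
        base = base[match(.data$probe, annotations$probe)],
        is_standard = annotations$is_standard[
          match(.data$probe, annotations$probe)])
    eff <- rep(0, nrow(grid))
    if (!is.null(true_rr_effects)) {
      key <- paste(grid$probe, grid$month)
      ekey <- paste(true_rr_effects$probe, true_rr_effects$month)
      hit <- match(key, ekey)
      eff <- ifelse(!is.na(hit) & grid$treatment == "warmed",
                    true_rr_effects$effect[hit], 0)
    }
    noise <- if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
    std_noise <- if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd / 6) else 0
    grid <- grid |>
      dplyr::mutate(
        signal = .data$base *
          ifelse(.data$batch == 2, batch_scale, 1) *
          exp(eff + ifelse(.data$is_standard, std_noise, noise)),
        cv = round(runif(dplyr::n(), 0.05, 0.5), 3),
        snr = round(runif(dplyr::n(), 8, 40), 2))
  })

  out <- grid |>
    dplyr::select("probe", "sample_id", "block", "month", "treatment",
                  "batch", "signal", "cv", "snr")
  attr(out, "annotations") <- annotations
  class(out) <- c("geochip_matrix", class(out))
  out
}
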