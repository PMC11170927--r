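# Shared fixtures and independent oracles used across test files.

# Brute-force community-trait oracle: treat each read as one rrn operon;
# an organism of taxon i accounts for 1/n_i organisms per read. Loops
# read-by-read on purpose (enumeration, not algebra).
oracle_community_rrn <- function(abundance, copy_number) {
  total_reads <- 0
  total_organisms <- 0
  for (i in seq_along(abundance)) {
    for (r in seq_len(abundance[i])) {
      total_reads <- total_reads + 1
      total_organisms <- total_organisms + 1 / copy_number[i]
    }
  }
  total_reads / total_organisms
}

# Independent spot-QC oracle: applies each masking rule in isolation and
# combines them, then evaluates group-wise detection.
oracle_qc <- function(gc, cv_max = 0.8, snr_min = c(`1` = 7, `2` = 3.5),
                      min_intensity = 100, min_detection = 0.5) {
  masked <- rep(FALSE, nrow(gc))
  for (i in seq_len(nrow(gc))) {
    if (gc$cv[i] > cv_max) masked[i] <- TRUE
    if (gc$snr[i] < snr_min[as.character(gc$batch[i])]) masked[i] <- TRUE
    if (gc$signal[i] < min_intensity) masked[i] <- TRUE
  }
  dropped <- rep(FALSE, nrow(gc))
  for (pr in unique(gc$probe)) {
    for (tr in unique(gc$treatment)) {
      for (mo in unique(gc$month)) {
        idx <- which(gc$probe == pr & gc$treatment == tr & gc$month == mo)
        if (length(idx) == 0) next
        if (mean(!masked[idx]) < min_detection) dropped[idx] <- TRUE
      }
    }
  }
  list(masked = masked, dropped = dropped & !masked)
}

# Minimal geochip long tibble with full control over QC fields.
toy_geochip <- function(probes = 2, samples = 4, signal = 500, cv = 0.2,
                        snr = 10) {
  grid <- tidyr::expand_grid(
    probe = sprintf("p%02d", seq_len(probes)),
    sample_id = sprintf("s%02d", seq_len(samples)))
  n <- nrow(grid)
  out <- grid |>
    dplyr::mutate(
      block = rep_len(1:2, n),
      month = ifelse(as.integer(sub("s", "", sample_id)) <= samples / 2,
                     1L, 7L),
      treatment = rep_len(c("control", "warmed"), n),
      batch = ifelse(month <= 6, 1L, 2L),
      signal = signal, cv = cv, snr = snr)
  class(out) <- c("geochip_matrix", class(out))
  out
}

# A constant-month forcing year for process-model toys.
flat_forcing <- function(days = 365, temperature = 15, moisture = 25,
                         gpp = 0) {
  month_len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  tibble::tibble(
    temperature = rep(temperature, days),
    moisture = rep(moisture, days),
    gpp = rep(gpp, days),
    month = rep(rep(1:12, month_len), length.out = days))
}

# Single-pool exponential-decay configuration of the baseline model.
decay_toy <- function(k = 0.01, x0 = 10) {
  teco_params(k = c(pool = k), A = matrix(0, 1, 1), b = 1, q10 = 2,
              t_ref = 15, initial = c(pool = x0))
}
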