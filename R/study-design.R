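#' Paired warming study design
#'
#' Describes a paired warming experiment: `n_blocks` replicate blocks, each
#' holding one warmed and one control plot, sampled monthly over one year.
#' The default (4 blocks x 12 months x 2 treatments) yields 96 samples, the
#' layout every generator and downstream estimator in this package assumes.
#'
#' @param n_blocks Number of replicate blocks (paired plots). Default 4.
#' @param year Calendar year of the sampling campaign. Default 2012.
#' @param months Integer vector of sampled months. Default `1:12`.
#' @param seed Master seed; all generator randomness derives from it.
#'
#' @return An object of class `study_design`: a list with `samples` (a tibble
#'   with one row per sample: `sample_id`, `block`, `month`, `treatment`),
#'   plus `n_blocks`, `year`, `months` and `seed`.
#' @examples
#' d <- study_design(seed = 1)
#' nrow(d$samples) # 96
#' @export
study_design <- function(n_blocks = 4, year = 2012, months = 1:12, seed) {
  stopifnot(n_blocks >= 1, all(months %in% 1:12))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  samples <- tidyr::expand_grid(
    block = seq_len(n_blocks),
    month = as.integer(months),
    treatment = c("control", "warmed")
  ) |>
    dplyr::mutate(sample_id = sprintf("B%dM%02d%s", .data$block, .data$month,
                                      ifelse(.data$treatment == "warmed", "W", "C"))) |>
    dplyr::select("sample_id", "block", "month", "treatment")
  structure(
    list(samples = samples, n_blocks = n_blocks, year = year,
         months = as.integer(months), seed = seed),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Paired warming study design: ", x$n_blocks, " blocks x ",
      length(x$months), " months x 2 treatments = ", nrow(x$samples),
      " samples (year ", x$year, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Calendar season labels
#'
#' The default month-to-season map: January-February early cool season,
#' March-September warm season, October-December late cool season. A
#' data-driven alternative can be derived with [derive_partition()].
#'
#' @return A tibble with columns `month` (1-12) and `season`.
#' @export
default_season_table <- function() {
  tibble::tibble(
    month = 1:12,
    season = c("early_cool", "early_cool", rep("warm", 7),
               rep("late_cool", 3))
  )
}

# map months to season labels using a season table (month, season)
season_of <- function(month, season_table = default_season_table()) {
  season_table$season[match(month, season_table$month)]
}
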