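#' Assign rrn copy numbers to ASVs by rank fallback
#'
#' Each ASV is matched to the copy-number lookup at the lowest taxonomic
#' rank whose classifier confidence strictly exceeds `confidence_floor`
#' (ranks at exactly the floor fail). For the matched taxon, the mean copy
#' number of its child entries is used when children exist; otherwise the
#' taxon's own entry; otherwise the search ascends the lineage to the
#' nearest ancestor with entries and uses the mean of that ancestor's child
#' taxa. ASVs with no matchable ancestor are returned as `NA` (and counted
#' in the `unassigned` attribute); they are excluded from community
#' aggregation rather than imputed.
#'
#' @param taxonomy Tibble with `asv_id`, `lineage` and `confidence`
#'   (semicolon-separated, domain to species).
#' @param lookup Tibble with `taxon`, `rank`, `copy_number` (> 0), `parent`.
#' @param confidence_floor Confidence threshold in (0, 1); default 0.5.
#'
#' @return A tibble `asv_id`, `copy_number`, `matched_taxon`, `matched_rank`
#'   with attribute `unassigned` (count of NA assignments).
#' @examples
#' lk <- tibble::tibble(taxon = c("g__A", "s__x", "s__y"),
#'                      rank = c("genus", "species", "species"),
#'                      copy_number = c(3, 2, 4), parent = c("f__F", "g__A", "g__A"))
#' tx <- tibble::tibble(asv_id = "ASV1",
#'                      lineage = "d__B;p__P;c__C;o__O;f__F;g__A;s__z",
#'                      confidence = "1;1;1;1;1;0.9;0.3")
#' assign_rrn(tx, lk)$copy_number # mean of child species of g__A = 3
#' @export
assign_rrn <- function(taxonomy, lookup, confidence_floor = 0.5) {
  stopifnot(confidence_floor > 0, confidence_floor < 1)
  if (!all(lookup$copy_number > 0))
    stop("lookup copy numbers must be > 0", call. = FALSE)

  child_mean <- tapply(lookup$copy_number, lookup$parent, mean)
  own <- setNames(lookup$copy_number, lookup$taxon)

  value_of <- function(taxon) {
    if (!is.na(child_mean[taxon])) return(unname(child_mean[taxon]))
    if (taxon %in% names(own)) return(unname(own[taxon]))
    NA_real_
  }

  res <- purrr::pmap(taxonomy[c("lineage", "confidence")],
                     function(lineage, confidence) {
    taxa <- strsplit(lineage, ";", fixed = TRUE)[[1]]
    conf <- as.numeric(strsplit(confidence, ";", fixed = TRUE)[[1]])
    if (length(taxa) == 0) stop("empty lineage", call. = FALSE)
    # lowest rank with confidence strictly above the floor
    ok <- which(conf > confidence_floor)
    if (length(ok) == 0)
      return(list(copy_number = NA_real_, matched_taxon = NA_character_,
                  matched_rank = NA_integer_))
    start <- max(ok)
    for (i in rev(seq_len(start))) {
      v <- value_of(taxa[i])
      if (!is.na(v))
        return(list(copy_number = v, matched_taxon = taxa[i],
                    matched_rank = i))
    }
    list(copy_number = NA_real_, matched_taxon = NA_character_,
         matched_rank = NA_integer_)
  })

  out <- tibble::tibble(
    asv_id = taxonomy$asv_id,
    copy_number = purrr::map_dbl(res, "copy_number"),
    matched_taxon = purrr::map_chr(res, "matched_taxon"),
    matched_rank = purrr::map_int(res, "matched_rank"))
  attr(out, "unassigned") <- sum(is.na(out$copy_number))
  out
}

#' Community-aggregated rrn copy number
#'
#' The abundance-weighted aggregate trait of a sample,
#' `sum(S_i) / sum(S_i / n_i)`: the number of reads divided by the implied
#' number of organisms when each read represents one rrn operon. ASVs with
#' `NA` copy number are dropped from numerator and denominator.
#'
#' @param abundance Non-negative integer read counts `S_i`.
#' @param copy_number Per-ASV rrn copy numbers `n_i` (> 0, `NA` allowed).
#' @return A single positive number, bounded by `range(copy_number)` over
#'   the ASVs present.
#' @examples
#' community_rrn(c(10, 10), c(1, 5)) # 20 / 12 = 1.667
#' @export
community_rrn <- function(abundance, copy_number) {
  if (length(abundance) != length(copy_number))
    stop("abundance and copy_number lengths differ", call. = FALSE)
  keep <- !is.na(copy_number)
  abundance <- abundance[keep]
  copy_number <- copy_number[keep]
  if (any(abundance < 0)) stop("negative abundance", call. = FALSE)
  if (any(copy_number <= 0)) stop("copy numbers must be > 0", call. = FALSE)
  if (sum(abundance) <= 0)
    stop("sample has no reads with assigned copy numbers", call. = FALSE)
  sum(abundance) / sum(abundance / copy_number)
}

#' Per-sample trait summaries for a study
#'
#' Applies [community_rrn()] to every sample column of an ASV count table.
#'
#' @param counts Tibble `asv_id` + one column per sample.
#' @param assignments Output of [assign_rrn()].
#' @param design A [study_design()] supplying sample metadata.
#' @param season_table Month-to-season map.
#' @return Tibble `sample_id`, `block`, `month`, `season`, `treatment`,
#'   `community_rrn`.
#' @export
trait_summaries <- function(counts, assignments, design,
                            season_table = default_season_table()) {
  n <- assignments$copy_number[match(counts$asv_id, assignments$asv_id)]
  sample_cols <- setdiff(names(counts), "asv_id")
  vals <- purrr::map_dbl(sample_cols, \(s) community_rrn(counts[[s]], n))
  design$samples |>
    dplyr::mutate(
      season = season_of(.data$month, season_table),
      community_rrn = vals[match(.data$sample_id, sample_cols)]) |>
    dplyr::select("sample_id", "block", "month", "season", "treatment",
                  "community_rrn")
}

#' Paired log-ratio of a trait between warmed and control
#'
#' `ln(value_warmed / value_control)` for a matched block-month pair.
#'
#' @param value_warmed,value_control Positive trait values.
#' @return The log-ratio (antisymmetric under argument swap).
#' @export
paired_log_ratio <- function(value_warmed, value_control) {
  if (any(value_warmed <= 0) || any(value_control <= 0))
    stop("paired log-ratio requires positive values", call. = FALSE)
  log(value_warmed / value_control)
}

#' Block-month paired log-ratios of community rrn copy number
#'
#' @param traits Output of [trait_summaries()].
#' @return Tibble keyed by `block`, `month` with `season` and `log_ratio`.
#' @export
paired_trait_ratios <- function(traits) {
  traits |>
    dplyr::select("block", "month", "season", "treatment", "community_rrn") |>
    tidyr::pivot_wider(names_from = "treatment",
                       values_from = "community_rrn") |>
    dplyr::mutate(log_ratio = paired_log_ratio(.data$warmed, .data$control)) |>
    dplyr::select("block", "month", "season", "log_ratio")
}

#' Microbial metabolic quotient
#'
#' Heterotrophic respiration per unit microbial biomass, with DNA yield as
#' the biomass proxy. Units cancel only in relative comparisons; keep them
#' consistent across samples.
#'
#' @param r_h Heterotrophic respiration flux (>= 0).
#' @param biomass_proxy Microbial biomass proxy (> 0), e.g. DNA yield.
#' @return `r_h / biomass_proxy`, vectorized.
#' @export
metabolic_quotient <- function(r_h, biomass_proxy) {
  if (any(biomass_proxy <= 0))
    stop("biomass proxy must be positive", call. = FALSE)
  r_h / biomass_proxy
}

#' Seasonal paired comparison of a trait
#'
#' Paired t-tests of warmed vs control per season (delegated to
#' [stats::t.test()]), the routine inference layer over the trait chain.
#'
#' @param traits Output of [trait_summaries()] (or any tibble with `block`,
#'   `month`, `season`, `treatment` and a `value` column).
#' @param value Column to compare (tidy-eval), default `community_rrn`.
#' @return Tibble per season: `n_pairs`, `mean_warmed`, `mean_control`,
#'   `mean_difference`, `p_value`.
#' @export
seasonal_trait_test <- function(traits, value = "community_rrn") {
  wide <- traits |>
    dplyr::select("block", "month", "season", "treatment",
                  value = dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "value")
  wide |>
    dplyr::group_by(.data$season) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_warmed = mean(.data$warmed),
      mean_control = mean(.data$control),
      mean_difference = mean(.data$warmed - .data$control),
      p_value = if (dplyr::n() >= 2)
        t.test(.data$warmed, .data$control, paired = TRUE)$p.value
      else NA_real_,
      .groups = "drop")
}
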