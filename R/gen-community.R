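#' Generate a synthetic ASV community with an rrn trait structure
#'
#' Builds an ASV count table, a taxonomy table with per-rank confidences and
#' an rrnDB-style copy-number lookup whose joint structure mirrors a paired
#' warming experiment: every sample shares a common species-abundance
#' backbone, and in the months where `warming_trait_effect` is non-zero the
#' warmed member of each block-month pair is tilted toward high-copy-number
#' taxa so that the log-ratio of community-aggregated rrn copy number
#' (warmed vs control) equals the configured effect at the level of true
#' relative abundances.
#'
#' Counts are drawn Dirichlet-multinomial at a fixed depth (default 21 567
#' reads per sample), emulating a rarefied ASV table.
#'
#' @param design A [study_design()].
#' @param n_asvs Number of ASVs (>= 2).
#' @param rrn_distribution List with `meanlog`, `sdlog` and `max` of the
#'   lognormal from which per-species rrn copy numbers are drawn (clamped to
#'   `[1, max]`). A degenerate distribution (`sdlog = 0`) is allowed but
#'   flagged with a warning.
#' @param warming_trait_effect Named per-season log-ratio effect on the
#'   community rrn copy number (warmed minus control); default +0.12 in both
#'   cool seasons, 0 in the warm season.
#' @param depth Reads per sample for the multinomial draw.
#' @param concentration Dirichlet concentration controlling sample-to-sample
#'   compositional variability (larger = more similar communities).
#' @param lowconf_fraction Fraction of ASVs whose species-rank confidence is
#'   generated below 0.5, exercising the rank-fallback assignment path.
#' @param season_table Month-to-season map; defaults to
#'   [default_season_table()].
#'
#' @return A list with tibbles `counts` (asv_id + one column per sample),
#'   `taxonomy` (`asv_id`, `lineage`, `confidence`; semicolon-separated
#'   domain..species), `lookup` (`taxon`, `rank`, `copy_number`, `parent`)
#'   and `truth` (per-sample true community rrn copy number on the
#'   underlying proportions and the configured effect).
#' @export
gen_community <- function(design, n_asvs = 400,
                          rrn_distribution = list(meanlog = log(2.2),
                                                  sdlog = 0.55, max = 15),
                          warming_trait_effect = c(early_cool = 0.12,
                                                   warm = 0,
                                                   late_cool = 0.12),
                          depth = 21567, concentration = 150,
                          lowconf_fraction = 0.08,
                          season_table = default_season_table()) {
  stopifnot(inherits(design, "study_design"))
  if (n_asvs < 2) stop("n_asvs must be >= 2", call. = FALSE)
  if (!all(is.finite(warming_trait_effect)))
    stop("warming_trait_effect must be finite", call. = FALSE)
  if (rrn_distribution$sdlog == 0)
    warning("degenerate rrn distribution: all species share one copy number")

  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")

  with_seed(derive_seed(design$seed, "community"), {
    # taxonomic scaffold: phyla > families > genera > species (one per ASV)
    n_phyla <- 6
    n_fam <- max(8, round(n_asvs / 25))
    n_gen <- max(n_fam + 1, round(n_asvs / 6))
    fam_phylum <- sample(n_phyla, n_fam, replace = TRUE)
    gen_fam <- sample(n_fam, n_gen, replace = TRUE)
    asv_gen <- sample(n_gen, n_asvs, replace = TRUE)

    species <- sprintf("s__sp%04d", seq_len(n_asvs))
    genus <- sprintf("g__gen%03d", asv_gen)
    family <- sprintf("f__fam%03d", gen_fam[asv_gen])
    phylum <- sprintf("p__phy%02d", fam_phylum[gen_fam[asv_gen]])

    copy_sp <- pmin(rrn_distribution$max,
                    pmax(1, rlnorm(n_asvs, rrn_distribution$meanlog,
                                   rrn_distribution$sdlog)))

    lineage <- paste("d__Bacteria", phylum, paste0("c__", sub("p__", "", phylum)),
                     paste0("o__", sub("f__", "", family)), family, genus,
                     species, sep = ";")
    conf <- matrix(round(runif(n_asvs * 7, 0.92, 1), 3), n_asvs, 7)
    low <- runif(n_asvs) < lowconf_fraction
    conf[low, 7] <- round(runif(sum(low), 0.05, 0.45), 3)
    confidence <- apply(conf, 1, paste, collapse = ";")

    taxonomy <- tibble::tibble(
      asv_id = sprintf("ASV%04d", seq_len(n_asvs)),
      lineage = lineage, confidence = confidence)

    sp_tbl <- tibble::tibble(taxon = species, rank = "species",
                             copy_number = copy_sp, parent = genus)
    gen_tbl <- sp_tbl |>
      dplyr::group_by(taxon = .data$parent) |>
      dplyr::summarise(copy_number = mean(.data$copy_number)) |>
      dplyr::mutate(rank = "genus",
                    parent = family[match(.data$taxon, genus)])
    fam_tbl <- gen_tbl |>
      dplyr::group_by(taxon = .data$parent) |>
      dplyr::summarise(copy_number = mean(.data$copy_number)) |>
      dplyr::mutate(rank = "family",
                    parent = phylum[match(.data$taxon, family)])
    lookup <- dplyr::bind_rows(sp_tbl, gen_tbl, fam_tbl) |>
      dplyr::select("taxon", "rank", "copy_number", "parent")

    # effective copy number: exactly what the downstream assignment returns
    n_eff <- assign_rrn(taxonomy, lookup)$copy_number

    # common species-abundance backbone + per-pair Dirichlet draws
    base <- rlnorm(n_asvs, 0, 1.3)
    base <- base / sum(base)

    samples <- design$samples
    pairs <- samples |>
      dplyr::distinct(.data$block, .data$month) |>
      dplyr::mutate(season = season_of(.data$month, season_table))

    counts <- matrix(0L, n_asvs, nrow(samples),
                     dimnames = list(taxonomy$asv_id, samples$sample_id))
    truth <- vector("list", nrow(samples))
    idx <- 1L
    for (k in seq_len(nrow(pairs))) {
      g <- rgamma(n_asvs, shape = concentration * n_asvs * base, rate = 1)
      p_ctl <- g / sum(g)
      eff <- unname(warming_trait_effect[pairs$season[k]])
      p_wrm <- tilt_to_effect(p_ctl, n_eff, eff)
      for (tr in c("control", "warmed")) {
        p <- if (tr == "control") p_ctl else p_wrm
        sid <- samples$sample_id[samples$block == pairs$block[k] &
                                   samples$month == pairs$month[k] &
                                   samples$treatment == tr]
        counts[, sid] <- rmultinom(1, depth, p)[, 1]
        truth[[idx]] <- tibble::tibble(
          sample_id = sid, block = pairs$block[k], month = pairs$month[k],
          treatment = tr, true_rrn = 1 / sum(p / n_eff),
          configured_effect = eff)
        idx <- idx + 1L
      }
    }
  })

  list(
    counts = tibble::as_tibble(counts, rownames = "asv_id"),
    taxonomy = taxonomy,
    lookup = lookup,
    truth = dplyr::bind_rows(truth)
  )
}

#' Tilt a composition toward high-trait taxa to hit a target log-effect
#'
#' Reweights relative abundances `p` as `p * n^theta` and solves for the
#' exponent `theta` such that the community-aggregated copy number of the
#' tilted composition exceeds that of `p` by exactly `delta` on the log
#' scale. Used by [gen_community()] to implant a known warming effect.
#'
#' @param p Relative abundances (will be normalized).
#' @param n Per-taxon trait values (> 0).
#' @param delta Target log-ratio (tilted vs original community trait).
#' @return The tilted composition (sums to 1).
#' @export
tilt_to_effect <- function(p, n, delta) {
  p <- p / sum(p)
  if (abs(delta) < 1e-12) return(p)
  crrn <- function(q) 1 / sum(q / n)
  base <- log(crrn(p))
  f <- function(theta) {
    q <- p * n^theta
    log(crrn(q / sum(q))) - base - delta
  }
  lim <- log(max(n) / crrn(p)) # supremum of achievable delta
  if (delta >= lim)
    stop("requested effect exceeds the trait range of the community",
         call. = FALSE)
  theta <- stats::uniroot(f, c(-50, 50), tol = 1e-12)$root
  q <- p * n^theta
  q / sum(q)
}
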