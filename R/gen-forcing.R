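#' Generate daily forcing series for a paired warming experiment
#'
#' Produces paired (warmed, control) daily series of soil temperature,
#' volumetric soil moisture and GPP with the seasonal structure of a
#' temperate mixed-grass prairie: an annual temperature sinusoid whose
#' monthly means span roughly 3.5 degC in the coldest month to 28.1 degC in
#' the warmest, AR(1) day-to-day variability, a constant season-specific
#' warming offset added to the warmed series, and a multiplicative
#' cool-season moisture reduction under warming.
#'
#' @param design A [study_design()].
#' @param climate List with `mean`, `amplitude` (> 0) and `peak_day` of the
#'   annual temperature cycle (degC; day of year of the maximum), and
#'   `noise_sd`, `noise_rho` for the AR(1) daily deviations.
#' @param warming_offsets Named numeric vector of soil-warming offsets
#'   (degC) per season; names must cover every season label in
#'   `season_table`. Defaults +3.6 (early cool), +4.5 (warm), +4.1 (late
#'   cool).
#' @param moisture_params List with per-season control means `base` (%V),
#'   per-season multiplicative warming factors `warming_factor`, and AR(1)
#'   noise settings.
#' @param gpp_params List with `mean`, `amplitude`, `peak_day` and noise
#'   settings of the GPP annual cycle (g C m-2 d-1).
#' @param season_table Month-to-season map used to apply per-season
#'   offsets; defaults to [default_season_table()].
#'
#' @return A tibble (classed `forcing_series`) with one row per day and
#'   treatment: `date`, `doy`, `month`, `treatment`, `temperature`,
#'   `moisture`, `gpp`.
#' @examples
#' f <- gen_forcing(study_design(seed = 1))
#' dplyr::count(f, treatment)
#' @export
gen_forcing <- function(design,
                        climate = list(mean = 15.8, amplitude = 12.3,
                                       peak_day = 197, noise_sd = 1.6,
                                       noise_rho = 0.7),
                        warming_offsets = c(early_cool = 3.6, warm = 4.5,
                                            late_cool = 4.1),
                        moisture_params = list(
                          base = c(early_cool = 10.7, warm = 13.0,
                                   late_cool = 7.5),
                          warming_factor = c(early_cool = 5.9 / 10.7,
                                             warm = 1.0,
                                             late_cool = 5.3 / 7.5),
                          noise_sd = 1.2, noise_rho = 0.6),
                        gpp_params = list(mean = 3.5, amplitude = 4.5,
                                          peak_day = 197, noise_sd = 0.8,
                                          noise_rho = 0.5),
                        season_table = default_season_table()) {
  stopifnot(inherits(design, "study_design"))
  if (!is.numeric(climate$amplitude) || climate$amplitude <= 0)
    stop("climate amplitude must be positive", call. = FALSE)
  if (!all(is.finite(warming_offsets)))
    stop("warming offsets must be finite", call. = FALSE)
  needed <- unique(season_table$season)
  if (!all(needed %in% names(warming_offsets)))
    stop("warming_offsets must name every season: ",
         paste(setdiff(needed, names(warming_offsets)), collapse = ", "),
         call. = FALSE)

  dates <- seq(as.Date(sprintf("%d-01-01", design$year)),
               as.Date(sprintf("%d-12-31", design$year)), by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  month <- as.integer(format(dates, "%m"))
  season <- season_of(month, season_table)

  ar1 <- function(n, sd, rho) {
    if (sd <= 0) return(rep(0, n))
    e <- rnorm(n, 0, sd * sqrt(1 - rho^2))
    as.numeric(stats::filter(e, rho, method = "recursive"))
  }

  with_seed(derive_seed(design$seed, "forcing"), {
    t_noise <- ar1(nd, climate$noise_sd, climate$noise_rho)
    m_noise <- ar1(nd, moisture_params$noise_sd, moisture_params$noise_rho)
    g_noise <- ar1(nd, gpp_params$noise_sd, gpp_params$noise_rho)
  })

  temp_c <- climate$mean +
    climate$amplitude * cos(2 * pi * (doy - climate$peak_day) / 365) + t_noise
  moist_c <- pmin(100, pmax(
    0, moisture_params$base[season] + m_noise))
  gpp_c <- pmax(0, gpp_params$mean +
                  gpp_params$amplitude *
                  cos(2 * pi * (doy - gpp_params$peak_day) / 365) + g_noise)

  control <- tibble::tibble(
    date = dates, doy = doy, month = month, treatment = "control",
    temperature = temp_c, moisture = as.numeric(moist_c), gpp = gpp_c)
  warmed <- control |>
    dplyr::mutate(
      treatment = "warmed",
      temperature = .data$temperature + unname(warming_offsets[season]),
      moisture = pmin(100, pmax(
        0, .data$moisture * unname(moisture_params$warming_factor[season]))))

  out <- dplyr::bind_rows(control, warmed)
  class(out) <- c("forcing_series", class(out))
  out
}

#' Monthly aggregation of a daily forcing series
#'
#' @param forcing A tibble from [gen_forcing()] (or the same columns).
#' @return A tibble with monthly means per treatment.
#' @export
monthly_forcing <- function(forcing) {
  forcing |>
    dplyr::group_by(.data$treatment, .data$month) |>
    dplyr::summarise(temperature = mean(.data$temperature),
                     moisture = mean(.data$moisture),
                     gpp = mean(.data$gpp), .groups = "drop")
}
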