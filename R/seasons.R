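#' Fit a smooth annual curve to twelve monthly temperatures
#'
#' Fits the smooth annual temperature curve from which season boundaries
#' are read off via the first derivative. The default is a natural
#' interpolating spline, which tracks the monthly series locally so the
#' derivative extrema fall at the sharpest month-to-month transitions; a
#' single global degree-5 least-squares polynomial is available as
#' `method = "polynomial"`. The global polynomial oversmooths sharp
#' seasonal transitions and its derivative is edge-dominated on realistic
#' mid-latitude climatologies, which is why the spline is the default (see
#' the methods vignette).
#'
#' @param monthly_temperature Exactly 12 finite values (degC), January to
#'   December.
#' @param method `"spline"` (default) or `"polynomial"`.
#' @return An `annual_curve` object: an evaluator `f(m)`, a derivative
#'   `df(m)`, fitted values, residuals, polynomial coefficients (ascending
#'   powers; `NULL` for the spline), and a `degenerate` flag (constant
#'   input). Fewer than 7 distinct values sets the `underdetermined` flag.
#' @examples
#' cv <- fit_annual_curve(15 - 12 * cos(2 * pi * (1:12 - 1) / 12))
#' cv$df(4) # temperature change rate around April
#' @export
fit_annual_curve <- function(monthly_temperature,
                             method = c("spline", "polynomial")) {
  method <- match.arg(method)
  y <- as.numeric(monthly_temperature)
  if (length(y) != 12 || !all(is.finite(y)))
    stop("need exactly 12 finite monthly temperatures", call. = FALSE)
  m <- 1:12
  degenerate <- isTRUE(all.equal(max(y), min(y)))
  underdetermined <- length(unique(y)) < 7
  if (method == "polynomial") {
    fit <- lm(y ~ poly(m, 5, raw = TRUE))
    cf <- unname(coef(fit))
    cf[is.na(cf)] <- 0
    f <- function(x) drop(outer(x, 0:5, "^") %*% cf)
    dcf <- cf[-1] * (1:5)
    df <- function(x) drop(outer(x, 0:4, "^") %*% dcf)
  } else {
    cf <- NULL
    sf <- stats::splinefun(m, y, method = "natural")
    f <- function(x) sf(x)
    df <- function(x) sf(x, deriv = 1)
  }
  structure(
    list(method = method, coefficients = cf, fitted = f(m),
         residuals = y - f(m), f = f, df = df, degenerate = degenerate,
         underdetermined = underdetermined, input = y),
    class = "annual_curve")
}

#' @export
print.annual_curve <- function(x, ...) {
  cat("Degree-5 annual temperature curve",
      if (x$degenerate) "(degenerate: constant input)", "\n")
  cat("  RMS residual:", signif(sqrt(mean(x$residuals^2)), 3), "degC\n")
  invisible(x)
}

#' Derive the cool/warm season partition from an annual curve
#'
#' Locates the fastest temperature rise (maximum of the first derivative)
#' and fastest fall (minimum) on a dense grid, rounds each to the nearest
#' month boundary, and labels months before the rise "early_cool", months
#' from the rise through the fall "warm", and months after the fall
#' "late_cool".
#'
#' @param curve An [fit_annual_curve()] object (non-degenerate).
#' @param grid_step Grid spacing in months for locating the derivative
#'   extrema. Default 0.01.
#' @return A `season_partition` object: tibble `month`/`season`, plus
#'   `rise_interval` and `fall_interval` (the flanking month pair of each
#'   boundary) and the raw extremum locations.
#' @examples
#' temps <- c(3.5, 5, 12.5, 17, 21, 25.5, 28.1, 27, 23.5, 15.5, 9, 5)
#' derive_partition(fit_annual_curve(temps))
#' @export
derive_partition <- function(curve, grid_step = 0.01) {
  stopifnot(inherits(curve, "annual_curve"))
  if (curve$degenerate)
    stop("cannot partition a degenerate (constant) annual curve",
         call. = FALSE)
  g <- seq(1, 12, by = grid_step)
  d <- curve$df(g)
  rise_at <- g[which.max(d)]
  fall_at <- g[which.min(d)]
  if (fall_at <= rise_at)
    stop("fitted curve has no rise-then-fall annual structure",
         call. = FALSE)
  # nearest half-integer month boundary: boundary k+0.5 separates k and k+1
  snap <- function(x) min(11.5, max(1.5, round(x - 0.5) + 0.5))
  rb <- snap(rise_at)
  fb <- snap(fall_at)
  season <- dplyr::case_when(
    1:12 < rb ~ "early_cool",
    1:12 < fb ~ "warm",
    TRUE ~ "late_cool")
  structure(
    list(table = tibble::tibble(month = 1:12, season = season),
         rise_interval = c(rb - 0.5, rb + 0.5),
         fall_interval = c(fb - 0.5, fb + 0.5),
         rise_at = rise_at, fall_at = fall_at),
    class = "season_partition")
}

#' @export
print.season_partition <- function(x, ...) {
  spans <- split(x$table$month, x$table$season)
  cat("Season partition (fastest rise between months",
      paste(x$rise_interval, collapse = " and "), "| fastest fall between",
      paste(x$fall_interval, collapse = " and "), ")\n")
  for (s in c("early_cool", "warm", "late_cool"))
    cat(sprintf("  %-10s %s\n", s,
                paste(month.abb[spans[[s]]], collapse = " ")))
  invisible(x)
}

#' Site-like monthly air temperature climatology
#'
#' A synthetic 12-value monthly mean air temperature series for a southern
#' Great Plains mixed-grass prairie: coldest in January (3.5 degC), warmest
#' in July (28.1 degC), with the sharpest month-to-month rise between
#' February and March and the sharpest fall between September and October.
#' Used as the default input to the season segmentation.
#'
#' @return Named numeric vector of 12 monthly means (degC).
#' @export
site_climatology <- function() {
  setNames(c(3.5, 5.0, 12.5, 17.0, 21.0, 25.5, 28.1, 27.0, 23.5,
             15.5, 9.0, 5.0), month.abb)
}
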