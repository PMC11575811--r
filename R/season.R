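#' Pollen season by the cumulative-percentage method
#'
#' Defines the pollen season of a calendar year as the period between the
#' day on which the cumulative annual sum first reaches `(100 - coverage)/2`
#' percent of the annual total and the day on which it first reaches
#' `100 - (100 - coverage)/2` percent. With the default `coverage = 95`
#' this is the common "95-percentage" definition (start at 2.5%, end at
#' 97.5%). Thresholds are inclusive (`>=`). Missing days count as zero for
#' the cumulative sum.
#'
#' @param series a [pollen_series] covering the full calendar `year`.
#' @param year calendar year to analyse.
#' @param coverage central mass of the annual total enclosed by the season,
#'   in percent (0 < coverage <= 100).
#' @return A [season_window].
#' @examples
#' d <- seq(as.Date("2022-01-01"), as.Date("2022-12-31"), by = "day")
#' v <- numeric(length(d)); v[100:199] <- 1
#' season_bounds(pollen_series(d, v), 2022)
#' @export
season_bounds <- function(series, year, coverage = 95) {
  stopifnot(inherits(series, "pollen_series"))
  if (coverage <= 0 || coverage > 100)
    stop("'coverage' must be in (0, 100]")
  y0 <- as.Date(sprintf("%d-01-01", year))
  y1 <- as.Date(sprintf("%d-12-31", year))
  if (y0 < series$dates[1L] || y1 > series$dates[length(series$dates)])
    stop("series does not cover the full calendar year ", year)
  keep <- series$dates >= y0 & series$dates <= y1
  dates <- series$dates[keep]
  vals <- series$values[keep]
  vals[is.na(vals)] <- 0
  total <- sum(vals)
  if (total <= 0)
    stop("annual total is zero: no season definable for ", year)
  cum <- cumsum(vals)
  tail_pct <- (100 - coverage) / 2
  lo <- total * tail_pct / 100
  hi <- total * (100 - tail_pct) / 100
  start <- if (lo > 0) dates[which(cum >= lo)[1L]] else dates[which(cum > 0)[1L]]
  end <- dates[which(cum >= hi)[1L]]
  season_window(start, end)
}

#' Descriptive statistics of a pollen season
#'
#' Mean, sample standard deviation, coefficient of variation
#' (CV = SD/mean x 100), quartiles (linear interpolation between order
#' statistics), maximum and season duration for the values of `series`
#' inside `window`. Missing days are excluded from the statistics; the
#' duration comes from the window itself.
#'
#' @param series a [pollen_series].
#' @param window a [season_window] within the series, holding at least two
#'   present values.
#' @return A one-row `data.frame` with columns `mean`, `sd`, `cv`, `q1`,
#'   `median`, `q3`, `max` (p/m^3; `cv` in percent) and `duration` (days).
#' @export
descriptive_stats <- function(series, window) {
  vals <- align_to_window(series, window)
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L)
    stop("need at least two present values in the window")
  m <- mean(vals)
  s <- stats::sd(vals)
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(
    mean = m, sd = s,
    cv = if (m > 0) s / m * 100 else NA_real_,
    q1 = q[1L], median = q[2L], q3 = q[3L], max = max(vals),
    duration = window$duration
  )
}

#' Variation Index of day-to-day pollen variability
#'
#' For every pair of consecutive days in the window with both values
#' present, the two-value mean and sample standard deviation
#' (`|a - b|/sqrt(2)`) give a moving coefficient of variation; the
#' Variation Index (VIn) is the average of these moving CVs over the
#' window, in percent. Pairs with a missing member or with mean zero are
#' excluded from the average (the CV is undefined at mean zero). VIn is
#' scale-free: multiplying the series by any positive constant leaves it
#' unchanged.
#'
#' @param series a [pollen_series].
#' @param window a [season_window] within the series.
#' @return VIn in percent (a single number).
#' @examples
#' d <- seq(as.Date("2022-01-01"), by = "day", length.out = 3)
#' s <- pollen_series(d, c(2, 2, 4))
#' variation_index(s, season_window(d[1], d[3]))  # 23.57
#' @export
variation_index <- function(series, window) {
  vals <- align_to_window(series, window)
  if (length(vals) < 2L)
    stop("window must span at least two days")
  a <- vals[-length(vals)]
  b <- vals[-1L]
  m <- (a + b) / 2
  s <- abs(a - b) / sqrt(2)  # sample SD of two values
  ok <- !is.na(m) & m > 0
  if (!any(ok))
    stop("no consecutive-day pair with positive mean: VIn undefined")
  mean(s[ok] / m[ok]) * 100
}
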