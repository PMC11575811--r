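#' Daily pollen concentration series
#'
#' A `pollen_series` holds daily airborne pollen concentrations (pollen
#' grains per cubic metre of air, p/m^3) for one monitoring station and one
#' taxon, on a gap-free consecutive calendar-day axis. Days without a
#' measurement carry `NA`; the date axis itself never has holes, so runs of
#' consecutive missing days ("gaps") are well defined.
#'
#' @param dates `Date` vector, strictly increasing with a step of exactly
#'   one day.
#' @param values numeric vector of concentrations, same length as `dates`;
#'   each non-missing value must be >= 0.
#' @param station_id,taxon single strings identifying the series.
#'
#' @return An object of class `pollen_series`: a list with elements
#'   `station_id`, `taxon`, `dates`, `values`.
#' @examples
#' d <- seq(as.Date("2022-01-01"), by = "day", length.out = 5)
#' pollen_series(d, c(1, 2, NA, 4, 5), "ST1", "Alnus")
#' @export
pollen_series <- function(dates, values, station_id = "station", taxon = "taxon") {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("'dates' and 'values' must have the same length")
  if (length(dates) == 0L)
    stop("a pollen series needs at least one day")
  if (anyNA(dates))
    stop("'dates' must not contain NA")
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("'dates' must be strictly increasing consecutive calendar days")
  if (any(values < 0, na.rm = TRUE))
    stop("concentrations must be nonnegative")
  structure(
    list(station_id = as.character(station_id)[1L],
         taxon = as.character(taxon)[1L],
         dates = dates, values = values),
    class = "pollen_series"
  )
}

#' @export
print.pollen_series <- function(x, ...) {
  n <- length(x$dates)
  n_na <- sum(is.na(x$values))
  cat(sprintf("<pollen_series> %s / %s\n", x$station_id, x$taxon))
  cat(sprintf("  %d days: %s to %s (%d missing)\n",
              n, format(x$dates[1L]), format(x$dates[n]), n_na))
  invisible(x)
}

#' @export
length.pollen_series <- function(x) length(x$values)

#' @export
as.data.frame.pollen_series <- function(x, ...) {
  data.frame(date = x$dates, station = x$station_id, taxon = x$taxon,
             concentration = x$values, stringsAsFactors = FALSE)
}

#' Calendar window of a pollen season or imputation period
#'
#' @param start_date,end_date first and last calendar day (inclusive);
#'   `start_date <= end_date`.
#' @return An object of class `season_window` with elements `start_date`,
#'   `end_date` and `duration` (days, inclusive of both ends).
#' @examples
#' season_window("2022-01-01", "2022-05-31")  # duration 151
#' @export
season_window <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date))
    stop("window dates must be valid calendar days")
  if (start_date > end_date)
    stop("'start_date' must not be after 'end_date'")
  structure(
    list(start_date = start_date, end_date = end_date,
         duration = as.integer(end_date - start_date) + 1L),
    class = "season_window"
  )
}

#' @export
print.season_window <- function(x, ...) {
  cat(sprintf("<season_window> %s to %s (%d days)\n",
              format(x$start_date), format(x$end_date), x$duration))
  invisible(x)
}

#' Read daily concentration tables into pollen series
#'
#' Reads a delimited text file with columns `date`, `station`, `taxon`,
#' `concentration` (ISO-8601 dates; missing concentrations as empty fields
#' or `NA`) and returns one [pollen_series] per (station, taxon). Calendar
#' days absent from the file are materialised as `NA` so every series has a
#' gap-free consecutive day axis. Rows with negative concentrations are
#' rejected with a warning; duplicate (date, station, taxon) rows are an
#' error.
#'
#' @param path file path (or connection) of the delimited table.
#' @param sep field separator, comma by default.
#' @return Named list of `pollen_series`, names `"<station>/<taxon>"`.
#' @seealso [write_pollen_csv()] for the inverse operation.
#' @export
read_pollen_csv <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = c(NA, "character", "character", NA))
  need <- c("date", "station", "taxon", "concentration")
  if (!all(need %in% names(df)))
    stop("input must have columns: ", paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  if (anyNA(df$date))
    stop("unparseable dates in input (expecting ISO-8601)")
  df$concentration <- as.numeric(df$concentration)
  bad <- !is.na(df$concentration) & df$concentration < 0
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with negative concentration", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  key <- paste(df$date, df$station, df$taxon, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (date, station, taxon) rows in input")
  out <- list()
  for (grp in split(df, paste(df$station, df$taxon, sep = "/"))) {
    days <- seq(min(grp$date), max(grp$date), by = "day")
    vals <- rep(NA_real_, length(days))
    vals[match(grp$date, days)] <- grp$concentration
    s <- pollen_series(days, vals, grp$station[1L], grp$taxon[1L])
    out[[paste(s$station_id, s$taxon, sep = "/")]] <- s
  }
  out[order(names(out))]
}

#' Write pollen series to a delimited text table
#'
#' @param series a `pollen_series` or a list of them.
#' @param path output file path.
#' @param sep field separator, comma by default.
#' @return `path`, invisibly.
#' @export
write_pollen_csv <- function(series, path, sep = ",") {
  if (inherits(series, "pollen_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  df <- df[order(df$station, df$taxon, df$date), , drop = FALSE]
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Extract the values of a series over a calendar window
#'
#' Returns the concentration vector over `window`, in day order. When the
#' window contains February 29 and `drop_leap_day` is set, that day is
#' removed so that the same calendar window has identical length in leap
#' and non-leap years — a requirement for stacking yearly columns into the
#' rectangular matrix used by [gappy_svd()].
#'
#' @param series a [pollen_series].
#' @param window a [season_window] lying within the series' date range.
#' @param drop_leap_day drop Feb 29 if the window contains it (default
#'   `FALSE`).
#' @return Numeric vector of length `window$duration` (minus one when a
#'   Feb 29 is dropped).
#' @export
align_to_window <- function(series, window, drop_leap_day = FALSE) {
  stopifnot(inherits(series, "pollen_series"), inherits(window, "season_window"))
  if (window$start_date < series$dates[1L] ||
      window$end_date > series$dates[length(series$dates)])
    stop("window lies outside the series' date range")
  keep <- series$dates >= window$start_date & series$dates <= window$end_date
  dates <- series$dates[keep]
  vals <- series$values[keep]
  if (drop_leap_day) {
    feb29 <- format(dates, "%m-%d") == "02-29"
    vals <- vals[!feb29]
  }
  vals
}
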