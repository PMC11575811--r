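# shared builders for tests

days_from <- function(start, n) seq(as.Date(start), by = "day", length.out = n)

toy_series <- function(values, start = "2022-01-01", station = "S", taxon = "T") {
  pollen_series(days_from(start, length(values)), values, station, taxon)
}

# full-calendar-year series with mass on given days of year
year_series <- function(year, mass_days, mass_values = 1, station = "S", taxon = "T") {
  d <- seq(as.Date(sprintf("%d-01-01", year)), as.Date(sprintf("%d-12-31", year)),
           by = "day")
  v <- numeric(length(d))
  v[mass_days] <- mass_values
  pollen_series(d, v, station, taxon)
}

# the published 24-cell scenario table: a 151-day window (short spring
# taxon) and a 214-day window (long summer taxon), three missing-data
# proportions by four gap lengths each
scenario_table <- function() {
  tab <- rbind(
    # season_len, prop, gap_len, n_gaps, total, pct
    c(151, 0.05,  3,  3,  9,  6.0),
    c(151, 0.05,  5,  2, 10,  6.6),
    c(151, 0.05,  7,  1,  7,  4.6),
    c(151, 0.05, 10,  1, 10,  6.6),
    c(151, 0.10,  3,  5, 15,  9.9),
    c(151, 0.10,  5,  3, 15,  9.9),
    c(151, 0.10,  7,  2, 14,  9.3),
    c(151, 0.10, 10,  2, 20, 13.2),
    c(151, 0.25,  3, 13, 39, 25.8),
    c(151, 0.25,  5,  8, 40, 26.5),
    c(151, 0.25,  7,  5, 35, 23.2),
    c(151, 0.25, 10,  4, 40, 26.5),
    c(214, 0.05,  3,  4, 12,  5.6),
    c(214, 0.05,  5,  2, 10,  4.7),
    c(214, 0.05,  7,  2, 14,  6.5),
    c(214, 0.05, 10,  1, 10,  4.7),
    c(214, 0.10,  3,  7, 21,  9.8),
    c(214, 0.10,  5,  4, 20,  9.3),
    c(214, 0.10,  7,  3, 21,  9.8),
    c(214, 0.10, 10,  2, 20,  9.3),
    c(214, 0.25,  3, 18, 54, 25.2),
    c(214, 0.25,  5, 11, 55, 25.7),
    c(214, 0.25,  7,  8, 56, 26.2),
    c(214, 0.25, 10,  5, 50, 23.4))
  colnames(tab) <- c("season_len", "prop", "gap_len", "n_gaps", "total", "pct")
  as.data.frame(tab)
}

# exact rank-1 nonnegative matrix from two positive smooth vectors
rank1_matrix <- function(nrow = 20, ncol = 8) {
  u <- sin(seq(0.1, pi - 0.1, length.out = nrow))^2 + 0.1
  w <- seq(1, 3, length.out = ncol)
  outer(u, w)
}
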