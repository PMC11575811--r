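#' Moving-mean gap interpolation
#'
#' Fills each run of consecutive missing days by averaging the observed
#' values in a symmetric window around every missing day, the window sized
#' relative to the length of the run it belongs to: for a run of length L
#' and window factor f, day i is imputed as the mean of the observed values
#' on days `[i - ceiling(f*L), i + ceiling(f*L)]` (truncated at the series
#' edges), i.e. a window twice the gap length plus the day itself at the
#' default `factor = 1`. When that window holds no observed value the
#' half-width is doubled until it does. Only originally observed values
#' feed the averages; observed days are never modified.
#'
#' @param series a [pollen_series] with at least one present value.
#' @param factor window half-width as a multiple of the gap length.
#' @return A [pollen_series] with every missing day filled.
#' @examples
#' d <- seq(as.Date("2022-01-01"), by = "day", length.out = 5)
#' s <- pollen_series(d, c(1, 2, NA, 4, 5))
#' impute_moving_mean(s)$values  # third day becomes mean(2, 4) = 3
#' @export
impute_moving_mean <- function(series, factor = 1) {
  stopifnot(inherits(series, "pollen_series"))
  v <- series$values
  obs <- !is.na(v)
  if (!any(obs)) stop("cannot impute a fully missing series")
  if (all(obs)) return(series)
  n <- length(v)
  out <- v
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    L <- r$lengths[k]
    for (i in starts[k]:ends[k]) {
      w <- ceiling(factor * L)
      repeat {
        lo <- max(1L, i - w)
        hi <- min(n, i + w)
        idx <- lo:hi
        present <- idx[obs[idx]]
        if (length(present) > 0L) break
        w <- 2L * w
      }
      out[i] <- mean(v[present])
    }
  }
  pollen_series(series$dates, out, series$station_id, series$taxon)
}
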