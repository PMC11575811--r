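#' Plan the number of gap runs for a missingness scenario
#'
#' Turns a (season length, target missing proportion, gap length) triple
#' into a concrete scenario: the unrounded target number of missing days is
#' `na_prop * season_len`; the number of gap runs is that target divided by
#' the gap length, rounded (half away from zero by default) and floored at
#' one so every scenario removes at least one run.
#'
#' @param season_len length of the imputation window, days.
#' @param na_prop target proportion of missing days, in (0, 1).
#' @param gap_len length of each run of consecutive missing days.
#' @param rounding how `target_days / gap_len` becomes an integer count:
#'   `"half-away"` (default) or `"half-even"` (banker's rounding, base
#'   `round`).
#' @return An object of class `gap_plan`: list with `season_len`,
#'   `na_prop`, `gap_len`, `target_days` (unrounded), `n_gaps`,
#'   `total_na_days` (`n_gaps * gap_len`) and `resulting_pct`
#'   (`total_na_days / season_len * 100`).
#' @examples
#' plan_gaps(151, 0.05, 3)   # 3 gaps, 9 days, 6.0%
#' plan_gaps(214, 0.25, 7)   # 8 gaps, 56 days, 26.2%
#' @export
plan_gaps <- function(season_len, na_prop, gap_len,
                      rounding = c("half-away", "half-even")) {
  rounding <- match.arg(rounding)
  if (na_prop <= 0 || na_prop >= 1) stop("'na_prop' must be in (0, 1)")
  if (gap_len < 1) stop("'gap_len' must be >= 1")
  if (season_len < gap_len) stop("'season_len' must be >= 'gap_len'")
  target <- na_prop * season_len
  ratio <- target / gap_len
  n_gaps <- switch(rounding,
                   "half-away" = floor(ratio + 0.5),  # ratio > 0 always
                   "half-even" = round(ratio))
  n_gaps <- max(1L, as.integer(n_gaps))
  total <- n_gaps * as.integer(gap_len)
  if (total > season_len)
    stop(sprintf("infeasible scenario: %d gaps of %d days exceed a %d-day window",
                 n_gaps, gap_len, season_len))
  structure(
    list(season_len = as.integer(season_len), na_prop = na_prop,
         gap_len = as.integer(gap_len), target_days = target,
         n_gaps = n_gaps, total_na_days = total,
         resulting_pct = total / season_len * 100),
    class = "gap_plan"
  )
}

#' @export
print.gap_plan <- function(x, ...) {
  cat(sprintf(
    "<gap_plan> %d-day window, %.0f%% target (%.2f days): %d gap(s) of %d days = %d days (%.1f%%)\n",
    x$season_len, 100 * x$na_prop, x$target_days, x$n_gaps, x$gap_len,
    x$total_na_days, x$resulting_pct))
  invisible(x)
}

#' Place gap runs at random positions in a window
#'
#' Draws a boolean missingness mask with exactly `plan$n_gaps` runs of
#' exactly `plan$gap_len` consecutive `TRUE` days, uniformly over all valid
#' configurations. By default runs must be separated by at least one
#' observed day (`min_sep = 1`), so every realised missing run has length
#' exactly `gap_len` and runs never merge; `min_sep = 0` allows touching
#' (but never overlapping) runs. Sampling uses the stars-and-bars bijection
#' between configurations and compositions of the slack days, so it is
#' exactly uniform and always terminates.
#'
#' @param season_len window length in days.
#' @param plan a [gap_plan].
#' @param seed integer seed; the same (plan, seed) always yields the same
#'   mask.
#' @param min_sep minimum number of observed days between consecutive runs.
#' @return Logical vector of length `season_len`; `TRUE` marks a removed
#'   day.
#' @export
place_gaps <- function(season_len, plan, seed, min_sep = 1L) {
  stopifnot(inherits(plan, "gap_plan"))
  n <- plan$n_gaps
  L <- plan$gap_len
  slack <- season_len - n * L - (n - 1L) * min_sep
  if (slack < 0)
    stop(sprintf("cannot place %d runs of %d days (min_sep %d) in %d days",
                 n, L, min_sep, season_len))
  # compositions of `slack` into n+1 nonnegative parts <-> n-subsets of
  # 1..(slack+n); uniform over subsets gives uniform over configurations
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cut <- sort(sample.int(slack + n, n))
  before <- c(cut[1L] - 1L, diff(cut) - 1L)  # slack before each run
  starts <- cumsum(before) + (seq_len(n) - 1L) * (L + min_sep) + 1L
  mask <- rep(FALSE, season_len)
  for (s in starts) mask[s:(s + L - 1L)] <- TRUE
  mask
}

#' Build the full simulation scenario grid
#'
#' Expands units (pollen x station combinations) against missing-data
#' proportions, gap lengths and replicates, planning each cell with
#' [plan_gaps()] and deriving one reproducible placement seed per
#' replicate from `master_seed`.
#'
#' @param units `data.frame` with columns `pollen`, `station` and
#'   `season_len` (the imputation-window length for that unit, days).
#' @param props missing-data proportions (fractions in (0,1)).
#' @param lens gap lengths in days.
#' @param reps number of replicate masks per scenario cell.
#' @param master_seed single integer governing all placement seeds.
#' @return `data.frame` with one row per (unit, proportion, gap length,
#'   replicate): columns `pollen`, `station`, `season_len`, `na_prop`,
#'   `gap_len`, `n_gaps`, `total_na_days`, `resulting_pct`, `replicate`,
#'   `seed`.
#' @examples
#' u <- data.frame(pollen = "Alnus", station = "ST1", season_len = 151)
#' nrow(build_scenarios(u, reps = 2))  # 12 cells x 2 reps
#' @export
build_scenarios <- function(units, props = c(0.05, 0.10, 0.25),
                            lens = c(3L, 5L, 7L, 10L), reps = 100L,
                            master_seed = 1L) {
  stopifnot(all(c("pollen", "station", "season_len") %in% names(units)))
  cells <- expand.grid(unit = seq_len(nrow(units)), na_prop = props,
                       gap_len = lens, KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$unit, cells$na_prop, cells$gap_len), , drop = FALSE]
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, nrow(cells) * reps)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    u <- cells$unit[i]
    p <- plan_gaps(units$season_len[u], cells$na_prop[i], cells$gap_len[i])
    rows[[i]] <- data.frame(
      pollen = units$pollen[u], station = units$station[u],
      season_len = p$season_len, na_prop = p$na_prop, gap_len = p$gap_len,
      n_gaps = p$n_gaps, total_na_days = p$total_na_days,
      resulting_pct = p$resulting_pct, replicate = seq_len(reps),
      seed = seeds[(i - 1L) * reps + seq_len(reps)],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
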