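#' Configuration of a full imputation simulation study
#'
#' Bundles everything [run_study()] needs: the dataset (a named list of
#' complete multi-year [pollen_series], e.g. from [make_study_fixture()] or
#' [read_pollen_csv()]), the target year whose season is degraded and
#' re-imputed, the per-taxon imputation windows, the scenario grid and the
#' methods to compare.
#'
#' @param dataset named list of [pollen_series], each covering the target
#'   year and the historical years.
#' @param target_year the year whose (complete) data are degraded.
#' @param windows named list mapping each taxon in `dataset` to
#'   `c(start, end)` month-day strings (`"MM-DD"`) delimiting its
#'   imputation window; the default covers the two synthetic profiles —
#'   a 151-day window (01 Jan - 31 May) for the short early taxon and a
#'   214-day window (01 Apr - 31 Oct) for the long summer taxon.
#' @param props missing-data proportions.
#' @param lens gap lengths in days.
#' @param reps replicate masks per scenario cell.
#' @param methods named list of method specifications; each element is
#'   `list(type = "movingmean")` or
#'   `list(type = "gsvd", n_modes = <int>, init = "mean"|"linear")`. The
#'   default is the three-method comparison: moving mean, GSVD with mean
#'   initialisation and 5 modes, GSVD with linear-interpolation
#'   initialisation and 10 modes.
#' @param gsvd_scope how the GSVD matrix is assembled per scenario cell.
#'   `"per_replicate"` (default) imputes each gappy series against the
#'   historical yearly columns only — the situation a practitioner faces:
#'   one incomplete year plus the station's record. `"pooled"` stacks all
#'   replicate columns of the cell into one wide matrix (optionally with
#'   the complete target-year column); because the replicates are copies of
#'   the same truth degraded at different positions, the pooled matrix lets
#'   the withheld values leak back through the column consensus and drives
#'   the apparent error to numerical noise — it is provided to reproduce
#'   that design, not recommended for method comparison.
#' @param include_reference_year keep the complete target-year column in
#'   the GSVD matrix (see [assemble_matrix()] for the leakage caveat).
#'   Default `FALSE`.
#' @param gap_only_rmse average squared errors over removed days only
#'   instead of the whole window.
#' @param tol,max_iter GSVD convergence settings.
#' @param master_seed single integer seed for the whole study.
#' @return A list of class `study_config`.
#' @export
study_config <- function(dataset, target_year = 2022,
                         windows = list(
                           alnus_like = c("01-01", "05-31"),
                           poaceae_like = c("04-01", "10-31")),
                         props = c(0.05, 0.10, 0.25),
                         lens = c(3L, 5L, 7L, 10L),
                         reps = 100L,
                         methods = list(
                           movingmean = list(type = "movingmean"),
                           gsvd_mean_5m = list(type = "gsvd", n_modes = 5L,
                                               init = "mean"),
                           gsvd_interp_10m = list(type = "gsvd", n_modes = 10L,
                                                  init = "linear")),
                         gsvd_scope = c("per_replicate", "pooled"),
                         include_reference_year = FALSE,
                         gap_only_rmse = FALSE,
                         tol = 1e-6, max_iter = 1000L,
                         master_seed = 1L) {
  gsvd_scope <- match.arg(gsvd_scope)
  stopifnot(length(dataset) >= 1L, reps >= 1L)
  for (s in dataset) stopifnot(inherits(s, "pollen_series"))
  taxa <- unique(vapply(dataset, function(s) s$taxon, ""))
  missing_win <- setdiff(taxa, names(windows))
  if (length(missing_win))
    stop("no imputation window for taxa: ", paste(missing_win, collapse = ", "))
  for (m in methods)
    if (!m$type %in% c("movingmean", "gsvd"))
      stop("unknown method type: ", m$type)
  structure(
    list(dataset = dataset, target_year = target_year, windows = windows,
         props = props, lens = lens, reps = as.integer(reps),
         methods = methods, gsvd_scope = gsvd_scope,
         include_reference_year = include_reference_year,
         gap_only_rmse = gap_only_rmse, tol = tol,
         max_iter = as.integer(max_iter), master_seed = master_seed),
    class = "study_config"
  )
}

#' Run the full imputation simulation study
#'
#' For every series in the dataset: aligns the complete target-year window
#' and the historical yearly columns (Feb 29 dropped so all columns have
#' equal length); plans and places the gap scenarios; imputes every
#' replicate with each configured method — moving mean on the gappy series
#' alone, Gappy-SVD on the matrix of historical years plus all replicate
#' columns of the scenario; and scores each replicate by RMSE against the
#' withheld truth. It then computes per-cell median RMSEs, the target-year
#' season statistics and Variation Index per series, and the stratified
#' log-RMSE regression with robust standard errors.
#'
#' Everything is driven by `config$master_seed`, so two runs with the same
#' configuration produce identical results, byte for byte.
#'
#' @param config a [study_config].
#' @param out_dir optional directory; when given, `scenarios.csv`,
#'   `records.csv`, `medians.csv`, `effects.csv`, `season_stats.csv` and
#'   `convergence.csv` are written there.
#' @return A list of class `study_result` with elements `records`
#'   (replicate-level RMSE rows), `medians` (per-cell medians),
#'   `scenarios` (the realised grid), `season_stats` (per-series
#'   descriptives plus VIn over the target-year season), `effects` (one
#'   [fit_error_model()] object per stratum, when estimable) and
#'   `convergence` (GSVD iteration diagnostics per scenario cell).
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  ds <- config$dataset
  units <- data.frame(
    pollen = vapply(ds, function(s) s$taxon, ""),
    station = vapply(ds, function(s) s$station_id, ""),
    stringsAsFactors = FALSE
  )
  yr <- config$target_year
  target_windows <- lapply(units$pollen, function(tx) {
    md <- config$windows[[tx]]
    season_window(sprintf("%d-%s", yr, md[1L]), sprintf("%d-%s", yr, md[2L]))
  })
  # effective column length: calendar duration minus a dropped Feb 29
  col_len <- function(w) {
    days <- seq(w$start_date, w$end_date, by = "day")
    sum(format(days, "%m-%d") != "02-29")
  }
  units$season_len <- vapply(target_windows, col_len, 0L)

  truth <- vector("list", nrow(units))
  hist_cols <- vector("list", nrow(units))
  for (u in seq_len(nrow(units))) {
    s <- ds[[u]]
    tw <- target_windows[[u]]
    tv <- align_to_window(s, tw, drop_leap_day = TRUE)
    if (anyNA(tv))
      stop(sprintf("target year %d is incomplete for %s/%s",
                   yr, units$station[u], units$pollen[u]))
    truth[[u]] <- tv
    md <- config$windows[[units$pollen[u]]]
    yrs <- sort(unique(as.integer(format(s$dates, "%Y"))))
    yrs <- setdiff(yrs, yr)
    cols <- list()
    for (y in yrs) {
      w <- season_window(sprintf("%d-%s", y, md[1L]), sprintf("%d-%s", y, md[2L]))
      if (w$start_date < s$dates[1L] || w$end_date > s$dates[length(s$dates)]) next
      cols[[as.character(y)]] <- align_to_window(s, w, drop_leap_day = TRUE)
    }
    hist_cols[[u]] <- cols
  }

  scen <- build_scenarios(units, props = config$props, lens = config$lens,
                          reps = config$reps, master_seed = config$master_seed)
  cell_key <- c("pollen", "station", "na_prop", "gap_len")

  records <- list()
  convergence <- list()
  for (u in seq_len(nrow(units))) {
    ukey <- scen$pollen == units$pollen[u] & scen$station == units$station[u]
    uscen <- scen[ukey, , drop = FALSE]
    n_days <- units$season_len[u]
    tv <- truth[[u]]
    axis <- seq(as.Date("2001-01-01"), by = "day", length.out = n_days)
    for (cell in split(uscen, uscen[, c("na_prop", "gap_len")], drop = TRUE)) {
      plan <- plan_gaps(n_days, cell$na_prop[1L], cell$gap_len[1L])
      masks <- lapply(cell$seed, function(sd) place_gaps(n_days, plan, sd))
      gappy <- lapply(masks, function(m) replace(tv, m, NA_real_))
      for (mn in names(config$methods)) {
        m <- config$methods[[mn]]
        if (m$type == "movingmean") {
          preds <- lapply(gappy, function(g) {
            impute_moving_mean(pollen_series(axis, g))$values
          })
        } else if (config$gsvd_scope == "per_replicate") {
          # one matrix per replicate: historical years + the gappy column;
          # the requested mode count is capped below the matrix's full rank
          # (a full-rank truncation would leave the gaps at their initial
          # fill and never exercise the iteration)
          fits <- lapply(gappy, function(g) {
            gm <- assemble_matrix(hist_cols[[u]], list(g), reference = tv,
                                  include_reference_year = config$include_reference_year)
            n_modes <- max(1L, min(m$n_modes, min(dim(gm$values)) - 1L))
            gappy_svd(gm, n_modes = n_modes, init = m$init,
                      tol = config$tol, max_iter = config$max_iter)
          })
          preds <- lapply(fits, function(f) f$completed[, ncol(f$completed)])
          convergence[[length(convergence) + 1L]] <- data.frame(
            pollen = units$pollen[u], station = units$station[u],
            method = mn, na_prop = cell$na_prop[1L],
            gap_len = cell$gap_len[1L],
            n_modes = fits[[1L]]$n_modes, runs = length(fits),
            median_iterations = stats::median(vapply(fits, `[[`, 0L, "iterations")),
            max_final_delta = max(vapply(fits, `[[`, 0, "final_delta")),
            all_converged = all(vapply(fits, `[[`, TRUE, "converged")),
            stringsAsFactors = FALSE)
        } else {
          gm <- assemble_matrix(hist_cols[[u]], gappy, reference = tv,
                                include_reference_year = config$include_reference_year)
          n_modes <- min(m$n_modes, dim(gm$values))
          fit <- gappy_svd(gm, n_modes = n_modes, init = m$init,
                           tol = config$tol, max_iter = config$max_iter)
          rep_cols <- ncol(gm$values) - length(gappy) + seq_along(gappy)
          preds <- lapply(rep_cols, function(j) fit$completed[, j])
          convergence[[length(convergence) + 1L]] <- data.frame(
            pollen = units$pollen[u], station = units$station[u],
            method = mn, na_prop = cell$na_prop[1L],
            gap_len = cell$gap_len[1L], n_modes = n_modes, runs = 1L,
            median_iterations = fit$iterations,
            max_final_delta = fit$final_delta,
            all_converged = fit$converged, stringsAsFactors = FALSE)
        }
        rm_vals <- vapply(seq_along(preds), function(i) {
          rmse(preds[[i]], tv, mask = masks[[i]],
               gap_only = config$gap_only_rmse)
        }, 0)
        records[[length(records) + 1L]] <- data.frame(
          pollen = units$pollen[u], station = units$station[u], method = mn,
          na_prop = cell$na_prop, gap_len = cell$gap_len,
          replicate = cell$replicate, rmse = rm_vals,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  records <- records[order(records$pollen, records$station, records$method,
                           records$na_prop, records$gap_len,
                           records$replicate), , drop = FALSE]
  rownames(records) <- NULL
  convergence <- if (length(convergence)) do.call(rbind, convergence) else NULL

  season_stats <- do.call(rbind, lapply(seq_len(nrow(units)), function(u) {
    s <- ds[[u]]
    sb <- season_bounds(s, yr)
    cbind(data.frame(pollen = units$pollen[u], station = units$station[u],
                     season_start = format(sb$start_date),
                     season_end = format(sb$end_date),
                     stringsAsFactors = FALSE),
          descriptive_stats(s, sb),
          data.frame(vin = variation_index(s, sb)))
  }))

  effects <- list()
  for (u in seq_len(nrow(units))) {
    stratum <- records[records$pollen == units$pollen[u] &
                         records$station == units$station[u], , drop = FALSE]
    key <- paste(units$pollen[u], units$station[u], sep = "/")
    effects[[key]] <- tryCatch(fit_error_model(stratum),
                               error = function(e) NULL)
  }

  out <- structure(
    list(records = records, medians = summarize_rmse(records),
         scenarios = scen, season_stats = season_stats,
         effects = effects, convergence = convergence, config = config),
    class = "study_result"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wr <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
    wr(out$scenarios, "scenarios.csv")
    wr(out$records, "records.csv")
    wr(out$medians, "medians.csv")
    wr(out$season_stats, "season_stats.csv")
    if (!is.null(convergence)) wr(convergence, "convergence.csv")
    eff <- do.call(rbind, lapply(names(effects), function(k) {
      if (is.null(effects[[k]])) return(NULL)
      cbind(stratum = k, effects[[k]]$effects)
    }))
    if (!is.null(eff)) wr(eff, "effects.csv")
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  r <- x$records
  cat("Imputation simulation study\n")
  cat(sprintf("  %d series (pollen x station), %d scenario cells, %d replicates\n",
              length(x$config$dataset),
              nrow(unique(r[c("pollen", "station", "na_prop", "gap_len")])),
              x$config$reps))
  cat(sprintf("  methods: %s\n", paste(unique(r$method), collapse = ", ")))
  cat(sprintf("  %d evaluation records; overall median RMSE %.2f p/m3\n",
              nrow(r), stats::median(r$rmse)))
  invisible(x)
}
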