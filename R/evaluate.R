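#' Root mean square error over an evaluation window
#'
#' `sqrt(mean((predicted - observed)^2))` over all N entries of the window.
#' By convention the denominator is the full window, so days that were
#' never removed contribute zero error; set `gap_only` with a mask to
#' average over the removed days only.
#'
#' @param predicted,observed equal-length numeric vectors without missing
#'   entries.
#' @param mask optional logical vector; when given with
#'   `gap_only = TRUE`, only entries with `mask == TRUE` enter the mean.
#' @param gap_only restrict the average to masked entries.
#' @return RMSE in the units of the data (p/m^3 for concentrations).
#' @examples
#' rmse(c(4, 7), c(1, 3))  # sqrt((9 + 16) / 2)
#' @export
rmse <- function(predicted, observed, mask = NULL, gap_only = FALSE) {
  if (length(predicted) != length(observed))
    stop("'predicted' and 'observed' must have the same length")
  if (anyNA(predicted) || anyNA(observed))
    stop("missing entries are not allowed in RMSE inputs")
  d2 <- (predicted - observed)^2
  if (gap_only) {
    if (is.null(mask)) stop("'gap_only' needs a mask")
    d2 <- d2[mask]
  }
  sqrt(mean(d2))
}

#' Median RMSE per scenario cell
#'
#' Collapses replicate-level evaluation records to the median RMSE for each
#' (pollen, station, method, %NA, gap length) combination — the summary
#' behind the per-method and per-VIn boxplot displays of a simulation
#' study.
#'
#' @param records `data.frame` with columns `pollen`, `station`, `method`,
#'   `na_prop`, `gap_len`, `replicate`, `rmse`.
#' @return `data.frame` with one row per cell and columns `pollen`,
#'   `station`, `method`, `na_prop`, `gap_len`, `n`, `median_rmse`.
#' @export
summarize_rmse <- function(records) {
  need <- c("pollen", "station", "method", "na_prop", "gap_len", "rmse")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(
    records$rmse,
    by = records[c("pollen", "station", "method", "na_prop", "gap_len")],
    FUN = function(z) c(n = length(z), median_rmse = stats::median(z))
  )
  out <- cbind(agg[names(agg) != "x"], as.data.frame(agg$x))
  out$n <- as.integer(out$n)
  out[order(out$pollen, out$station, out$method, out$na_prop, out$gap_len), ,
      drop = FALSE]
}

#' Log-RMSE regression with robust standard errors
#'
#' Fits, for one pollen-by-station stratum, an ordinary least squares model
#' of `log(rmse)` on the imputation method, the missing-data proportion and
#' the gap length, all as unordered categories against the references
#' `movingmean` / 5% / 3 days. Standard errors are heteroskedasticity-
#' consistent (`sandwich::vcovHC`, HC1 by default). Coefficients are
#' reported exponentiated — `Exp(beta)` is the ratio of geometric-mean RMSE
#' versus the reference level — with 95% confidence intervals.
#'
#' @param records `data.frame` of replicate-level records for a single
#'   stratum, with columns `method`, `na_prop`, `gap_len` and `rmse` (all
#'   `rmse > 0`).
#' @param ref_method,ref_prop,ref_len reference levels for the three
#'   covariates.
#' @param hc_type flavour of the heteroskedasticity-consistent covariance
#'   (`"HC1"` default, `"HC3"` the common small-sample alternative).
#' @param conf_level confidence level for the intervals.
#' @return An object of class `error_model`: list with `effects` (a
#'   `data.frame` of `term`, `level`, `exp_beta`, `ci_low`, `ci_high`,
#'   `reference`), the underlying `lm` fit (`fit`), the robust covariance
#'   (`vcov`) and `hc_type`. Reference rows carry `exp_beta = 1` and
#'   `reference = TRUE`.
#' @export
fit_error_model <- function(records, ref_method = "movingmean",
                            ref_prop = NULL, ref_len = NULL,
                            hc_type = c("HC1", "HC3"),
                            conf_level = 0.95) {
  hc_type <- match.arg(hc_type)
  need <- c("method", "na_prop", "gap_len", "rmse")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$rmse <= 0))
    stop("all RMSE values must be positive (log undefined at zero)")
  relevel_to <- function(x, ref) {
    f <- factor(x)
    if (is.null(ref)) ref <- levels(f)[which.min(suppressWarnings(as.numeric(levels(f))))]
    if (!as.character(ref) %in% levels(f))
      stop("reference level '", ref, "' not present in the records")
    stats::relevel(f, ref = as.character(ref))
  }
  df <- data.frame(
    log_rmse = log(records$rmse),
    method = relevel_to(records$method, ref_method),
    na_prop = relevel_to(records$na_prop, ref_prop),
    gap_len = relevel_to(records$gap_len, ref_len)
  )
  keep <- vapply(df[-1L], function(f) nlevels(f) > 1L, TRUE)
  form <- stats::reformulate(names(df)[-1L][keep], response = "log_rmse")
  fit <- stats::lm(form, data = df)
  if (fit$rank < length(stats::coef(fit)) || anyNA(stats::coef(fit)))
    stop("rank-deficient design: covariate levels are confounded")
  vc <- sandwich::vcovHC(fit, type = hc_type)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  ci <- lmtest::coefci(fit, vcov. = vc, level = conf_level)
  rows <- list()
  for (term in c("method", "na_prop", "gap_len")) {
    f <- df[[term]]
    for (lev in levels(f)) {
      cn <- paste0(term, lev)
      is_ref <- lev == levels(f)[1L] || !cn %in% rownames(ct)
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, level = lev,
        exp_beta = if (is_ref) 1 else exp(ct[cn, "Estimate"]),
        ci_low = if (is_ref) 1 else exp(ci[cn, 1L]),
        ci_high = if (is_ref) 1 else exp(ci[cn, 2L]),
        reference = is_ref, stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(effects = do.call(rbind, rows), fit = fit, vcov = vc,
         hc_type = hc_type, conf_level = conf_level, n = nrow(df)),
    class = "error_model"
  )
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("Log-RMSE regression (%d records, %s robust SE)\n",
              x$n, x$hc_type))
  e <- x$effects
  lab <- c(method = "Imputation method", na_prop = "% of NAs",
           gap_len = "Gap length (days)")
  for (term in unique(e$term)) {
    cat(lab[[term]], ":\n", sep = "")
    for (i in which(e$term == term)) {
      if (e$reference[i]) {
        cat(sprintf("  %-16s Ref.\n", e$level[i]))
      } else {
        cat(sprintf("  %-16s %.2f (%.2f-%.2f)\n", e$level[i],
                    e$exp_beta[i], e$ci_low[i], e$ci_high[i]))
      }
    }
  }
  invisible(x)
}

#' @export
coef.error_model <- function(object, ...) {
  stats::setNames(object$effects$exp_beta,
                  paste(object$effects$term, object$effects$level, sep = ""))
}

#' @export
summary.error_model <- function(object, ...) {
  lmtest::coeftest(object$fit, vcov. = object$vcov)
}
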