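#' Initial fill of missing entries in a column
#'
#' Seeds the Gappy-SVD iteration by replacing missing entries of a vector
#' either with the mean of its present entries or by linear interpolation
#' between the nearest present neighbours (flat extension of the nearest
#' present value beyond the first/last observation).
#'
#' @param x numeric vector with `NA` at the entries to fill.
#' @param method `"mean"` or `"linear"`.
#' @return `x` with every `NA` replaced.
#' @export
initial_fill <- function(x, method = c("mean", "linear")) {
  method <- match.arg(method)
  obs <- !is.na(x)
  if (!any(obs)) stop("cannot fill a fully missing column")
  if (all(obs)) return(x)
  if (method == "mean") {
    x[!obs] <- mean(x[obs])
  } else {
    idx <- which(obs)
    x[!obs] <- stats::approx(idx, x[idx], xout = which(!obs),
                             method = "linear", rule = 2)$y
  }
  x
}

#' Assemble the gappy day-by-series matrix
#'
#' Stacks aligned yearly columns (the historical record) and gappy
#' replicate columns into the rectangular matrix handed to [gappy_svd()].
#' Columns are the historical series first — including the complete
#' target-year column only if `include_reference_year` — followed by the
#' replicates. The mask marks every replicate gap and any historically
#' missing entry.
#'
#' @param historical list (or matrix) of equal-length numeric vectors, one
#'   per historical year; `NA` marks historically missing days.
#' @param replicates list (or matrix) of equal-length gappy target-year
#'   vectors; `NA` marks the simulated gaps. May be empty.
#' @param reference complete target-year vector, appended to the historical
#'   block when `include_reference_year = TRUE`; note that keeping the
#'   complete target year in the matrix while imputing its gappy copies
#'   leaks the truth into the reconstruction — set
#'   `include_reference_year = FALSE` for a leakage-free evaluation.
#' @param include_reference_year keep `reference` as a column (default
#'   `TRUE`, mirroring the study design this package reproduces).
#' @return A list of class `gappy_matrix` with elements `values` (matrix,
#'   `NA` at masked entries) and `mask` (logical matrix, `TRUE` = to
#'   impute).
#' @export
assemble_matrix <- function(historical, replicates = list(), reference = NULL,
                            include_reference_year = TRUE) {
  as_cols <- function(x, prefix) {
    if (is.matrix(x)) x <- lapply(seq_len(ncol(x)), function(j) x[, j])
    if (length(x) == 0L) return(NULL)
    lens <- vapply(x, length, 0L)
    if (length(unique(lens)) > 1L) stop("all columns must have the same length")
    m <- do.call(cbind, x)
    if (is.null(colnames(m)) || all(colnames(m) == ""))
      colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    m
  }
  hist <- as_cols(historical, "year")
  if (include_reference_year && !is.null(reference)) {
    if (nrow(hist) != length(reference)) stop("all columns must have the same length")
    hist <- cbind(hist, reference = reference)
  }
  reps <- as_cols(replicates, "rep")
  if (!is.null(reps) && !is.null(hist) && nrow(reps) != nrow(hist))
    stop("all columns must have the same length")
  values <- cbind(hist, reps)
  structure(list(values = values, mask = is.na(values)),
            class = "gappy_matrix")
}

#' Gappy singular value decomposition imputation
#'
#' Fits a low-rank reconstruction of a matrix with missing entries by the
#' iterative Gappy-SVD algorithm: missing entries are seeded by an initial
#' fill ([initial_fill()] per column), then the loop (1) takes the SVD
#' `X = U S V'` of the current filled matrix, (2) truncates it to the first
#' `n_modes` modes, `X* = U* S* V*'`, and (3) replaces the missing entries
#' of `X` by the corresponding entries of `X*`, until the mean squared
#' change of the imputed entries between successive iterations falls below
#' `tol` (or `max_iter` is reached, in which case the fit is flagged as not
#' converged rather than erroring). Observed entries are never altered.
#' Because the data are concentrations, imputed values are clipped at zero
#' after convergence (`clip_negative = FALSE` disables this).
#'
#' The first few modes carry the dominant structure shared across columns
#' (the seasonal pattern and its year-to-year modulation); later modes fit
#' noise and the initial guess, so `n_modes` acts as a noise filter as much
#' as a rank constraint.
#'
#' @param x numeric matrix, or a `gappy_matrix` from [assemble_matrix()].
#'   `NA` entries are the ones to impute (unless `mask` is given).
#' @param n_modes number of retained modes, between 1 and `min(dim(x))`.
#' @param mask optional logical matrix, `TRUE` = impute; defaults to
#'   `is.na(x)`.
#' @param init initial fill: `"mean"` or `"linear"` (see [initial_fill()]).
#' @param tol convergence tolerance on the inter-iteration mean squared
#'   change of the imputed entries; default `1e-6`.
#' @param max_iter iteration cap.
#' @param delta `"absolute"` (default) uses the mean squared change as is;
#'   `"relative"` divides it by the mean square of the current imputed
#'   entries, making convergence invariant under rescaling of the data.
#' @param clip_negative clip imputed entries at zero after convergence.
#' @return An object of class `gsvd` with elements `completed` (the filled
#'   matrix), `iterations`, `final_delta`, `converged`, `mask`, `n_modes`,
#'   `init`, `d` (singular values of the final filled matrix), `u`, `v`
#'   (its first `n_modes` singular vectors) and `call`. Methods:
#'   [print.gsvd()], [summary.gsvd()], [fitted.gsvd()], [residuals.gsvd()],
#'   [plot.gsvd()].
#' @examples
#' x <- outer(sin(seq(0, pi, length.out = 20))^2 + 0.1, 1:8)
#' xg <- x; xg[sample(length(x), 16)] <- NA
#' fit <- gappy_svd(xg, n_modes = 1)
#' max(abs(fitted(fit) - x))
#' @export
gappy_svd <- function(x, n_modes, mask = NULL,
                      init = c("mean", "linear"),
                      tol = 1e-6, max_iter = 1000L,
                      delta = c("absolute", "relative"),
                      clip_negative = TRUE) {
  cl <- match.call()
  init <- match.arg(init)
  delta <- match.arg(delta)
  if (inherits(x, "gappy_matrix")) {
    mask <- x$mask
    x <- x$values
  }
  x <- as.matrix(x)
  if (is.null(mask)) mask <- is.na(x)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(x)))
    stop("'mask' and 'x' must have identical shape")
  if (any(!is.finite(x[!mask])))
    stop("observed entries must be finite")
  if (n_modes < 1 || n_modes > min(dim(x)))
    stop("'n_modes' must be between 1 and min(dim(x))")
  if (tol <= 0) stop("'tol' must be positive")
  if (any(colSums(!mask) == 0L))
    stop("cannot impute a fully masked column")

  filled <- apply(`[<-`(x, mask, NA_real_), 2L, initial_fill, method = init)
  n_modes <- as.integer(n_modes)
  iterations <- 0L
  final_delta <- 0
  converged <- TRUE
  sv <- svd(filled)
  if (any(mask)) {
    converged <- FALSE
    repeat {
      iterations <- iterations + 1L
      sv <- svd(filled, nu = n_modes, nv = n_modes)
      recon <- sv$u %*% (sv$d[seq_len(n_modes)] * t(sv$v))
      new_vals <- recon[mask]
      final_delta <- mean((new_vals - filled[mask])^2)
      if (delta == "relative") {
        denom <- mean(filled[mask]^2)
        if (denom > 0) final_delta <- final_delta / denom
      }
      filled[mask] <- new_vals
      if (final_delta < tol) { converged <- TRUE; break }
      if (iterations >= max_iter) break
    }
    if (clip_negative) filled[mask] <- pmax(filled[mask], 0)
    sv <- svd(filled, nu = n_modes, nv = n_modes)
  }
  structure(
    list(completed = filled, iterations = iterations,
         final_delta = final_delta, converged = converged,
         mask = mask, n_modes = n_modes, init = init, tol = tol,
         d = sv$d,
         u = sv$u[, seq_len(n_modes), drop = FALSE],
         v = sv$v[, seq_len(n_modes), drop = FALSE],
         call = cl),
    class = "gsvd"
  )
}

#' @export
print.gsvd <- function(x, ...) {
  cat("Gappy-SVD imputation\n")
  cat(sprintf("  matrix: %d x %d, %d imputed entries (%.1f%%)\n",
              nrow(x$completed), ncol(x$completed), sum(x$mask),
              100 * mean(x$mask)))
  cat(sprintf("  modes: %d, init: %s\n", x$n_modes, x$init))
  cat(sprintf("  %s after %d iteration(s), final delta %.3g (tol %.1g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$final_delta, x$tol))
  invisible(x)
}

#' Summarise a Gappy-SVD fit
#'
#' @param object a `gsvd` fit.
#' @param ... unused.
#' @return A list of class `summary.gsvd` with the fit's dimensions,
#'   convergence diagnostics, the retained singular values and the fraction
#'   of total variance (squared singular values) they capture.
#' @export
summary.gsvd <- function(object, ...) {
  d2 <- object$d^2
  structure(
    list(dim = dim(object$completed), n_imputed = sum(object$mask),
         n_modes = object$n_modes, init = object$init,
         iterations = object$iterations, final_delta = object$final_delta,
         converged = object$converged,
         singular_values = object$d[seq_len(object$n_modes)],
         energy = sum(d2[seq_len(object$n_modes)]) / sum(d2)),
    class = "summary.gsvd"
  )
}

#' @export
print.summary.gsvd <- function(x, ...) {
  cat("Gappy-SVD imputation\n")
  cat(sprintf("  %d x %d matrix, %d imputed entries\n",
              x$dim[1L], x$dim[2L], x$n_imputed))
  cat(sprintf("  %d retained mode(s) (init %s) capture %.1f%% of variance\n",
              x$n_modes, x$init, 100 * x$energy))
  cat("  leading singular values:",
      paste(signif(x$singular_values, 4), collapse = ", "), "\n")
  cat(sprintf("  %s after %d iteration(s), final delta %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$final_delta))
  invisible(x)
}

#' @rdname gappy_svd
#' @param object,... a `gsvd` fit; further arguments ignored.
#' @details `fitted()` returns the rank-`n_modes` reconstruction of the
#'   final filled matrix; `residuals()` returns observed minus fitted at
#'   the observed entries (`NA` at imputed ones).
#' @export
fitted.gsvd <- function(object, ...) {
  r <- object$u %*% (object$d[seq_len(object$n_modes)] * t(object$v))
  dimnames(r) <- dimnames(object$completed)
  r
}

#' @rdname gappy_svd
#' @export
residuals.gsvd <- function(object, ...) {
  r <- object$completed - fitted(object)
  r[object$mask] <- NA_real_
  r
}

#' Diagnostic plot of a Gappy-SVD fit
#'
#' Left: singular-value spectrum of the completed matrix with the retained
#' modes highlighted. Right: one column of the completed matrix with its
#' imputed entries marked.
#'
#' @param x a `gsvd` fit.
#' @param column which column to display (default: the column with the
#'   most imputed entries).
#' @param ... passed to `plot`.
#' @return `x`, invisibly.
#' @export
plot.gsvd <- function(x, column = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  keep <- seq_len(x$n_modes)
  plot(x$d, log = "y", xlab = "mode", ylab = "singular value",
       pch = 19, col = ifelse(seq_along(x$d) %in% keep, "firebrick", "grey50"),
       main = "spectrum", ...)
  if (is.null(column)) column <- which.max(colSums(x$mask))
  v <- x$completed[, column]
  plot(v, type = "l", xlab = "day", ylab = "concentration",
       main = sprintf("column %s", column))
  imp <- which(x$mask[, column])
  graphics::points(imp, v[imp], pch = 19, col = "firebrick")
  invisible(x)
}
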