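#' Subtract the angular mean from a polar pattern
#'
#' For each q row, subtracts the mean intensity over the row's valid azimuth
#' bins; invalid bins are set to zero and stay flagged.  Rows with no valid
#' bin are flagged entirely invalid and excluded downstream.  The output
#' carries `mean_subtracted = TRUE` and has zero angular mean on every valid
#' row by construction.
#'
#' @param p a [polar_pattern()].
#' @return a mean-subtracted [polar_pattern()].
#' @export
subtract_angular_mean <- function(p) {
  stopifnot(inherits(p, "polar_pattern"))
  I <- p$intensity; M <- p$mask
  nvalid <- rowSums(M)
  mu <- ifelse(nvalid > 0, rowSums(I * M) / pmax(nvalid, 1), 0)
  out <- (I - mu) * M
  M[nvalid == 0, ] <- FALSE
  polar_pattern(out, p$grid, mask = M, meta = p$meta, mean_subtracted = TRUE)
}

# circular cross-correlation sums via FFT.
# Returns num[dphi, qprime] = sum_phi a[phi] * B[phi + dphi, qprime]
# for one row spectrum fa (length n_phi) against all column spectra FB.
cc_from_fft <- function(fa, FB) {
  n <- nrow(FB)
  Re(stats::mvfft(Conj(fa) * FB, inverse = TRUE)) / n
}

#' Angular intensity correlation of one exposure
#'
#' Computes the mask-aware circular correlation
#' `C_k(q, q', dphi) = (1/n_valid) * sum_phi I(q, phi) I(q', phi + dphi)`
#' where the sum runs over azimuth pairs with both bins valid and `n_valid`
#' counts those pairs.  Implemented with FFTs (numerator and pair counts are
#' both circular correlations); equality with the direct double loop is exact
#' to rounding and is enforced by the test-suite.  Entries with no valid pair
#' are `NA`.
#'
#' @param p a mean-subtracted [polar_pattern()].
#' @return an `n_q x n_q x n_phi` array with `dimnames`-free dimensions
#'   ordered (q, q', dphi).
#' @export
correlate_pattern <- function(p) {
  stopifnot(inherits(p, "polar_pattern"))
  if (!p$mean_subtracted)
    stop("correlate_pattern expects a mean-subtracted pattern")
  n_q <- p$grid$n_q; n_phi <- p$grid$n_phi
  A <- p$intensity * p$mask
  M <- p$mask * 1
  FA <- stats::mvfft(t(A))          # n_phi x n_q, FFT along phi per q row
  FM <- stats::mvfft(t(M))
  C <- array(NA_real_, c(n_q, n_q, n_phi))
  for (i in seq_len(n_q)) {
    num <- cc_from_fft(FA[, i], FA)           # n_phi x n_q
    den <- cc_from_fft(FM[, i], FM)
    den <- round(den)                          # exact integer pair counts
    val <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
    C[i, , ] <- t(val)
  }
  C
}

#' Correlate a stack of exposures
#'
#' Convenience wrapper: mean-subtracts (if needed) and correlates every
#' pattern, then averages with [average_correlations()].
#'
#' @param patterns list of [polar_pattern()]s sharing one grid.
#' @return a [correlation_volume()].
#' @export
correlate_stack <- function(patterns) {
  if (length(patterns) < 1) stop("empty stack")
  grid <- patterns[[1]]$grid
  acc <- cnt <- NULL
  for (p in patterns) {                 # incremental: one array in memory
    if (!p$mean_subtracted) p <- subtract_angular_mean(p)
    C <- correlate_pattern(p)
    ok <- !is.na(C)
    if (is.null(acc)) { acc <- array(0, dim(C)); cnt <- array(0L, dim(C)) }
    acc[ok] <- acc[ok] + C[ok]
    cnt <- cnt + ok
  }
  out <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  correlation_volume(out, grid, n_d = length(patterns))
}

#' Ensemble-averaged correlation volume
#'
#' Arithmetic mean over exposures of the per-exposure correlation arrays,
#' ignoring invalid (`NA`) entries; records the number of exposures `n_d`.
#'
#' @param corrs list of correlation arrays from [correlate_pattern()].
#' @param grid the shared [polar_grid()].
#' @return a [correlation_volume()].
#' @export
average_correlations <- function(corrs, grid) {
  if (length(corrs) < 1) stop("empty stack")
  dims <- dim(corrs[[1]])
  acc <- array(0, dims); cnt <- array(0L, dims)
  for (C in corrs) {
    if (any(dim(C) != dims)) stop("correlation arrays differ in shape")
    ok <- !is.na(C)
    acc[ok] <- acc[ok] + C[ok]
    cnt <- cnt + ok
  }
  out <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  correlation_volume(out, grid, n_d = length(corrs))
}

#' Correlation volume container
#'
#' Holds the ensemble-averaged angular correlation `C(q, q', dphi)` on the
#' polar grid's q values and azimuth lags, with the exposure count `n_d`.
#' The stored array satisfies `C(q, q', dphi) = C(q', q, -dphi)` and, for
#' mean-subtracted input, zero mean over `dphi` at every `(q, q')` with full
#' angular support.
#'
#' @param values `n_q x n_q x n_phi` array.
#' @param grid a [polar_grid()] (its phi values serve as the dphi lags).
#' @param n_d number of exposures averaged.
#' @param mean_subtracted flag, default `TRUE`.
#' @return an object of class `correlation_volume`.
#' @export
correlation_volume <- function(values, grid, n_d = 1L, mean_subtracted = TRUE) {
  stopifnot(inherits(grid, "polar_grid"))
  d <- dim(values)
  if (length(d) != 3 || d[1] != grid$n_q || d[2] != grid$n_q ||
      d[3] != grid$n_phi)
    stop("values must be an n_q x n_q x n_phi array")
  structure(list(values = values, q = grid$q, dphi = grid$phi,
                 grid = grid, n_d = as.integer(n_d),
                 mean_subtracted = mean_subtracted),
            class = "correlation_volume")
}

#' @export
print.correlation_volume <- function(x, ...) {
  cat("correlation_volume:", length(x$q), "x", length(x$q), "x",
      length(x$dphi), "averaged over", x$n_d, "exposures\n")
  invisible(x)
}
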