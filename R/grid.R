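#' Polar (q, phi) grid
#'
#' Defines the common polar sampling used throughout the pipeline: strictly
#' increasing scattering-vector magnitudes `q` (nm^-1) and `n_phi` uniform
#' azimuth bin centres spanning `[0, 2*pi)`.  `n_phi` must be even so that
#' twofold (Friedel) symmetric quantities fall on grid points.
#'
#' @param q_values strictly increasing numeric vector of q bin centres (nm^-1).
#' @param n_phi even integer, number of azimuth bins (default 360, i.e. 1
#'   degree bins; fine enough to resolve a sixth-order polynomial fit and
#'   Legendre orders up to l = 12).
#' @return an object of class `polar_grid` with fields `q`, `phi`, `n_q`,
#'   `n_phi`, `dphi`.
#' @export
polar_grid <- function(q_values, n_phi = 360L) {
  q_values <- as.numeric(q_values)
  n_phi <- as.integer(n_phi)
  if (length(q_values) < 1 || any(diff(q_values) <= 0))
    stop("q_values must be strictly increasing")
  if (any(q_values < 0)) stop("q_values must be non-negative")
  if (n_phi < 2 || n_phi %% 2 != 0) stop("n_phi must be even and >= 2")
  structure(list(q = q_values,
                 phi = 2 * pi * (seq_len(n_phi) - 1) / n_phi,
                 n_q = length(q_values), n_phi = n_phi,
                 dphi = 2 * pi / n_phi),
            class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat("polar_grid:", x$n_q, "q bins in [", min(x$q), ",", max(x$q),
      "] nm^-1,", x$n_phi, "phi bins\n")
  invisible(x)
}

#' One exposure on a polar grid
#'
#' Container for a single diffraction pattern resampled onto a [polar_grid()]:
#' an intensity matrix indexed `[q, phi]`, a logical mask (`TRUE` = valid bin)
#' and optional metadata (exposure id, ground-truth modulation angle for
#' synthetic data).  The `mean_subtracted` flag records whether
#' [subtract_angular_mean()] has been applied.
#'
#' @param intensity numeric `n_q x n_phi` matrix.
#' @param grid a [polar_grid()].
#' @param mask logical matrix of the same shape, `TRUE` where valid.
#' @param meta named list of metadata.
#' @param mean_subtracted logical flag.
#' @return an object of class `polar_pattern`.
#' @export
polar_pattern <- function(intensity, grid, mask = NULL, meta = list(),
                          mean_subtracted = FALSE) {
  stopifnot(inherits(grid, "polar_grid"))
  if (!is.matrix(intensity) || nrow(intensity) != grid$n_q ||
      ncol(intensity) != grid$n_phi)
    stop("intensity must be an n_q x n_phi matrix matching the grid")
  if (is.null(mask)) mask <- matrix(TRUE, grid$n_q, grid$n_phi)
  if (!is.logical(mask) || any(dim(mask) != dim(intensity)))
    stop("mask must be a logical matrix matching intensity")
  if (any(!is.finite(intensity[mask])))
    stop("intensity must be finite on valid bins")
  if (!mean_subtracted && any(intensity[mask] < 0))
    stop("raw intensity must be non-negative on valid bins")
  structure(list(intensity = intensity, mask = mask, grid = grid,
                 meta = meta, mean_subtracted = mean_subtracted),
            class = "polar_pattern")
}

#' @export
print.polar_pattern <- function(x, ...) {
  cat("polar_pattern:", x$grid$n_q, "x", x$grid$n_phi,
      if (x$mean_subtracted) "(mean-subtracted)" else "",
      sprintf("[%.0f%% valid]\n", 100 * mean(x$mask)))
  invisible(x)
}
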