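#' Radial (azimuthally averaged) intensity profile
#'
#' Mean over valid azimuth bins at each q; fully masked rows are `NA`.
#'
#' @param p a [polar_pattern()].
#' @return numeric vector of length `n_q`.
#' @export
radial_profile <- function(p) {
  stopifnot(inherits(p, "polar_pattern"))
  nvalid <- rowSums(p$mask)
  out <- rowSums(p$intensity * p$mask) / pmax(nvalid, 1)
  out[nvalid == 0] <- NA_real_
  out
}

# local maxima above a prominence floor with a minimum separation (in bins)
find_peaks <- function(y, prominence = 0.05, min_separation = 3) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(y))) == -2) + 1
  cand <- cand[y[cand] >= prominence * max(y, na.rm = TRUE)]
  cand <- cand[order(-y[cand])]
  keep <- integer(0)
  for (i in cand)
    if (all(abs(i - keep) >= min_separation)) keep <- c(keep, i)
  sort(keep)
}

#' Identify the mesophase from peak-position ratios
#'
#' Detects peaks in a radial profile and tests the hexagonal signature
#' q ratios 1 : sqrt(3) : 2.  The phase is `"hexagonal"` when peaks matching
#' the (10) and (11) positions are both present within `tolerance` (the (20)
#' order may be missing, as is typical when higher-order intensities are
#' weak); the lattice parameter is `a = 4*pi/(sqrt(3)*q10)`.
#'
#' @param profile radial intensity profile.
#' @param q q values (nm^-1) matching the profile.
#' @param tolerance relative tolerance on peak ratios (default 0.02).
#' @param prominence peak floor as a fraction of the profile maximum.
#' @param min_separation minimum peak separation in bins.
#' @return list with `phase` (`"hexagonal"`, `"unknown"` or `"empty"`),
#'   `a` (nm, NA unless hexagonal), `peaks` (detected peak q values).
#' @export
identify_phase <- function(profile, q, tolerance = 0.02, prominence = 0.05,
                           min_separation = 3) {
  ok <- is.finite(profile)
  idx <- find_peaks(ifelse(ok, profile, -Inf), prominence, min_separation)
  if (length(idx) == 0)
    return(list(phase = "empty", a = NA_real_, peaks = numeric(0)))
  pk <- q[idx]
  for (q10 in pk) {
    r <- pk / q10
    has11 <- any(abs(r - sqrt(3)) / sqrt(3) <= tolerance)
    if (has11)
      return(list(phase = "hexagonal", a = 4 * pi / (sqrt(3) * q10),
                  peaks = pk))
  }
  list(phase = "unknown", a = NA_real_, peaks = pk)
}

#' Filter records on lattice-parameter consistency
#'
#' Iteratively drops records whose lattice parameter deviates from the mean
#' of the kept set by more than `tolerance` (relative), until the kept set is
#' stable.  The result is independent of record order.
#'
#' @param records data frame with a column `a` (lattice parameter, nm).
#' @param tolerance relative tolerance (default 0.05).
#' @return `records` with a logical column `keep` added/overwritten.
#' @export
lattice_filter <- function(records, tolerance = 0.05) {
  if (!"a" %in% names(records)) stop("records need a column 'a'")
  keep <- is.finite(records$a)
  if (!any(keep)) stop("no consistent ensemble: no finite lattice parameters")
  repeat {
    mu <- mean(records$a[keep])
    newkeep <- is.finite(records$a) & abs(records$a - mu) / mu <= tolerance
    if (!any(newkeep)) stop("no consistent ensemble: all records dropped")
    if (identical(newkeep, keep)) break
    keep <- newkeep
  }
  records$keep <- keep
  records
}

#' Profile agreement factor R_k
#'
#' L1 relative residual between a profile and a reference (crystallographic
#' R-factor form): `R_k = sum |I_k - Iref| / sum Iref`.  Zero for identical
#' profiles; `R_k(c * Iref, Iref) = |c - 1|`.
#'
#' @param profile,reference numeric vectors on the same q grid.
#' @return non-negative scalar.
#' @export
profile_agreement <- function(profile, reference) {
  if (length(profile) != length(reference))
    stop("profile and reference must share one q grid")
  ok <- is.finite(profile) & is.finite(reference)
  denom <- sum(reference[ok])
  if (!is.finite(denom) || denom == 0) stop("zero-norm reference profile")
  sum(abs(profile[ok] - reference[ok])) / denom
}

#' Fit the azimuthal orientation of a diffraction ring
#'
#' Determines the magnitude and peak angle of a twofold orientational
#' modulation from the intensity around a ring.  The azimuth is folded to
#' `[0, 180)` degrees (twofold degeneracy), recentred so the coarse maximum
#' (order-2 circular moment) sits mid-interval to avoid wrap artefacts, and
#' interpolated with a sixth-order least-squares polynomial.  `phi_max` is
#' the polynomial's argmax mapped back to the original frame; the magnitude
#' is `(max - min) / mean` of the fitted polynomial.
#'
#' @param ring intensity versus azimuth (full circle).
#' @param phi_deg azimuth bin centres in degrees (default: uniform over
#'   `[0, 360)`).
#' @param mask logical vector, `TRUE` for valid bins.
#' @return list with `magnitude`, `phi_max` (degrees in `[0, 180)`), `ok`
#'   (FALSE for flat/degenerate rings, which are flagged omitted).
#' @export
azimuthal_orientation_fit <- function(ring, phi_deg = NULL, mask = NULL) {
  n <- length(ring)
  if (is.null(phi_deg)) phi_deg <- 360 * (seq_len(n) - 1) / n
  if (is.null(mask)) mask <- rep(TRUE, n)
  mask <- mask & is.finite(ring)
  if (sum(mask) < 14)
    return(list(magnitude = NA_real_, phi_max = NA_real_, ok = FALSE))
  y <- ring[mask]; ph <- phi_deg[mask]
  if (stats::sd(y) < 1e-6 * max(abs(mean(y)), .Machine$double.eps))
    return(list(magnitude = 0, phi_max = NA_real_, ok = FALSE))

  # coarse centre from the order-2 circular moment (degrees)
  z <- sum(y * exp(2i * ph * pi / 180))
  centre <- (Arg(z) / 2 * 180 / pi) %% 180
  # folded, recentred coordinate in [0, 180) with the peak near 90
  x <- (ph - centre + 90) %% 180
  fit <- try(stats::lm(y ~ stats::poly(x, 6, raw = TRUE)), silent = TRUE)
  if (inherits(fit, "try-error") || anyNA(stats::coef(fit)))
    return(list(magnitude = NA_real_, phi_max = NA_real_, ok = FALSE))
  xfine <- seq(0, 180, length.out = 721)
  yfine <- stats::predict(fit, data.frame(x = xfine))
  mu <- mean(yfine)
  mag <- if (mu > 0) (max(yfine) - min(yfine)) / mu else NA_real_
  phi_max <- (xfine[which.max(yfine)] - 90 + centre) %% 180
  list(magnitude = mag, phi_max = phi_max, ok = TRUE)
}

#' Arrange per-exposure orientation fits into maps
#'
#' Builds the modulation-magnitude and peak-angle images of a raster scan
#' from a list of [azimuthal_orientation_fit()] results (row-major order,
#' i.e. the first `shape[2]` fits fill the first row).
#'
#' @param fits list of fit results.
#' @param shape integer length-2, scan grid (rows, columns).
#' @return list of matrices `magnitude`, `phi_max` and logical `omitted`.
#' @export
build_orientation_map <- function(fits, shape) {
  stopifnot(length(shape) == 2, length(fits) == prod(shape))
  grab <- function(f, what) if (isTRUE(f$ok)) f[[what]] else NA_real_
  mag <- matrix(vapply(fits, grab, 0, what = "magnitude"),
                nrow = shape[1], byrow = TRUE)
  ang <- matrix(vapply(fits, grab, 0, what = "phi_max"),
                nrow = shape[1], byrow = TRUE)
  om <- matrix(!vapply(fits, function(f) isTRUE(f$ok), TRUE),
               nrow = shape[1], byrow = TRUE)
  list(magnitude = mag, phi_max = ang, omitted = om)
}

#' Build profile records for an ensemble
#'
#' Runs [radial_profile()], [identify_phase()] and [profile_agreement()]
#' (against the ensemble-mean profile) over a pattern stack, producing the
#' curation table used by [lattice_filter()] and R_k thresholding.
#'
#' @param patterns list of [polar_pattern()]s.
#' @param tolerance peak-ratio tolerance for phase identification.
#' @param rk_max optional R_k threshold; records above it get `keep = FALSE`
#'   after lattice filtering.
#' @param lattice_tolerance relative lattice tolerance (default 0.05).
#' @return data frame with columns `exposure`, `phase`, `a`, `r_k`, `keep`.
#' @export
ensemble_filter <- function(patterns, tolerance = 0.02, rk_max = Inf,
                            lattice_tolerance = 0.05) {
  profs <- vapply(patterns, radial_profile,
                  numeric(patterns[[1]]$grid$n_q))
  refp <- rowMeans(profs, na.rm = TRUE)
  q <- patterns[[1]]$grid$q
  rec <- do.call(rbind, lapply(seq_along(patterns), function(k) {
    ph <- identify_phase(profs[, k], q, tolerance)
    data.frame(exposure = k, phase = ph$phase, a = ph$a,
               r_k = profile_agreement(profs[, k], refp))
  }))
  rec <- lattice_filter(rec, lattice_tolerance)
  rec$keep <- rec$keep & rec$r_k <= rk_max & rec$phase == "hexagonal"
  rec
}
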