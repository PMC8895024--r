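#' Spherical Bessel function of the first kind
#'
#' `j_l(x) = sqrt(pi/(2x)) J_{l+1/2}(x)` with the limiting values at zero
#' (`j_0(0) = 1`, `j_l(0) = 0` for `l > 0`).
#'
#' @param l non-negative integer order.
#' @param x non-negative evaluation points.
#' @return numeric vector.
#' @export
sph_bessel_j <- function(l, x) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- sqrt(pi / (2 * x[nz])) * besselJ(x[nz], l + 0.5)
  out[!nz] <- if (l == 0) 1 else 0
  out
}

#' Spherical Bessel transform matrix
#'
#' Matrix form of the order-l spherical Bessel transform on a fixed q grid:
#' `M[i, j] = j_l(q_j * r_i) * q_j^2 * w_j` with trapezoid weights `w`.
#' Applying it to both variables of a harmonic matrix (`M B t(M)`) carries
#' `B_l(q, q')` to `B_l(r, r')`.
#'
#' @param l even order.
#' @param q_values strictly increasing q grid (nm^-1).
#' @param r_values r grid (nm).
#' @return `length(r_values) x length(q_values)` matrix.
#' @export
sbt_matrix <- function(l, q_values, r_values) {
  if (length(q_values) > 1 && any(diff(q_values) <= 0))
    stop("q grid must be strictly increasing")
  w <- trapezoid_weights(q_values)
  J <- outer(r_values, q_values, function(r, q) sph_bessel_j(l, q * r))
  sweep(J, 2, q_values^2 * w, "*")
}

trapezoid_weights <- function(x) {
  n <- length(x)
  if (n == 1) return(1)
  d <- diff(x)
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

#' Transform harmonic matrices to real space
#'
#' `B_l(r, r') = M_l B_l(q, q') t(M_l)` per order, preserving q <-> q'
#' symmetry.  An optional raised-cosine window over the top fraction of the
#' q range damps truncation ringing (off by default).
#'
#' @param bl a [bl_matrices()].
#' @param r_values r grid in nm.  The default working range 1-10 nm with 64
#'   points respects the `pi/q_max` resolution bound of typical small-angle
#'   grids.
#' @param window fraction of the upper q range tapered by a cosine window
#'   (0 = none).
#' @return list with `l`, `r`, `matrices` (real-space per-l matrices).
#' @export
bl_qq_to_rr <- function(bl, r_values = seq(1, 10, length.out = 64),
                        window = 0) {
  stopifnot(inherits(bl, "bl_matrices"))
  taper <- rep(1, length(bl$q))
  if (window > 0) {
    qmax <- max(bl$q); q0 <- qmax - window * (qmax - min(bl$q))
    hi <- bl$q > q0
    taper[hi] <- 0.5 * (1 + cos(pi * (bl$q[hi] - q0) / (qmax - q0)))
  }
  mats <- lapply(seq_along(bl$l), function(i) {
    M <- sbt_matrix(bl$l[i], bl$q, r_values)
    Bq <- bl$matrices[[i]] * outer(taper, taper)
    M %*% Bq %*% t(M)
  })
  names(mats) <- paste0("l", bl$l)
  list(l = bl$l, r = r_values, matrices = mats)
}

#' Assemble the pair-angle distribution function
#'
#' Legendre synthesis of the real-space volume,
#' `Theta(r, r', theta) = sum_l B_l(r, r') P_l(cos theta)` over even orders,
#' omitting `l = 0` by default (mean-subtracted correlations carry no
#' isotropic term).  The overall scale is arbitrary; the volume is
#' normalised to `max |Theta| = 1`.
#'
#' @param bl_rr output of [bl_qq_to_rr()].
#' @param theta_values angle grid in degrees, default 0..180 in 1 degree
#'   steps.
#' @param include_l0 keep the l = 0 term (default FALSE).
#' @return an object of class `padf_volume`: `r` (nm), `theta` (degrees),
#'   `volume` (`n_r x n_r x n_theta`), `bl_rr`.
#' @export
assemble_padf <- function(bl_rr, theta_values = seq(0, 180, 1),
                          include_l0 = FALSE) {
  keep <- if (include_l0) seq_along(bl_rr$l) else which(bl_rr$l > 0)
  n_r <- length(bl_rr$r)
  vol <- array(0, c(n_r, n_r, length(theta_values)))
  if (length(keep)) {
    P <- legendre_table(bl_rr$l[keep], cos(theta_values * pi / 180))
    for (i in seq_along(keep))
      vol <- vol + outer(bl_rr$matrices[[keep[i]]], P[, i])
  }
  m <- max(abs(vol))
  if (m > 0) vol <- vol / m
  structure(list(r = bl_rr$r, theta = theta_values, volume = vol,
                 bl_rr = bl_rr), class = "padf_volume")
}

#' @export
print.padf_volume <- function(x, ...) {
  cat("padf_volume:", length(x$r), "r bins in [", min(x$r), ",", max(x$r),
      "] nm,", length(x$theta), "theta bins\n")
  invisible(x)
}

#' Diagonal slice of the PADF
#'
#' Extracts `Theta(r = r', theta)` as an `n_r x n_theta` matrix, together
#' with the theta profile at the r of strongest diagonal intensity
#' (`attr(..., "r_star")`, `attr(..., "profile")`).
#'
#' @param padf a `padf_volume`.
#' @return matrix with attributes `r_star` (nm) and `profile`.
#' @export
slice_requal <- function(padf) {
  stopifnot(inherits(padf, "padf_volume"))
  n_r <- length(padf$r)
  S <- t(vapply(seq_len(n_r), function(i) padf$volume[i, i, ],
                numeric(length(padf$theta))))
  istar <- which.max(apply(abs(S), 1, max))
  attr(S, "r_star") <- padf$r[istar]
  attr(S, "profile") <- S[istar, ]
  S
}

#' Per-l diagonal profiles normalised to l = 2
#'
#' Returns `B_l(r, r)` curves for `l >= 4` divided by `max |B_2(r, r)|`,
#' the standard way of tracking how higher-order texture contributions grow
#' relative to the dominant twofold term.
#'
#' @param bl_rr output of [bl_qq_to_rr()].
#' @return data frame with columns `r`, `l`, `value`.
#' @export
blrr_profile <- function(bl_rr) {
  if (!2 %in% bl_rr$l) stop("l = 2 term required for normalisation")
  d2 <- diag(bl_rr$matrices[[match(2, bl_rr$l)]])
  norm <- max(abs(d2))
  if (norm == 0) stop("zero l = 2 diagonal; normalisation undefined")
  ls <- bl_rr$l[bl_rr$l >= 2]
  do.call(rbind, lapply(ls, function(l)
    data.frame(r = bl_rr$r, l = l,
               value = diag(bl_rr$matrices[[match(l, bl_rr$l)]]) / norm)))
}

#' Secondary angular feature of the diagonal slice
#'
#' Locates the strongest two-dimensional local maximum of the absolute
#' diagonal slice `|Theta(r, r, theta)|` with theta restricted to an open
#' window (default 10-80 degrees).  The primary maxima of a textured PADF
#' sit at 0 and 180 degrees; secondary blobs inside the window are the
#' signature of higher-order (l >= 4) pole-distribution content.
#'
#' @param padf a `padf_volume`.
#' @param theta_window open interval in degrees.
#' @return list with `theta`, `r`, `value`, or `NULL` if no interior local
#'   maximum exists.
#' @export
padf_secondary_peak <- function(padf, theta_window = c(10, 80)) {
  S <- abs(slice_requal(padf))
  th <- padf$theta
  n_r <- nrow(S); n_t <- ncol(S)
  best <- NULL
  for (i in 2:(n_r - 1)) for (j in 2:(n_t - 1)) {
    if (th[j] <= theta_window[1] || th[j] >= theta_window[2]) next
    v <- S[i, j]
    if (v > S[i - 1, j] && v > S[i + 1, j] &&
        v > S[i, j - 1] && v > S[i, j + 1] &&
        v >= S[i - 1, j - 1] && v >= S[i + 1, j + 1] &&
        v >= S[i - 1, j + 1] && v >= S[i + 1, j - 1]) {
      if (is.null(best) || v > best$value)
        best <- list(theta = th[j], r = padf$r[i], value = v)
    }
  }
  best
}

#' Full correlation-to-PADF chain
#'
#' Convenience wrapper: [correlation_to_bl()], [bl_qq_to_rr()],
#' [assemble_padf()].
#'
#' @param vol a [correlation_volume()].
#' @param l_max maximum even order.
#' @param r_values r grid (nm).
#' @param theta_values theta grid (degrees).
#' @param svd_cutoff relative SVD cutoff.
#' @return a `padf_volume`.
#' @export
padf_from_correlation <- function(vol, l_max = 8,
                                  r_values = seq(1, 10, length.out = 64),
                                  theta_values = seq(0, 180, 1),
                                  svd_cutoff = 1e-6) {
  bl <- correlation_to_bl(vol, l_max = l_max, svd_cutoff = svd_cutoff)
  assemble_padf(bl_qq_to_rr(bl, r_values), theta_values)
}
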