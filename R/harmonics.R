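#' Legendre polynomials by upward recurrence
#'
#' @param l_values integer vector of orders.
#' @param x evaluation points in `[-1, 1]`.
#' @return matrix `length(x) x length(l_values)` with `P_l(x)` columns.
#' @export
legendre_table <- function(l_values, x) {
  lmax <- max(l_values)
  P <- matrix(0, length(x), lmax + 1)
  P[, 1] <- 1
  if (lmax >= 1) P[, 2] <- x
  if (lmax >= 2) for (l in 2:lmax)
    P[, l + 1] <- ((2 * l - 1) * x * P[, l] - (l - 1) * P[, l - 1]) / l
  P[, l_values + 1, drop = FALSE]
}

#' Legendre design matrix on an azimuth-lag grid
#'
#' Builds the design matrix of the harmonic expansion
#' `C(dphi) = sum_l B_l P_l(cos theta3d(dphi))`.  In the small-angle limit
#' the 3D angle between scattering vectors equals the detector azimuth lag
#' (`theta3d = dphi`).  The `"ewald"` mapping applies the exact relation
#' `cos theta3d = sin a sin a' + cos a cos a' cos dphi` with
#' `sin a = q*lambda/(4*pi)` (scattering vectors sit at polar angle
#' `pi/2 + a` from the beam), which reduces to the small-angle form for
#' `q*lambda/(4*pi) << 1`.
#'
#' @param dphi azimuth lags in radians.
#' @param l_values even Legendre orders.
#' @param mapping `"small_angle"` (default) or `"ewald"`.
#' @param q,qprime scattering-vector magnitudes (nm^-1), ewald mapping only.
#' @param wavelength wavelength in angstrom, ewald mapping only.
#' @return `length(dphi) x length(l_values)` matrix.
#' @export
legendre_design <- function(dphi, l_values,
                            mapping = c("small_angle", "ewald"),
                            q = NULL, qprime = q, wavelength = NULL) {
  mapping <- match.arg(mapping)
  if (any(l_values %% 2 != 0)) stop("l_values must be even")
  x <- if (mapping == "small_angle") {
    cos(dphi)
  } else {
    if (is.null(q) || is.null(wavelength))
      stop("ewald mapping needs q and wavelength")
    lambda_nm <- wavelength / 10
    sa <- q * lambda_nm / (4 * pi); sb <- qprime * lambda_nm / (4 * pi)
    ca <- sqrt(1 - sa^2); cb <- sqrt(1 - sb^2)
    pmin(pmax(sa * sb + ca * cb * cos(dphi), -1), 1)
  }
  legendre_table(l_values, x)
}

#' Harmonic matrices container
#'
#' Even-order Legendre coefficient matrices `B_l(q, q')` of a correlation
#' volume, or theory predictions thereof.
#'
#' @param l_values even integer orders.
#' @param matrices list of symmetric `n_q x n_q` matrices, one per order.
#' @param q q grid (nm^-1).
#' @param provenance `"measured"`, `"predicted_texture"` or
#'   `"predicted_nanostructure"`.
#' @return an object of class `bl_matrices`.
#' @export
bl_matrices <- function(l_values, matrices, q, provenance = "measured") {
  stopifnot(length(l_values) == length(matrices))
  if (any(l_values %% 2 != 0)) stop("odd l excluded by Friedel symmetry")
  names(matrices) <- paste0("l", l_values)
  structure(list(l = as.integer(l_values), matrices = matrices, q = q,
                 provenance = provenance), class = "bl_matrices")
}

#' @export
print.bl_matrices <- function(x, ...) {
  cat("bl_matrices (", x$provenance, "): l =", paste(x$l, collapse = ", "),
      "on", length(x$q), "q bins\n")
  invisible(x)
}

#' Extract B_l(q, q') from a correlation volume by SVD inversion
#'
#' Least-squares fit of even Legendre polynomials to `C(q, q', .)` at every
#' `(q, q')` pair, using the pseudo-inverse of the design matrix with
#' singular values below `svd_cutoff` times the largest discarded.  `l = 0`
#' is included in the fit (it absorbs any residual offset) and reported; it
#' is excluded from power fractions by [bl_power()].  The output matrices are
#' symmetrised in `q <-> q'` (they are already symmetric up to rounding for a
#' valid correlation volume).
#'
#' @param vol a [correlation_volume()].
#' @param l_max maximum even order (default 12); needs `n_phi >= 2*l_max`.
#' @param svd_cutoff relative singular-value cutoff (default 1e-6).
#' @param mapping angle mapping passed to [legendre_design()].
#' @param wavelength wavelength in angstrom (ewald mapping only).
#' @return a [bl_matrices()] with provenance `"measured"`.
#' @export
correlation_to_bl <- function(vol, l_max = 12, svd_cutoff = 1e-6,
                              mapping = c("small_angle", "ewald"),
                              wavelength = NULL) {
  stopifnot(inherits(vol, "correlation_volume"))
  mapping <- match.arg(mapping)
  if (l_max %% 2 != 0) stop("l_max must be even")
  if (vol$grid$n_phi < 2 * l_max) stop("n_phi must be at least 2*l_max")
  ls <- seq(0, l_max, 2)
  n_q <- length(vol$q); n_phi <- length(vol$dphi)

  solve_ls <- function(A, y) {
    sv <- svd(A)
    keep <- sv$d > svd_cutoff * sv$d[1]
    if (!any(keep)) stop("design matrix numerically rank-zero at given cutoff")
    sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  }

  Cmat <- matrix(aperm(vol$values, c(3, 1, 2)), nrow = n_phi)  # dphi x (q*q')
  B <- matrix(NA_real_, length(ls), n_q * n_q)
  if (mapping == "small_angle") {
    A <- legendre_design(vol$dphi, ls)
    full <- !anyNA(Cmat)
    if (full) {
      B <- solve_ls(A, Cmat)
    } else {
      for (j in seq_len(ncol(Cmat))) {
        ok <- !is.na(Cmat[, j])
        if (sum(ok) >= length(ls))
          B[, j] <- solve_ls(A[ok, , drop = FALSE], Cmat[ok, j])
      }
    }
  } else {
    for (j in seq_len(ncol(Cmat))) {
      iq <- (j - 1) %% n_q + 1; jq <- (j - 1) %/% n_q + 1
      A <- legendre_design(vol$dphi, ls, mapping = "ewald",
                           q = vol$q[iq], qprime = vol$q[jq],
                           wavelength = wavelength)
      ok <- !is.na(Cmat[, j])
      if (sum(ok) >= length(ls))
        B[, j] <- solve_ls(A[ok, , drop = FALSE], Cmat[ok, j])
    }
  }
  mats <- lapply(seq_along(ls), function(i) {
    m <- matrix(B[i, ], n_q, n_q)
    (m + t(m)) / 2
  })
  bl_matrices(ls, mats, vol$q, provenance = "measured")
}

#' Synthesise a correlation volume from harmonic matrices
#'
#' Exact synthesis `C(q, q', dphi) = sum_l B_l(q, q') P_l(cos dphi)`
#' (small-angle mapping); the inverse of [correlation_to_bl()] for
#' band-limited volumes.
#'
#' @param bl a [bl_matrices()].
#' @param grid a [polar_grid()] whose q values match `bl$q`.
#' @return a [correlation_volume()].
#' @export
bl_to_correlation <- function(bl, grid) {
  stopifnot(inherits(bl, "bl_matrices"), inherits(grid, "polar_grid"))
  if (length(grid$q) != length(bl$q)) stop("q grids differ")
  n_q <- length(bl$q); n_phi <- grid$n_phi
  P <- legendre_design(grid$phi, bl$l)
  C <- array(0, c(n_q, n_q, n_phi))
  for (i in seq_along(bl$l))
    C <- C + outer(bl$matrices[[i]], P[, i])
  correlation_volume(C, grid, n_d = 1L)
}

#' Angular power per order and fractions relative to l = 2
#'
#' `power_l = sum_{q,q'} B_l(q, q')^2`; fractions are `power_l / power_2`
#' with `l = 0` excluded (mean subtraction removes it physically).
#'
#' @param bl a [bl_matrices()].
#' @return data frame with columns `l`, `power`, `fraction` (NA for l = 0).
#' @export
bl_power <- function(bl) {
  stopifnot(inherits(bl, "bl_matrices"))
  power <- vapply(bl$matrices, function(m) sum(m^2), 0)
  if (!2 %in% bl$l || power[match(2, bl$l)] == 0)
    stop("l = 2 power missing or zero; fractions undefined")
  p2 <- power[match(2, bl$l)]
  frac <- ifelse(bl$l == 0, NA_real_, power / p2)
  data.frame(l = bl$l, power = unname(power), fraction = unname(frac))
}

#' Even Legendre spectrum of a pole-density modulation
#'
#' Projects the density modulation `2*pi*density(phi) - 1` (deviation from
#' uniformity, evaluated at `phi_max = 0`) onto even Legendre polynomials.
#' A twofold pole-density modulation is an even function of `cos(phi)`, so
#' the orthogonal projection uses the Legendre measure:
#' `Q_l = ((2l+1)/2) integral m(phi) P_l(cos phi) sin(phi) dphi` over
#' `[0, pi]`, evaluated by dense trapezoid quadrature in `x = cos(phi)`.
#' The uniform model gives `Q_l = 0` for all `l >= 2`; the sinusoidal model
#' gives `Q_2 = 8*epsilon/3` exactly and no other order.
#'
#' @param model an [orientation_model()].
#' @param l_max maximum even order.
#' @param n_quad quadrature points (>= 512).
#' @return data frame with columns `l`, `Q`.
#' @export
pole_to_ql <- function(model, l_max = 12, n_quad = 4096) {
  stopifnot(n_quad >= 512)
  ls <- seq(0, l_max, 2)
  x <- seq(-1, 1, length.out = n_quad)
  m <- 2 * pi * pole_density(model, acos(x), 0) - 1
  P <- legendre_table(ls, x)
  w <- trapezoid_weights(x)
  data.frame(l = ls,
             Q = as.vector(crossprod(P, m * w)) * (2 * ls + 1) / 2)
}

#' Predicted texture harmonic matrices
#'
#' The preferred-orientation (inter-domain) contribution to the harmonic
#' matrices for `n_c` domains per exposure:
#' `B_t,l(q, q') = n_c^2 * Q_l^2 * I0(q) * I0(q')` for `l >= 2`, where `I0`
#' is the isotropic single-domain radial profile.  Quadratic in `n_c`.
#'
#' @param spectrum output of [pole_to_ql()].
#' @param ring_profile isotropic profile `I0(q)` on the q grid.
#' @param q q grid (nm^-1).
#' @param n_c number of domains per exposure.
#' @return a [bl_matrices()] with provenance `"predicted_texture"`.
#' @export
predict_texture_bl <- function(spectrum, ring_profile, q, n_c) {
  stopifnot(n_c >= 1)
  ls <- spectrum$l[spectrum$l >= 2]
  outerI <- outer(ring_profile, ring_profile)
  mats <- lapply(ls, function(l)
    n_c^2 * spectrum$Q[spectrum$l == l]^2 * outerI)
  bl_matrices(ls, mats, q, provenance = "predicted_texture")
}

#' Predicted nanostructure harmonic matrices
#'
#' The self (single-domain) contribution for `n_c` domains per exposure is
#' `n_c` times the single-domain matrices: linear in `n_c`.
#'
#' @param single_bl [bl_matrices()] measured from one domain's correlation.
#' @param n_c number of domains per exposure.
#' @return a [bl_matrices()] with provenance `"predicted_nanostructure"`.
#' @export
predict_nanostructure_bl <- function(single_bl, n_c) {
  stopifnot(inherits(single_bl, "bl_matrices"), n_c >= 1)
  mats <- lapply(single_bl$matrices, function(m) n_c * m)
  bl_matrices(single_bl$l, mats, single_bl$q,
              provenance = "predicted_nanostructure")
}

#' Texture / nanostructure balance
#'
#' Quantifies which contribution dominates the correlation signal at a given
#' `n_c`.  Angular powers are Frobenius norms summed over `l >= 2` (linear in
#' the matrix scale, so the ratio `power_t / power_c` is linear in `n_c`:
#' texture matrices scale with `n_c^2`, nanostructure with `n_c`).  The
#' crossover is the `n_c` at which the ratio reaches 1.
#'
#' @param bt texture prediction ([predict_texture_bl()]) at `n_c`.
#' @param bc nanostructure prediction ([predict_nanostructure_bl()]) at `n_c`.
#' @param n_c the domain count both predictions were evaluated at.
#' @return list with `power_c`, `power_t`, `ratio`, `n_c`, `crossover_nc`
#'   (NA with a warning if the nanostructure power is zero).
#' @export
balance_ratio <- function(bt, bc, n_c) {
  stopifnot(inherits(bt, "bl_matrices"), inherits(bc, "bl_matrices"))
  fnorm <- function(bl) sum(vapply(bl$matrices[bl$l >= 2],
                                   function(m) sqrt(sum(m^2)), 0))
  power_t <- fnorm(bt); power_c <- fnorm(bc)
  if (power_c == 0) {
    warning("zero nanostructure power; ratio undefined")
    return(list(power_c = 0, power_t = power_t, ratio = NA_real_,
                n_c = n_c, crossover_nc = NA_real_))
  }
  ratio <- power_t / power_c
  crossover <- if (ratio > 0) n_c / ratio else Inf
  list(power_c = power_c, power_t = power_t, ratio = ratio,
       n_c = n_c, crossover_nc = crossover)
}

# order-m cosine amplitude of a circular signal on a uniform grid
cos_amplitude <- function(y, m) {
  n <- length(y)
  phi <- 2 * pi * (seq_len(n) - 1) / n
  (2 / n) * sum(y * cos(m * phi))
}

#' Nc-scaling experiment for texture and nanostructure correlations
#'
#' For each domain count in `nc_values`, simulates `n_patterns` sparse-domain
#' exposures on the (10) ring (orientations drawn from `model` around a
#' per-exposure random `phi_max`, with twofold excitation weighting so the
#' domain profile carries an order-2 moment) and computes the exact
#' self/cross decomposition of the mean-subtracted angular correlation:
#' the correlation of each exposure splits into the sum of single-domain
#' autocorrelations (self, the nanostructure term, linear in Nc) and the
#' cross-domain remainder (the texture term, quadratic in Nc for a twofold
#' pole density).
#'
#' Components measured on the ensemble averages:
#' \itemize{
#'   \item texture: order-2 cosine amplitude of the cross term;
#'   \item nanostructure: mean height of the self term's 60-degree comb peaks
#'     (lags 60, 120, 180, 240, 300 degrees) after removing its order-0 and
#'     order-2 content.
#' }
#' Log-log slopes are fitted by variance-weighted least squares (delta-method
#' weights from the per-exposure spread); at small Nc the cross term is
#' shot-noise limited and its weight is correspondingly small.
#'
#' @param nc_values at least 3 distinct domain counts.
#' @param model an [orientation_model()].
#' @param n_patterns exposures per domain count (default 200).
#' @param lattice a [hex_lattice()].
#' @param n_phi azimuth bins (default 360).
#' @param sigma_phi azimuthal peak width, radians.
#' @param excitation twofold excitation weighting (default 1).
#' @param seed integer seed.
#' @return list with `table` (data frame: `n_c`, `texture`, `texture_se`,
#'   `nano`, `nano_se`), `texture_slope`, `nano_slope`.
#' @export
scaling_experiment <- function(nc_values, model, n_patterns = 200,
                               lattice = hex_lattice(), n_phi = 360,
                               sigma_phi = 2 * pi / 180, excitation = 1,
                               seed = 1) {
  if (length(unique(nc_values)) < 3)
    stop("need at least 3 distinct n_c values")
  grid1 <- polar_grid(lattice$q10, n_phi = n_phi)
  rows <- lapply(seq_along(nc_values), function(iv) {
    nc <- nc_values[iv]
    tex <- nano <- numeric(n_patterns)
    for (k in seq_len(n_patterns)) {
      set.seed(sub_seed(seed + 7919L * iv, k))
      pm <- stats::runif(1, 0, 2 * pi)
      g <- sample_orientations(model, nc, pm)
      prof <- vapply(g, function(gi)
        ring10_profile(lattice, gi, grid1, sigma_phi, excitation),
        numeric(n_phi))                       # n_phi x nc
      prof <- prof - rep(colMeans(prof), each = n_phi)   # per-domain mean off
      FP <- stats::mvfft(prof)
      tot <- rowSums(FP)                      # FFT of summed exposure
      c_tot <- Re(stats::fft(Conj(tot) * tot, inverse = TRUE)) / n_phi^2
      c_self <- Re(stats::mvfft(Conj(FP) * FP, inverse = TRUE)) / n_phi^2
      c_self <- rowSums(c_self)
      c_cross <- c_tot - c_self
      tex[k] <- cos_amplitude(c_cross, 2)
      resid <- c_self - mean(c_self) -
        cos_amplitude(c_self, 2) * cos(2 * grid1$phi)
      comb <- round(seq(60, 300, 60) / 360 * n_phi) + 1
      nano[k] <- mean(resid[comb])
    }
    data.frame(n_c = nc, texture = mean(tex),
               texture_se = stats::sd(tex) / sqrt(n_patterns),
               nano = mean(nano), nano_se = stats::sd(nano) / sqrt(n_patterns))
  })
  tab <- do.call(rbind, rows)

  wls_slope <- function(m, se) {
    ok <- m > 0 & is.finite(m)
    if (sum(ok) < 2) return(NA_real_)
    w <- (m[ok] / pmax(se[ok], .Machine$double.eps))^2
    unname(stats::coef(stats::lm(log(m[ok]) ~ log(tab$n_c[ok]),
                                 weights = w))[2])
  }
  list(table = tab,
       texture_slope = wls_slope(tab$texture, tab$texture_se),
       nano_slope = wls_slope(tab$nano, tab$nano_se))
}

#' Powder-limit contrast experiment
#'
#' For uniformly oriented sparse-domain ensembles, the angular correlation
#' contrast `max|C| / (ring mean)^2` on the (10) ring decays like `1/Nc`:
#' many domains wash out angular structure (the ideal powder limit).  The
#' maximum is taken over lags away from zero-lag by at least one peak width.
#'
#' @inheritParams scaling_experiment
#' @return list with `table` (`n_c`, `contrast`) and `slope` (log-log).
#' @export
powder_limit_experiment <- function(nc_values, n_patterns = 50,
                                    lattice = hex_lattice(), n_phi = 360,
                                    sigma_phi = 2 * pi / 180, seed = 1) {
  if (length(unique(nc_values)) < 3)
    stop("need at least 3 distinct n_c values")
  grid1 <- polar_grid(lattice$q10, n_phi = n_phi)
  model <- orientation_model("uniform")
  rows <- lapply(seq_along(nc_values), function(iv) {
    nc <- nc_values[iv]
    cc <- matrix(0, n_phi, n_patterns); ringmean <- numeric(n_patterns)
    for (k in seq_len(n_patterns)) {
      set.seed(sub_seed(seed + 104729L * iv, k))
      g <- sample_orientations(model, nc, 0)
      prof <- rowSums(vapply(g, function(gi)
        ring10_profile(lattice, gi, grid1, sigma_phi), numeric(n_phi)))
      ringmean[k] <- mean(prof)
      prof <- prof - mean(prof)
      F1 <- stats::fft(prof)
      cc[, k] <- Re(stats::fft(Conj(F1) * F1, inverse = TRUE)) / n_phi^2
    }
    C <- rowMeans(cc)
    keep <- seq_len(n_phi)[-c(1:8, (n_phi - 6):n_phi)]  # exclude zero-lag peak
    data.frame(n_c = nc, contrast = max(abs(C[keep])) / mean(ringmean)^2)
  })
  tab <- do.call(rbind, rows)
  slope <- unname(stats::coef(stats::lm(log(tab$contrast) ~ log(tab$n_c)))[2])
  list(table = tab, slope = slope)
}
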