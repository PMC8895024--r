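#' Two-dimensional hexagonal lattice of a columnar mesophase
#'
#' Describes the reciprocal lattice of a 2D hexagonal (H1) phase of lattice
#' parameter `a` (nm): ring positions at q ratios 1 : sqrt(3) : 2 with
#' `q10 = 4*pi/(sqrt(3)*a)`, and the azimuthal offsets of the
#' symmetry-equivalent reflections ((10) family every 60 degrees, (11) family
#' at 30 + 60k degrees).  Relative ring intensities default to a strong (10)
#' ring with very weak higher orders, as observed for CTAB-water hexagonal
#' phases.
#'
#' @param a lattice parameter in nm (default 5.6, typical of concentrated
#'   CTAB-water at room temperature).
#' @param rel_intensity named numeric, relative integrated intensities of the
#'   `10`, `11` and `20` rings.
#' @return an object of class `hex_lattice` with a `peaks` data frame
#'   (columns `hk`, `q`, `offset` in radians, `rel`).
#' @export
hex_lattice <- function(a = 5.6, rel_intensity = c(`10` = 1, `11` = 0.1,
                                                   `20` = 0.03)) {
  if (a <= 0) stop("lattice parameter must be positive")
  q10 <- 4 * pi / (sqrt(3) * a)
  fam <- function(hk, qv, off0, rel)
    data.frame(hk = hk, q = qv, offset = off0 + (0:5) * pi / 3, rel = rel)
  peaks <- rbind(
    fam("10", q10, 0, rel_intensity[["10"]]),
    fam("11", q10 * sqrt(3), pi / 6, rel_intensity[["11"]]),
    fam("20", q10 * 2, 0, rel_intensity[["20"]]))
  structure(list(a = a, q10 = q10, peaks = peaks,
                 rel_intensity = rel_intensity), class = "hex_lattice")
}

#' Pole-distribution model for in-plane domain orientations
#'
#' The simulator works with the two-dimensional (azimuthal) reduction of the
#' pole distribution: a probability density on `[0, 2*pi)` for the in-plane
#' orientation of a crystal domain, relative to a per-exposure preferred
#' angle `phi_max`.  Three families are supported:
#' \describe{
#'   \item{uniform}{constant `1/(2*pi)` (no texture).}
#'   \item{sinusoidal}{`(1 + 2*epsilon*cos(2*(phi - phi_max)))/(2*pi)`, a
#'     twofold modulation of amplitude `epsilon <= 1/2` (non-negativity).}
#'   \item{lorentzian}{a twofold-periodic Lorentzian: wrapped peaks of
#'     half-width `gamma` (radians) at `phi_max` and `phi_max + pi`,
#'     normalised numerically to integrate to 1.}
#' }
#' Both non-uniform families reduce to the uniform one as `epsilon -> 0` /
#' `gamma -> Inf`.
#'
#' @param kind one of `"uniform"`, `"sinusoidal"`, `"lorentzian"`.
#' @param epsilon sinusoidal modulation amplitude (0 to 1/2).
#' @param gamma periodic-Lorentzian half-width in radians (> 0).
#' @return an object of class `orientation_model`.
#' @export
orientation_model <- function(kind = c("uniform", "sinusoidal", "lorentzian"),
                              epsilon = 0, gamma = 0.35) {
  kind <- match.arg(kind)
  if (kind == "sinusoidal") {
    if (epsilon < 0 || epsilon > 0.5)
      stop("sinusoidal model needs 0 <= epsilon <= 0.5 (density would go negative)")
  }
  if (kind == "lorentzian" && gamma <= 0) stop("gamma must be positive")
  structure(list(kind = kind, epsilon = epsilon, gamma = gamma),
            class = "orientation_model")
}

# wrapped angular difference, result in (-pi, pi]
wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

# unnormalised twofold periodic Lorentzian
lorentz_unnorm <- function(phi, phi_max, gamma) {
  1 / (1 + (wrap_pi(phi - phi_max) / gamma)^2) +
    1 / (1 + (wrap_pi(phi - phi_max - pi) / gamma)^2)
}

#' Pole density
#'
#' Evaluates the orientation-model probability density (per radian) at the
#' given azimuths.
#'
#' @param model an [orientation_model()].
#' @param phi azimuth(s) in radians.
#' @param phi_max preferred angle in radians (ignored for uniform).
#' @return density values, same length as `phi`.
#' @export
pole_density <- function(model, phi, phi_max = 0) {
  stopifnot(inherits(model, "orientation_model"))
  switch(model$kind,
    uniform = rep(1 / (2 * pi), length(phi)),
    sinusoidal = (1 + 2 * model$epsilon * cos(2 * (phi - phi_max))) / (2 * pi),
    lorentzian = {
      # normalisation is phi_max independent; dense trapezoid on [0, 2pi)
      ngrid <- 4096
      pg <- 2 * pi * (seq_len(ngrid) - 1) / ngrid
      z <- mean(lorentz_unnorm(pg, 0, model$gamma)) * 2 * pi
      lorentz_unnorm(phi, phi_max, model$gamma) / z
    })
}

#' Sample domain orientations from a pole density
#'
#' Inverse-CDF sampling on a 4096-point table.  Draws are i.i.d.; the caller
#' controls reproducibility through R's RNG state (`set.seed`).
#'
#' @param model an [orientation_model()].
#' @param n number of draws.
#' @param phi_max preferred angle in radians.
#' @return numeric vector of `n` angles in `[0, 2*pi)`.
#' @export
sample_orientations <- function(model, n, phi_max = 0) {
  stopifnot(n >= 1)
  if (model$kind == "uniform") return(stats::runif(n, 0, 2 * pi))
  ngrid <- 4096
  pg <- 2 * pi * (0:ngrid) / ngrid
  dens <- pole_density(model, pg, phi_max)
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(pg)))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, pg, xout = stats::runif(n), ties = "ordered")$y %% (2 * pi)
}

# wrapped Gaussian on the circle evaluated on the phi grid (matrix-safe)
wrapped_gauss <- function(dphi, sigma) {
  d <- abs(wrap_pi(dphi))
  exp(-d^2 / (2 * sigma^2))
}

#' Diffraction pattern of a single hexagonal domain
#'
#' Renders one domain at in-plane orientation `g` as a sum of Gaussian peaks
#' at `(q_hk, offset_hk + g)`, with radial width `sigma_q` (nm^-1) and
#' azimuthal width `sigma_phi` (radians).  With the default
#' `excitation = 0` all symmetry-equivalent reflections of a family carry the
#' stated relative intensity, so the (10) ring shows 6 equal peaks and the
#' pattern is invariant under 60 degree rotations of `g`.
#'
#' `excitation > 0` applies a twofold weighting `1 + excitation*cos(2*off)`
#' over the reflections of each family (offset `off` in the domain frame).
#' This is the 2D reduction of Ewald-sphere selection for domains tilted out
#' of the plane - antipodal reflection pairs are excited more strongly than
#' the rest - and gives the domain profile the even-order azimuthal moment
#' required for a twofold pole density to couple to it.  It is used by
#' [scaling_experiment()] and breaks the 60 degree symmetry.
#'
#' @param lattice a [hex_lattice()].
#' @param orientation domain orientation `g` in radians.
#' @param grid a [polar_grid()].
#' @param sigma_q radial peak width in nm^-1.
#' @param sigma_phi azimuthal peak width in radians; values below half an
#'   azimuth bin are clamped (with a warning).
#' @param excitation twofold excitation weighting amplitude in `[0, 1]`.
#' @return a [polar_pattern()].
#' @export
domain_pattern <- function(lattice, orientation, grid, sigma_q = 0.03,
                           sigma_phi = 2 * pi / 180, excitation = 0) {
  stopifnot(inherits(lattice, "hex_lattice"), inherits(grid, "polar_grid"))
  if (sigma_q <= 0 || sigma_phi <= 0) stop("peak widths must be positive")
  if (sigma_phi < grid$dphi / 2) {
    warning("sigma_phi below half an azimuth bin; clamping")
    sigma_phi <- grid$dphi / 2
  }
  I <- matrix(0, grid$n_q, grid$n_phi)
  pk <- lattice$peaks
  for (i in seq_len(nrow(pk))) {
    radial <- exp(-(grid$q - pk$q[i])^2 / (2 * sigma_q^2))
    if (max(radial) < 1e-12) next
    w <- pk$rel[i] * (1 + excitation * cos(2 * pk$offset[i]))
    azim <- wrapped_gauss(grid$phi - orientation - pk$offset[i], sigma_phi)
    I <- I + w * outer(radial, azim)
  }
  polar_pattern(I, grid, meta = list(orientation = orientation))
}

#' Azimuthal profile of the (10) ring of one domain
#'
#' Fast single-ring version of [domain_pattern()] used by the scaling
#' experiments: the azimuthal intensity of the (10) reflection family only,
#' as a vector over the phi grid.
#'
#' @inheritParams domain_pattern
#' @return numeric vector of length `n_phi`.
#' @keywords internal
ring10_profile <- function(lattice, orientation, grid,
                           sigma_phi = 2 * pi / 180, excitation = 0) {
  off <- lattice$peaks$offset[lattice$peaks$hk == "10"]
  w <- 1 + excitation * cos(2 * off)
  out <- numeric(grid$n_phi)
  for (j in seq_along(off))
    out <- out + w[j] * wrapped_gauss(grid$phi - orientation - off[j], sigma_phi)
  out
}

#' Isotropic radial profile of a hexagonal phase
#'
#' Sum of Gaussian rings at the lattice peak positions with the lattice's
#' relative intensities; the `I0(q)` of the texture predictions and the
#' radial profile used by ring-mode simulations.
#'
#' @param lattice a [hex_lattice()].
#' @param q numeric vector of q values (nm^-1).
#' @param sigma_q radial width in nm^-1.
#' @return numeric vector of intensities.
#' @export
hex_ring_profile <- function(lattice, q, sigma_q = 0.05) {
  fams <- unique(lattice$peaks[, c("hk", "q", "rel")])
  out <- numeric(length(q))
  for (i in seq_len(nrow(fams)))
    out <- out + fams$rel[i] * exp(-(q - fams$q[i])^2 / (2 * sigma_q^2))
  out
}

#' Smooth ring pattern with azimuthal texture modulation
#'
#' The ring-modulation rendering mode: an azimuthally uniform pattern with
#' radial profile `ring_profile(q)` is modulated by the pole density,
#' `I(q, phi) = ring_profile(q) * 2*pi * density(phi; phi_max)`, emulating
#' the smooth many-domain rings of a textured mesophase.  Optional Poisson
#' noise is applied after scaling the pattern to `photon_scale` expected
#' total counts.
#'
#' @param ring_profile numeric vector of non-negative intensities over the
#'   grid's q values.
#' @param model an [orientation_model()].
#' @param phi_max modulation peak angle in radians.
#' @param grid a [polar_grid()].
#' @param photon_scale expected total photon count for Poisson noise, or
#'   `NULL` (default) for a noise-free pattern.
#' @return a [polar_pattern()]; `meta$phi_max` records the truth.
#' @export
ring_modulation_pattern <- function(ring_profile, model, phi_max, grid,
                                    photon_scale = NULL) {
  stopifnot(inherits(grid, "polar_grid"))
  if (length(ring_profile) != grid$n_q)
    stop("ring_profile must have one value per q bin")
  if (any(ring_profile < 0)) stop("ring_profile must be non-negative")
  I <- outer(ring_profile, 2 * pi * pole_density(model, grid$phi, phi_max))
  if (!is.null(photon_scale)) {
    tot <- sum(I)
    if (tot > 0) {
      scale <- photon_scale / tot
      I <- matrix(stats::rpois(length(I), I * scale), nrow(I), ncol(I)) / scale
    }
  }
  polar_pattern(I, grid, meta = list(phi_max = phi_max))
}

#' Simulation configuration
#'
#' @param n_domains average number of crystal domains per exposure (Nc >= 1).
#' @param n_patterns number of exposures (Nd >= 1).
#' @param sigma_q radial peak width, nm^-1.
#' @param sigma_phi azimuthal peak width, radians.
#' @param mode `"rings"` (smooth modulated rings) or `"domains"` (sum of
#'   `n_domains` discrete domain patterns per exposure).
#' @param photon_scale expected total counts for Poisson noise, or `NULL`.
#' @param seed integer master seed; per-exposure sub-seeds are derived by a
#'   counter so any single frame is reproducible.
#' @param excitation twofold excitation weighting for domain rendering
#'   (see [domain_pattern()]).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_domains = 10, n_patterns = 100, sigma_q = 0.05,
                       sigma_phi = 2 * pi / 180,
                       mode = c("rings", "domains"),
                       photon_scale = NULL, seed = 1, excitation = 0) {
  mode <- match.arg(mode)
  if (n_domains < 1 || n_patterns < 1) stop("n_domains and n_patterns must be >= 1")
  if (sigma_q <= 0 || sigma_phi <= 0) stop("widths must be positive")
  structure(list(n_domains = as.integer(n_domains),
                 n_patterns = as.integer(n_patterns),
                 sigma_q = sigma_q, sigma_phi = sigma_phi, mode = mode,
                 photon_scale = photon_scale, seed = as.integer(seed),
                 excitation = excitation),
            class = "sim_config")
}

# deterministic per-exposure sub-seed below 2^31
sub_seed <- function(seed, k) as.integer((seed + 747796405 * k) %% 2147483647L)

#' Simulate a textured diffraction ensemble
#'
#' Generates `n_patterns` exposures.  Each exposure draws its own preferred
#' angle `phi_max` uniformly on `[0, 2*pi)` (microtexture without
#' macrotexture: the ensemble-averaged azimuthal profile is flat).  In
#' `"rings"` mode each exposure is one [ring_modulation_pattern()] with the
#' lattice's isotropic radial profile; in `"domains"` mode each exposure sums
#' `n_domains` [domain_pattern()]s whose orientations are drawn from the pole
#' density at that exposure's `phi_max`.
#'
#' @param config a [sim_config()].
#' @param lattice a [hex_lattice()].
#' @param model an [orientation_model()].
#' @param grid a [polar_grid()].
#' @return list with `patterns` (list of [polar_pattern()]),
#'   `truth` (data frame: `exposure`, `phi_max`), `orientations` (list of
#'   per-exposure domain orientation vectors, `"domains"` mode only), and the
#'   inputs (`config`, `grid`).
#' @export
simulate_ensemble <- function(config, lattice, model, grid) {
  stopifnot(inherits(config, "sim_config"), inherits(lattice, "hex_lattice"),
            inherits(model, "orientation_model"), inherits(grid, "polar_grid"))
  n_d <- config$n_patterns
  patterns <- vector("list", n_d)
  orientations <- if (config$mode == "domains") vector("list", n_d) else NULL
  phi_max <- numeric(n_d)
  ring <- hex_ring_profile(lattice, grid$q, config$sigma_q)
  for (k in seq_len(n_d)) {
    set.seed(sub_seed(config$seed, k))
    phi_max[k] <- stats::runif(1, 0, 2 * pi)
    if (config$mode == "rings") {
      patterns[[k]] <- ring_modulation_pattern(ring, model, phi_max[k], grid,
                                               config$photon_scale)
    } else {
      g <- sample_orientations(model, config$n_domains, phi_max[k])
      I <- matrix(0, grid$n_q, grid$n_phi)
      for (gi in g)
        I <- I + domain_pattern(lattice, gi, grid, config$sigma_q,
                                config$sigma_phi, config$excitation)$intensity
      if (!is.null(config$photon_scale)) {
        scale <- config$photon_scale / sum(I)
        I <- matrix(stats::rpois(length(I), I * scale), nrow(I), ncol(I)) / scale
      }
      orientations[[k]] <- g
      patterns[[k]] <- polar_pattern(I, grid, meta = list(phi_max = phi_max[k]))
    }
    patterns[[k]]$meta$exposure <- k
  }
  list(patterns = patterns,
       truth = data.frame(exposure = seq_len(n_d), phi_max = phi_max),
       orientations = orientations, config = config, grid = grid)
}
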