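# Shared fixture builders (all fixtures are generated in code).

# small polar grid around the (10)/(11) rings of the default lattice
tiny_grid <- function(n_q = 8, n_phi = 16) {
  polar_grid(seq(1, 2.6, length.out = n_q), n_phi)
}

# deterministic pseudo-random pattern on a tiny grid
random_pattern <- function(seed = 1, n_q = 8, n_phi = 16, mask_frac = 0) {
  set.seed(seed)
  g <- tiny_grid(n_q, n_phi)
  I <- matrix(stats::runif(n_q * n_phi), n_q, n_phi)
  mask <- matrix(stats::runif(n_q * n_phi) >= mask_frac, n_q, n_phi)
  mask[, 1] <- TRUE                      # keep every row alive
  polar_pattern(I, g, mask = mask)
}

# brute-force mask-aware correlation oracle (direct double loop)
direct_correlation <- function(p) {
  I <- p$intensity * p$mask
  M <- p$mask
  n_q <- p$grid$n_q; n_phi <- p$grid$n_phi
  C <- array(NA_real_, c(n_q, n_q, n_phi))
  for (i in seq_len(n_q)) for (j in seq_len(n_q)) for (d in 0:(n_phi - 1)) {
    s <- 0; n <- 0
    for (ph in 0:(n_phi - 1)) {
      ph2 <- (ph + d) %% n_phi
      if (M[i, ph + 1] && M[j, ph2 + 1]) {
        s <- s + I[i, ph + 1] * I[j, ph2 + 1]
        n <- n + 1
      }
    }
    if (n > 0) C[i, j, d + 1] <- s / n
  }
  C
}

# synthetic detector image of a Gaussian ring at a given pixel radius
ring_image <- function(nx, ny, centre, radius_px, sigma_px = 2, amp = 1000) {
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  r <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
  amp * exp(-(r - radius_px)^2 / (2 * sigma_px^2))
}

# intensity-weighted radial centroid of a ring image
measure_ring_radius_px <- function(img, centre) {
  x <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  y <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  r <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
  sum(r * img) / sum(img)
}
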