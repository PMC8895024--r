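test_that("pole densities are valid probability densities", {
  phi <- 2 * pi * (0:4095) / 4096
  models <- list(orientation_model("uniform"),
                 orientation_model("sinusoidal", epsilon = 0.25),
                 orientation_model("sinusoidal", epsilon = 0.5),
                 orientation_model("lorentzian", gamma = 0.35),
                 orientation_model("lorentzian", gamma = 1.2))
  for (m in models) {
    for (pm in c(0, 1.1, 4.0)) {
      d <- pole_density(m, phi, pm)
      expect_true(all(d >= 0))
      expect_equal(mean(d) * 2 * pi, 1, tolerance = 1e-6)
      if (m$kind != "uniform") {
        # twofold: density(phi) == density(phi + pi)
        half <- length(phi) / 2
        expect_equal(d[1:half], d[(half + 1):length(phi)], tolerance = 1e-12)
      }
    }
  }
  expect_equal(pole_density(orientation_model("uniform"), 1.23), 1 / (2 * pi))
  m <- orientation_model("sinusoidal", epsilon = 0.25)
  expect_equal(pole_density(m, 0.7, phi_max = 0.7), 1.5 / (2 * pi))
  expect_error(orientation_model("sinusoidal", epsilon = 0.6), "negative")
})

test_that("sample_orientations draws from the stated densities", {
  set.seed(42)
  # uniform: chi-square over 36 bins at alpha = 0.01
  g <- sample_orientations(orientation_model("uniform"), 1e5, 0)
  counts <- tabulate(floor(g / (2 * pi) * 36) + 1, 36)
  chi2 <- sum((counts - 1e5 / 36)^2 / (1e5 / 36))
  expect_lt(chi2, qchisq(0.99, 35))

  # sinusoidal eps = 0: indistinguishable from uniform (KS)
  set.seed(43)
  g0 <- sample_orientations(orientation_model("sinusoidal", epsilon = 0), 5e3, 1)
  expect_gt(stats::ks.test(g0 / (2 * pi), "punif")$p.value, 0.01)

  # sinusoidal eps = 0.2: order-2 moment of the density is eps
  set.seed(44)
  pm <- 0.9
  g2 <- sample_orientations(orientation_model("sinusoidal", epsilon = 0.2),
                            1e5, pm)
  expect_lt(abs(mean(cos(2 * (g2 - pm))) - 0.2), 0.01)
})

test_that("domain_pattern renders the hexagonal peak geometry", {
  lat <- hex_lattice()
  # lattice invariants
  q <- unique(lat$peaks$q)
  expect_equal(q[2] / q[1], sqrt(3), tolerance = 1e-12)
  expect_equal(q[3] / q[1], 2, tolerance = 1e-12)

  grid <- polar_grid(seq(1, 2.8, length.out = 24), 360)
  p <- domain_pattern(lat, orientation = 0.4, grid)

  # 6 local maxima on the (10) ring
  iq <- which.min(abs(grid$q - lat$q10))
  ring <- p$intensity[iq, ]
  ext <- ring - pmax(c(ring[-1], ring[1]), c(ring[length(ring)], ring[-length(ring)]))
  expect_equal(sum(ext > 0), 6)

  # 60-degree rotation leaves the default pattern unchanged
  p60 <- domain_pattern(lat, orientation = 0.4 + pi / 3, grid)
  expect_lt(max(abs(p60$intensity - p$intensity)), 1e-10)

  # rendering equals a direct per-peak brute-force oracle
  oracle <- matrix(0, grid$n_q, grid$n_phi)
  for (i in seq_len(nrow(lat$peaks))) {
    pk <- lat$peaks[i, ]
    for (iq2 in seq_len(grid$n_q)) for (ip in seq_len(grid$n_phi)) {
      dph <- grid$phi[ip] - 0.4 - pk$offset
      dph <- abs(((dph + pi) %% (2 * pi)) - pi)
      oracle[iq2, ip] <- oracle[iq2, ip] + pk$rel *
        exp(-(grid$q[iq2] - pk$q)^2 / (2 * 0.03^2)) *
        exp(-dph^2 / (2 * (2 * pi / 180)^2))
    }
  }
  expect_equal(p$intensity, oracle, tolerance = 1e-10)

  # integrated family intensities track the stated relative intensities,
  # up to the (computable) radial discretisation of each ring
  win <- function(q0) abs(grid$q - q0) < 0.15
  rad <- function(q0) sum(exp(-(grid$q[win(q0)] - q0)^2 / (2 * 0.03^2)))
  ratio <- sum(p$intensity[win(lat$q10 * sqrt(3)), ]) /
    sum(p$intensity[win(lat$q10), ])
  want <- lat$rel_intensity[["11"]] * rad(lat$q10 * sqrt(3)) / rad(lat$q10)
  expect_equal(ratio, want, tolerance = 1e-6)

  expect_warning(domain_pattern(lat, 0, grid, sigma_phi = 1e-4), "clamping")
})

test_that("ring_modulation_pattern carries the density's Fourier content", {
  lat <- hex_lattice()
  grid <- polar_grid(seq(1, 2.6, length.out = 10), 180)
  prof <- hex_ring_profile(lat, grid$q)

  # eps = 0: azimuthally constant
  p0 <- ring_modulation_pattern(prof, orientation_model("sinusoidal", epsilon = 0),
                                0.3, grid)
  expect_lt(max(apply(p0$intensity, 1, stats::sd)), 1e-12)

  # sinusoidal eps = 0.1: order-2 / order-0 Fourier ratio = eps exactly
  p1 <- ring_modulation_pattern(prof, orientation_model("sinusoidal", epsilon = 0.1),
                                0.7, grid)
  iq <- which.max(prof)
  ring <- p1$intensity[iq, ]
  c0 <- mean(ring)
  c2 <- sqrt(mean(ring * cos(2 * grid$phi))^2 + mean(ring * sin(2 * grid$phi))^2) * 2
  expect_equal(c2 / c0 / 2, 0.1, tolerance = 1e-9)

  # lorentzian: order-4 content present
  p2 <- ring_modulation_pattern(prof, orientation_model("lorentzian", gamma = 0.35),
                                0.2, grid)
  ring2 <- p2$intensity[iq, ]
  c4 <- sqrt(mean(ring2 * cos(4 * grid$phi))^2 + mean(ring2 * sin(4 * grid$phi))^2) * 2
  expect_gt(c4 / mean(ring2), 1e-3)

  expect_error(ring_modulation_pattern(-prof, orientation_model("uniform"),
                                       0, grid), "non-negative")
})

test_that("simulate_ensemble is reproducible and macroscopically untextured", {
  lat <- hex_lattice()
  grid <- polar_grid(seq(1.2, 1.4, length.out = 3), 90)
  model <- orientation_model("sinusoidal", epsilon = 0.4)
  cfg <- sim_config(n_domains = 4, n_patterns = 12, mode = "domains", seed = 7)

  e1 <- simulate_ensemble(cfg, lat, model, grid)
  e2 <- simulate_ensemble(cfg, lat, model, grid)
  expect_identical(lapply(e1$patterns, `[[`, "intensity"),
                   lapply(e2$patterns, `[[`, "intensity"))
  expect_equal(nrow(e1$truth), 12)
  expect_equal(lengths(e1$orientations), rep(4, 12))

  # ring mode determinism too
  cfgr <- sim_config(n_patterns = 5, mode = "rings", seed = 3,
                     photon_scale = 1e6)
  r1 <- simulate_ensemble(cfgr, lat, model, grid)
  r2 <- simulate_ensemble(cfgr, lat, model, grid)
  expect_identical(r1$patterns[[5]]$intensity, r2$patterns[[5]]$intensity)

  # microtexture has no macrotexture: with random phi_max per exposure the
  # ensemble-mean ring is flat within sampling error
  cfgm <- sim_config(n_patterns = 400, mode = "rings", seed = 8)
  em <- simulate_ensemble(cfgm, lat, model, grid)
  iq <- 2
  avg <- rowMeans(vapply(em$patterns, function(p) p$intensity[iq, ],
                         numeric(grid$n_phi)))
  expect_lt(stats::sd(avg) / mean(avg), 0.05)
})

test_that("angular contrast averages down like sqrt(Nc)", {
  lat <- hex_lattice()
  grid <- polar_grid(lat$q10, 360)
  model <- orientation_model("uniform")
  contrast <- function(nc, n_pat = 30, seed = 21) {
    v <- vapply(seq_len(n_pat), function(k) {
      set.seed(seed + k)
      g <- sample_orientations(model, nc, 0)
      prof <- Reduce(`+`, lapply(g, function(gi)
        padftex:::ring10_profile(lat, gi, grid)))
      stats::sd(prof) / mean(prof)
    }, 0)
    mean(v)
  }
  ratio <- contrast(10) / contrast(1000)
  expect_equal(ratio, sqrt(100), tolerance = 0.25 * sqrt(100))
})
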