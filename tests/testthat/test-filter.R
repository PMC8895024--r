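test_that("radial_profile is the masked azimuthal mean", {
  g <- tiny_grid(3, 12)
  p <- polar_pattern(matrix(2.5, 3, 12), g)
  expect_equal(radial_profile(p), rep(2.5, 3))

  # sinusoidal modulation averages out exactly on a full circle
  lat <- hex_lattice()
  grid <- polar_grid(seq(1, 2.6, length.out = 6), 120)
  prof <- hex_ring_profile(lat, grid$q)
  pm <- ring_modulation_pattern(prof, orientation_model("sinusoidal",
                                                        epsilon = 0.3),
                                0.8, grid)
  expect_equal(radial_profile(pm), prof, tolerance = 1e-9)

  # brute-force per-bin mean on a random masked grid
  p2 <- random_pattern(seed = 9, mask_frac = 0.3)
  want <- sapply(seq_len(p2$grid$n_q), function(i)
    mean(p2$intensity[i, p2$mask[i, ]]))
  expect_equal(radial_profile(p2), want)
})

test_that("identify_phase recognises hexagonal peak ratios", {
  q <- seq(0.5, 3, length.out = 300)
  mkprof <- function(positions, heights = rep(1, length(positions)), noise = 0)
    Reduce(`+`, Map(function(p, h) h * exp(-(q - p)^2 / (2 * 0.02^2)),
                    positions, heights)) + noise

  ph <- identify_phase(mkprof(1.2 * c(1, sqrt(3), 2), c(1, 0.3, 0.1)), q)
  expect_equal(ph$phase, "hexagonal")
  expect_equal(ph$a, 4 * pi / (sqrt(3) * 1.2), tolerance = 0.01)

  # 1.30 ratio is not hexagonal at 2% tolerance
  expect_equal(identify_phase(mkprof(c(1.2, 1.56), c(1, 0.5)), q)$phase,
               "unknown")
  expect_equal(identify_phase(rep(0, 300), q)$phase, "empty")

  # noisy profile: lattice parameter recovered within 1%
  set.seed(77)
  noisy <- mkprof(1.2 * c(1, sqrt(3), 2), c(1, 0.3, 0.1),
                  noise = rnorm(300, 0, 0.02))
  phn <- identify_phase(noisy, q)
  expect_equal(phn$phase, "hexagonal")
  expect_lt(abs(phn$a - 4 * pi / (sqrt(3) * 1.2)) / phn$a, 0.01)
})

test_that("lattice_filter drops outliers and converges", {
  rec <- data.frame(a = c(rep(5, 99), 6))
  out <- lattice_filter(rec, tolerance = 0.05)
  expect_equal(sum(!out$keep), 1)
  expect_false(out$keep[100])

  # identical values all kept; second pass is a fixed point
  expect_true(all(lattice_filter(data.frame(a = rep(5, 10)))$keep))
  out2 <- lattice_filter(out, tolerance = 0.05)
  expect_identical(out2$keep, out$keep)

  # keep-set independent of record order
  perm <- sample(100)
  outp <- lattice_filter(rec[perm, , drop = FALSE], tolerance = 0.05)
  expect_identical(outp$keep, out$keep[perm])

  expect_error(lattice_filter(data.frame(a = c(1, 100)), tolerance = 0.05),
               "no consistent ensemble")
})

test_that("profile_agreement is the L1 relative residual", {
  ref <- c(1, 2, 3, 4)
  expect_equal(profile_agreement(ref, ref), 0)
  expect_equal(profile_agreement(2 * ref, ref), 1)
  expect_equal(profile_agreement(0.25 * ref, ref), 0.75)  # |c - 1| scaling
  set.seed(3)
  a <- runif(50); b <- runif(50) + 0.5
  expect_equal(profile_agreement(a, b), sum(abs(a - b)) / sum(b),
               tolerance = 1e-12)
  expect_error(profile_agreement(a, numeric(50)), "zero-norm")
  expect_error(profile_agreement(a, b[1:10]), "share one q grid")
})

test_that("azimuthal_orientation_fit recovers twofold modulations", {
  phi <- 360 * (0:359) / 360

  # flat ring: magnitude ~ 0, flagged unstable
  flat <- azimuthal_orientation_fit(rep(2, 360), phi)
  expect_false(flat$ok)
  expect_lt(abs(flat$magnitude), 1e-6)

  # 1 + 0.3 cos 2(phi - 40): phi_max = 40 +/- 1 bin, magnitude ~ 0.6
  ring <- 1 + 0.3 * cos(2 * (phi - 40) * pi / 180)
  fit <- azimuthal_orientation_fit(ring, phi)
  expect_true(fit$ok)
  expect_lt(abs(fit$phi_max - 40), 1)
  expect_equal(fit$magnitude, 0.6, tolerance = 0.05)

  # equivariance: rotating the ring rotates phi_max (mod 180), +/- 1 bin
  for (delta in c(25, 80, 155)) {
    ringd <- 1 + 0.3 * cos(2 * (phi - 40 - delta) * pi / 180)
    fd <- azimuthal_orientation_fit(ringd, phi)
    err <- abs(fd$phi_max - (40 + delta) %% 180)
    expect_lt(min(err, 180 - err), 1)
  }

  # 5% additive noise: median |phi_max error| < 3 degrees over 100 trials
  set.seed(55)
  errs <- replicate(100, {
    truth <- runif(1, 0, 180)
    r <- 1 + 0.3 * cos(2 * (phi - truth) * pi / 180) + rnorm(360, 0, 0.05)
    f <- azimuthal_orientation_fit(r, phi)
    e <- abs(f$phi_max - truth)
    min(e, 180 - e)
  })
  expect_lt(median(errs), 3)
})

test_that("build_orientation_map reproduces a two-region scan", {
  phi <- 360 * (0:119) / 120
  mkfit <- function(angle)
    azimuthal_orientation_fit(1 + 0.4 * cos(2 * (phi - angle) * pi / 180), phi)
  fits <- c(lapply(1:12, function(i) mkfit(30)),
            lapply(1:12, function(i) mkfit(120)))
  # row-major 4 x 6 scan: first two rows at 30 deg, last two at 120 deg
  m <- build_orientation_map(fits, c(4, 6))
  expect_equal(dim(m$phi_max), c(4, 6))
  expect_true(all(abs(m$phi_max[1:2, ] - 30) < 1))
  expect_true(all(abs(m$phi_max[3:4, ] - 120) < 1))
  expect_true(all(!m$omitted))

  # all-omitted scan
  bad <- replicate(6, list(magnitude = NA, phi_max = NA, ok = FALSE),
                   simplify = FALSE)
  mb <- build_orientation_map(bad, c(2, 3))
  expect_true(all(mb$omitted))
  expect_true(all(is.na(mb$phi_max)))
})

test_that("ensemble_filter ties the curation pipeline together", {
  lat_good <- hex_lattice(a = 5.0)
  lat_bad <- hex_lattice(a = 6.0)
  grid <- polar_grid(seq(0.8, 3.2, length.out = 160), 90)
  model <- orientation_model("sinusoidal", epsilon = 0.2)
  mk <- function(lat, pm) ring_modulation_pattern(
    hex_ring_profile(lat, grid$q, sigma_q = 0.03), model, pm, grid)
  pats <- c(lapply(seq_len(19), function(k) mk(lat_good, k)),
            list(mk(lat_bad, 0)))
  rec <- ensemble_filter(pats, lattice_tolerance = 0.05)
  expect_equal(sum(!rec$keep), 1)
  expect_false(rec$keep[20])
  expect_true(all(rec$phase == "hexagonal"))
  expect_equal(rec$a[1], 5.0, tolerance = 0.02)
})
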