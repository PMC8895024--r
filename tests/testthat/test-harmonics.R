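test_that("legendre_design evaluates the expected polynomials", {
  dphi <- 2 * pi * (0:359) / 360
  A <- legendre_design(dphi, c(0, 2, 4))
  expect_true(all(A[, 1] == 1))
  i90 <- which.min(abs(dphi - pi / 2))
  expect_equal(A[i90, 2], -0.5, tolerance = 1e-10)
  expect_equal(A[i90, 3], 0.375, tolerance = 1e-10)
  expect_error(legendre_design(dphi, c(1, 2)), "even")

  # ewald mapping reduces to small angle when q lambda / 4 pi << 1:
  # the mapped cos(theta3d) deviates from cos(dphi) by ~ 2 (q lambda/4 pi)^2
  q <- 1.0; lambda <- 0.6                      # q lambda/(4 pi) ~ 4.8e-3
  sa <- q * (lambda / 10) / (4 * pi)
  x3d <- sa^2 + (1 - sa^2) * cos(dphi)
  expect_lt(max(abs(x3d - cos(dphi))), 1e-4)
  Ae <- legendre_design(dphi, c(0, 2, 4), mapping = "ewald",
                        q = q, wavelength = lambda)
  expect_lt(max(abs(Ae - A)), 1e-3)
  expect_gt(max(abs(Ae - A)), 0)               # and is not the identity map
})

test_that("correlation_to_bl inverts band-limited volumes exactly", {
  g <- polar_grid(c(1, 1.5, 2), 60)

  # Legendre basis input recovers a single order
  Cb <- array(0, c(3, 3, 60))
  P2 <- legendre_table(2, cos(g$phi))
  Cb[2, 2, ] <- P2
  bl <- correlation_to_bl(correlation_volume(Cb, g), l_max = 8)
  expect_equal(bl$matrices$l2[2, 2], 1, tolerance = 1e-10)
  for (l in c(0, 4, 6, 8))
    expect_lt(max(abs(bl$matrices[[paste0("l", l)]])), 1e-8)

  # cos 2 dphi = (4 P2 - 1)/3: B2/B0 = -4 (quadrature oracle frozen)
  Cc <- array(0, c(3, 3, 60)); Cc[1, 1, ] <- cos(2 * g$phi)
  blc <- correlation_to_bl(correlation_volume(Cc, g), l_max = 8)
  expect_equal(blc$matrices$l2[1, 1] / blc$matrices$l0[1, 1], -4,
               tolerance = 1e-8)
  expect_lt(abs(blc$matrices$l4[1, 1]), 1e-10)

  # synthesis round trip on a random band-limited volume
  set.seed(6)
  ls <- seq(0, 8, 2)
  mats <- lapply(ls, function(l) { m <- matrix(rnorm(9), 3); (m + t(m)) / 2 })
  bl0 <- bl_matrices(ls, mats, g$q)
  vol <- bl_to_correlation(bl0, g)
  bl1 <- correlation_to_bl(vol, l_max = 8)
  for (i in seq_along(ls))
    expect_equal(bl1$matrices[[i]], bl0$matrices[[i]], tolerance = 1e-8)
  vol2 <- bl_to_correlation(bl1, g)
  expect_lt(max(abs(vol2$values - vol$values)), 1e-8)

  # masked-entry path: NA lags at one (q, q') still invert
  Cm <- vol$values; Cm[1, 2, 5:10] <- NA; Cm[2, 1, c(1, 57:60)] <- NA
  blm <- correlation_to_bl(correlation_volume(Cm, g), l_max = 8)
  expect_equal(blm$matrices$l2[1, 2], bl0$matrices[[2]][1, 2],
               tolerance = 1e-6)
})

test_that("Parseval-style power consistency for band-limited volumes", {
  set.seed(8)
  g <- polar_grid(c(1, 2), 360)
  ls <- c(2, 4, 6)
  mats <- lapply(ls, function(l) { m <- matrix(rnorm(4), 2); (m + t(m)) / 2 })
  vol <- bl_to_correlation(bl_matrices(ls, mats, g$q), g)
  # with the Legendre measure |sin dphi|:
  # int C^2 |sin| ddphi = 4 sum_l ||B_l||^2 / (2l + 1)
  w <- abs(sin(g$phi)) * (2 * pi / g$n_phi)
  total_var <- sum(apply(vol$values, c(1, 2), function(y) sum(y^2 * w)))
  want <- 4 * sum(vapply(seq_along(ls), function(i)
    sum(mats[[i]]^2) / (2 * ls[i] + 1), 0))
  expect_equal(total_var, want, tolerance = 0.01 * want)
})

test_that("bl_power normalises to the l = 2 term", {
  g <- polar_grid(c(1, 2), 60)
  mats <- list(matrix(0, 2, 2), diag(2), 0.1 * diag(2))
  bl <- bl_matrices(c(0, 2, 4), mats, g$q)
  pw <- bl_power(bl)
  expect_true(is.na(pw$fraction[pw$l == 0]))
  expect_equal(pw$fraction[pw$l == 2], 1)
  expect_equal(pw$fraction[pw$l == 4], 0.01)
  bl0 <- bl_matrices(c(0, 4), mats[1:2], g$q)
  expect_error(bl_power(bl0), "l = 2")
})

test_that("pole_to_ql projects density modulations correctly", {
  expect_true(all(abs(pole_to_ql(orientation_model("uniform"))$Q[-1]) < 1e-12))

  # linear in epsilon
  q1 <- pole_to_ql(orientation_model("sinusoidal", epsilon = 0.1))
  q2 <- pole_to_ql(orientation_model("sinusoidal", epsilon = 0.2))
  expect_equal(q2$Q[q2$l == 2], 2 * q1$Q[q1$l == 2], tolerance = 1e-9)
  # closed form: m = 2 eps (2x^2 - 1), so Q2 = (5/2) eps int (6x^4 - 5x^2 + 1)
  # = 8 eps / 3, all other even orders zero
  expect_equal(q1$Q[q1$l == 2], 8 * 0.1 / 3, tolerance = 1e-5)
  expect_lt(abs(q1$Q[q1$l == 4]), 1e-5)

  ql <- pole_to_ql(orientation_model("lorentzian", gamma = 0.35))
  v <- abs(ql$Q[match(c(2, 4, 6), ql$l)])
  expect_true(all(v > 1e-4))
  expect_true(all(diff(v) < 0))
})

test_that("texture and nanostructure predictions scale as Nc^2 and Nc", {
  lat <- hex_lattice()
  q <- seq(1, 2.6, length.out = 5)
  prof <- hex_ring_profile(lat, q)

  spec_u <- pole_to_ql(orientation_model("uniform"))
  bt_u <- predict_texture_bl(spec_u, prof, q, n_c = 50)
  expect_true(all(vapply(bt_u$matrices, function(m) max(abs(m)), 0) < 1e-20))

  spec <- pole_to_ql(orientation_model("sinusoidal", epsilon = 0.1))
  bt1 <- predict_texture_bl(spec, prof, q, n_c = 50)
  bt2 <- predict_texture_bl(spec, prof, q, n_c = 100)
  expect_equal(bt2$matrices$l2, 4 * bt1$matrices$l2, tolerance = 1e-12)
  # sinusoidal: only Q2 nonzero, so fraction(4) vanishes
  expect_lt(sum(bt1$matrices$l4^2) / sum(bt1$matrices$l2^2), 1e-6)

  # nanostructure: linear in n_c, identity at n_c = 1
  single <- domain_pattern(lat, 0.3, polar_grid(q, 360))
  bc <- correlation_to_bl(correlate_stack(list(single)), l_max = 8)
  expect_identical(predict_nanostructure_bl(bc, 1)$matrices, bc$matrices)
  expect_equal(predict_nanostructure_bl(bc, 4)$matrices$l6,
               4 * bc$matrices$l6)
  # single hexagonal domain: 60-degree comb spreads power over even l
  pw <- bl_power(bc)
  expect_gt(pw$power[pw$l == 6], 0)
})

test_that("balance_ratio is linear in Nc with a well-defined crossover", {
  lat <- hex_lattice()
  q <- seq(1, 2.6, length.out = 5)
  prof <- hex_ring_profile(lat, q)
  single <- domain_pattern(lat, 0.3, polar_grid(q, 360))
  bc1 <- correlation_to_bl(correlate_stack(list(single)), l_max = 8)
  spec <- pole_to_ql(orientation_model("sinusoidal", epsilon = 0.1))

  r1 <- balance_ratio(predict_texture_bl(spec, prof, q, 10),
                      predict_nanostructure_bl(bc1, 10), 10)
  r2 <- balance_ratio(predict_texture_bl(spec, prof, q, 20),
                      predict_nanostructure_bl(bc1, 20), 20)
  expect_equal(r2$ratio / r1$ratio, 2, tolerance = 1e-10)
  expect_equal(r1$crossover_nc, r2$crossover_nc, tolerance = 1e-6)

  # zero texture
  r0 <- balance_ratio(predict_texture_bl(pole_to_ql(orientation_model("uniform")),
                                         prof, q, 10),
                      predict_nanostructure_bl(bc1, 10), 10)
  expect_equal(r0$ratio, 0)
})

test_that("scaling_experiment validates inputs and fits both components", {
  expect_error(scaling_experiment(c(8, 8), orientation_model("uniform")),
               "3 distinct")
  # scaled-down run: strong texture so all points are signal-dominated
  model <- orientation_model("sinusoidal", epsilon = 0.4)
  res <- scaling_experiment(c(4, 16, 64), model, n_patterns = 60, seed = 12)
  expect_equal(res$nano_slope, 1, tolerance = 0.05)
  expect_equal(res$texture_slope, 2, tolerance = 0.3)
  expect_equal(nrow(res$table), 3)
})
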