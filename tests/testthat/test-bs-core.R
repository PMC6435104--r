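pr_I <- oracle_protocol()         # standard resolution reference protocol
proto_I <- protocol_preset("I")

test_that("echo-shift factor matches the scalar oracle on both branches", {
  expect_equal(q_factor(0, proto_I), 1)
  expect_equal(bs_relative(0, 0, 0, proto_I)$local_te, proto_I$te0)
  for (g in c(-80, -25, 10, 50, 120)) {
    expect_equal(q_factor(g, proto_I, "positive"),
                 oracle_q(g, pr_I, "positive"))
    expect_equal(q_factor(g, proto_I, "negative"),
                 oracle_q(g, pr_I, "negative"))
  }
  ## the worked case: 50 uT/m at positive polarity
  q <- q_factor(50, proto_I, "positive")
  expect_equal(q, 0.7956, tolerance = 1e-4)
  expect_equal(proto_I$te0 / q, 37.7e-3, tolerance = 1e-3)
  expect_equal(q_factor(50, proto_I, "negative"), 2 - q)  # mirror branch
})

test_that("through-plane attenuation follows the Gaussian-profile formula", {
  expect_equal(through_plane_attenuation(0, 0, proto_I), 1)
  ## perfect compensation: M = -G_SL * TE cancels the dephasing
  g_sl <- -40
  m_comp <- -g_sl * 1e-6 * proto_I$te0 * 1e6  # mT/m*ms
  expect_equal(through_plane_attenuation(g_sl, m_comp, proto_I), 1)
  ## net moment of 1 mT/m*ms at 3 mm slices
  expect_equal(through_plane_attenuation(0, 1, proto_I),
               oracle_attenuation(0, 1, pr_I$te0, pr_I))
  expect_equal(through_plane_attenuation(0, 1, proto_I), 0.920,
               tolerance = 1e-3)
  ## configurable profile constant
  alt <- bs_config(profile_constant = 4 * sqrt(log(2)))
  expect_equal(through_plane_attenuation(0, 1, proto_I, config = alt),
               oracle_attenuation(0, 1, pr_I$te0, pr_I, 4 * sqrt(log(2))))
})

test_that("dropout triggers exactly at the acquisition-window bounds", {
  expect_false(dropout(0, 0, proto_I))
  ## RO bound at nominal TE: pi / (dx * gamma * TE0)
  g_crit_ro <- pi / (pr_I$dx * ORACLE_GAMMA * pr_I$te0) * 1e6
  cfg_nom <- bs_config(dropout_te_mode = "nominal")
  expect_false(dropout(0, g_crit_ro - 0.01, proto_I, config = cfg_nom))
  expect_true(dropout(0, g_crit_ro + 0.01, proto_I, config = cfg_nom))
  expect_equal(g_crit_ro, 130.5, tolerance = 1e-3)
  ## local mode: positive G_PE prolongs TE, tightening the RO bound
  g_pe <- 50
  te_loc <- pr_I$te0 / oracle_q(g_pe, pr_I, "positive")
  g_crit_loc <- pi / (pr_I$dx * ORACLE_GAMMA * te_loc) * 1e6
  expect_false(dropout(g_pe, g_crit_loc - 0.01, proto_I))
  expect_true(dropout(g_pe, g_crit_loc + 0.01, proto_I))
  ## PE bound from Eq.-(6)-style algebra: q at TE0 + TA/2
  q_edge <- pr_I$te0 / (pr_I$te0 + pr_I$ta / 2)
  g_edge <- (1 - q_edge) / (ORACLE_GBAR * pr_I$dt * pr_I$fov) * 1e6
  expect_false(dropout(g_edge - 0.01, 0, proto_I))
  expect_true(dropout(g_edge + 0.01, 0, proto_I))
  ## q <= 0 is routed to dropout, not an error
  g_total <- 1 / (ORACLE_GBAR * pr_I$dt * pr_I$fov) * 1e6
  expect_true(dropout(g_total + 1, 0, proto_I))
  expect_equal(bs_relative(0, g_total + 1, 0, proto_I)$bs, 0)
})

test_that("voxel BS chains the oracles and can exceed 1", {
  v0 <- voxel_bs(0, 0, 0, proto_I)
  expect_equal(v0$bs_rel, 1)
  expect_false(v0$dropped)

  ## 50 uT/m PE gradient, net slice moment 1 mT/m*ms after compensation:
  ## local-TE prolongation raises BS above 1 despite the dephasing loss
  g_pe <- 50
  q <- oracle_q(g_pe, pr_I, "positive")
  te <- pr_I$te0 / q
  g_sl <- -30
  m <- 1 - g_sl * 1e-6 * te * 1e6          # net moment 1 mT/m*ms at local TE
  expected <- q^-2 * exp(-(te - pr_I$te0) / pr_I$t2s) *
    oracle_attenuation(g_sl, m, te, pr_I)
  v <- voxel_bs(0, g_pe, g_sl, proto_I, adjustable_params(zshim = m))
  expect_equal(v$bs_rel, expected, tolerance = 1e-12)
  expect_gt(v$bs_rel, 1.2)
  expect_equal(v$bs_rel, 1.25, tolerance = 0.01)

  ## dropout cases give exactly zero
  expect_identical(voxel_bs(200, 0, 0, proto_I)$bs_rel, 0)
})

test_that("well-shimmed loss depends only on |zshim|", {
  expect_equal(wellshimmed_loss(adjustable_params(), proto_I), 0)
  for (m in c(0.5, 1, 2.5)) {
    lp <- wellshimmed_loss(adjustable_params(zshim = m), proto_I)
    ln <- wellshimmed_loss(adjustable_params(zshim = -m), proto_I)
    expect_equal(lp, ln)
    lt <- wellshimmed_loss(adjustable_params(zshim = m, tilt = 30,
                                             polarity = "negative"), proto_I)
    expect_equal(lp, lt)
  }
  expect_equal(wellshimmed_loss(adjustable_params(zshim = 1), proto_I),
               0.080, tolerance = 1e-2)
})

test_that("symmetric percent gain has the documented fixed points", {
  expect_equal(bs_gain(1, 1), 0)
  expect_equal(bs_gain(0, 2), -200)
  expect_equal(bs_gain(2, 0), 200)
  expect_equal(bs_gain(1.5, 1), 40)
  expect_true(is.na(bs_gain(0, 0)))
  set.seed(3)
  b <- runif(100); r <- runif(100)
  expect_true(all(bs_gain(b, r) >= -200 & bs_gain(b, r) <= 200))
})

test_that("PE-flip antisymmetry holds to machine precision", {
  set.seed(11)
  n <- 2000
  g_pe <- runif(n, -150, 150)
  g_ro <- runif(n, -80, 80)
  g_sl <- runif(n, -80, 80)
  pos <- bs_relative(g_ro, g_pe, g_sl, proto_I, zshim = 0.5,
                     polarity = "positive")
  neg <- bs_relative(g_ro, -g_pe, g_sl, proto_I, zshim = 0.5,
                     polarity = "negative")
  expect_identical(pos$bs, neg$bs)
  expect_identical(pos$q, neg$q)
})

test_that("BS over shim moment is a Gaussian peaking at -G_SL*TE0", {
  g_sl <- -25
  m_star <- -g_sl * 1e-6 * pr_I$te0 * 1e6   # closed-form optimum, mT/m*ms
  m_grid <- seq(-3, 3, by = 0.001)
  bs <- vapply(m_grid, function(m) {
    bs_relative(0, 0, g_sl, proto_I, zshim = m)$bs
  }, numeric(1))
  expect_equal(m_grid[which.max(bs)], m_star, tolerance = 2e-3)
  expect_equal(max(bs), 1)
  ## symmetric about the optimum
  bs_l <- bs_relative(0, 0, g_sl, proto_I, zshim = m_star - 0.7)$bs
  bs_r <- bs_relative(0, 0, g_sl, proto_I, zshim = m_star + 0.7)$bs
  expect_equal(bs_l, bs_r, tolerance = 1e-12)
})

test_that("with no dephasing and infinite T2*, BS reduces to 1/q^2", {
  proto_inf <- protocol_preset("I", t2star = 1e9)
  for (g in c(-60, -10, 30, 90)) {
    r <- bs_relative(0, g, 0, proto_inf)
    if (!r$dropped) {
      expect_equal(r$bs, oracle_q(g, pr_I, "positive")^-2, tolerance = 1e-6)
    }
  }
})

test_that("difference stats summarise the voxel-wise gain mismatch", {
  dims <- c(10, 10, 10)
  a <- array(rnorm(1000), dims)
  mask <- array(TRUE, dims)
  s0 <- bs_difference_stats(a, a, mask)
  expect_equal(s0$mean, 0)
  expect_equal(s0$sd, 0)
  s5 <- bs_difference_stats(a + 5, a, mask)
  expect_equal(s5$mean, 5)
  expect_equal(s5$sd, 0)
  set.seed(21)
  noise <- array(rnorm(1e4, 0, 10), c(100, 10, 10))
  sn <- bs_difference_stats(noise, array(0, dim(noise)),
                            array(TRUE, dim(noise)))
  expect_lt(abs(sn$mean), 3 * 10 / sqrt(1e4))
  expect_equal(sn$sd, 10, tolerance = 0.05)
  expect_identical(sum(sn$histogram$count), 10000L)
  expect_error(bs_difference_stats(a, a, array(FALSE, dims)), "empty mask")
})

test_that("experimental BS recovers uniform and line-shifted echoes", {
  er <- effective_readout(proto_I)
  n <- er$acquired_lines
  dims <- c(n, 8, 2)
  vox <- c(3, 3, 3)
  mag <- field_map(array(2, dims), vox)
  ## uniform phase: local TE = TE0, BS = TE0 * I
  flat <- experimental_bs(mag, field_map(array(0.3, dims), vox), proto_I,
                          "positive", pe_axis = 1)
  expect_equal(flat$local_te$values, array(proto_I$te0, dims))
  expect_equal(flat$bs$values, array(proto_I$te0 * 2, dims))

  ## a k-space echo shifted by exactly 2 lines is an image phase ramp of
  ## 2*pi*2/N per PE voxel
  ramp <- array(((seq_len(n) - 1) * 2 * pi * 2 / n) %% (2 * pi), dims)
  shifted <- experimental_bs(mag, field_map(ramp, vox), proto_I,
                             "positive", pe_axis = 1)
  te_expected <- proto_I$te0 + 2 * er$echo_spacing_eff
  interior <- shifted$local_te$values[2:(n - 2), , ]
  expect_equal(interior, array(te_expected, dim(interior)),
               tolerance = 1e-10)
  ## negative polarity flips the sign of the shift
  shifted_neg <- experimental_bs(mag, field_map(ramp, vox), proto_I,
                                 "negative", pe_axis = 1)
  expect_equal(shifted_neg$local_te$values[5, 1, 1],
               proto_I$te0 - 2 * er$echo_spacing_eff, tolerance = 1e-10)

  expect_error(experimental_bs(mag, field_map(array(0, c(n, 8, 3)), vox),
                               proto_I), "geometry")
})
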