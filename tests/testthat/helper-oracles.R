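## Independent oracles: scalar arithmetic re-implementations of the physics
## and a naive exhaustive optimizer, sharing no code with the package paths
## they check. Constants are written out literally on purpose.

ORACLE_GAMMA <- 2.6753e8                 # rad/s/T
ORACLE_GBAR <- 2.6753e8 / (2 * pi)       # Hz/T

## protocol constants as a plain list in SI units
oracle_protocol <- function(te0_ms = 30, dt_ms = 0.5, lines = 64,
                            fov_mm = 192, dx_mm = 3, dz_mm = 3,
                            t2s_ms = 50) {
  list(te0 = te0_ms * 1e-3, dt = dt_ms * 1e-3, lines = lines,
       fov = fov_mm * 1e-3, dx = dx_mm * 1e-3, dz = dz_mm * 1e-3,
       t2s = t2s_ms * 1e-3, ta = lines * dt_ms * 1e-3)
}

oracle_q <- function(g_pe_uTm, pr, polarity) {
  s <- if (polarity == "positive") -1 else 1
  1 + s * ORACLE_GBAR * pr$dt * pr$fov * g_pe_uTm * 1e-6
}

oracle_attenuation <- function(g_sl_uTm, zshim, te_s, pr,
                               const = 4 * log(2)) {
  psi <- ORACLE_GAMMA * pr$dz / const *
    (g_sl_uTm * 1e-6 * te_s + zshim * 1e-6)
  exp(-psi^2)
}

oracle_dropped <- function(g_pe, g_ro, pr, polarity) {
  q <- oracle_q(g_pe, pr, polarity)
  if (q <= 0) return(TRUE)
  te <- pr$te0 / q
  if (te < pr$te0 - pr$ta / 2 || te > pr$te0 + pr$ta / 2) return(TRUE)
  abs(ORACLE_GAMMA * te * g_ro * 1e-6) > pi / pr$dx
}

oracle_bs <- function(g_ro, g_pe, g_sl, zshim, polarity, pr,
                      const = 4 * log(2)) {
  if (oracle_dropped(g_pe, g_ro, pr, polarity)) return(0)
  q <- oracle_q(g_pe, pr, polarity)
  te <- pr$te0 / q
  q^-2 * exp(-(te - pr$te0) / pr$t2s) * oracle_attenuation(g_sl, zshim, te, pr,
                                                           const)
}

## vectorized-over-voxels variant used inside the exhaustive triple loop
oracle_bs_vec <- function(g_ro, g_pe, g_sl, zshim, polarity, pr,
                          const = 4 * log(2)) {
  q <- oracle_q(g_pe, pr, polarity)
  te <- ifelse(q > 0, pr$te0 / q, NA_real_)
  dropped <- q <= 0 | te < pr$te0 - pr$ta / 2 | te > pr$te0 + pr$ta / 2 |
    abs(ORACLE_GAMMA * ifelse(is.na(te), pr$te0, te) * g_ro * 1e-6) >
      pi / pr$dx
  psi <- ORACLE_GAMMA * pr$dz / const *
    (g_sl * 1e-6 * ifelse(is.na(te), pr$te0, te) + zshim * 1e-6)
  bs <- q^-2 * exp(-(te - pr$te0) / pr$t2s) * exp(-psi^2)
  bs[dropped] <- 0
  bs
}

## slice-frame projection for transverse acquisitions, written from the
## stated convention (positive tilt tips the anterior edge towards the feet)
oracle_project_transverse <- function(gx, gy, gz, tilt_deg) {
  th <- tilt_deg * pi / 180
  ## e_pe = (0, -cos t, sin t); e_sl = (0, sin t, cos t); e_ro = (1, 0, 0)
  list(g_ro = gx,
       g_pe = -gy * cos(th) + gz * sin(th),
       g_sl = gy * sin(th) + gz * cos(th))
}

## exhaustive triple loop over z-shim x tilt x polarity for transverse
## acquisitions, with the documented tie-break (smallest |zshim|, then
## smallest |tilt|, then positive polarity, positive values first)
oracle_optimize <- function(gx, gy, gz, pr, zshims, tilts, polarities,
                            max_loss = 0.15) {
  n <- length(gx)
  best_bs <- rep(-Inf, n)
  best <- data.frame(zshim = rep(NA_real_, n), tilt = NA_real_,
                     polarity = NA_character_, stringsAsFactors = FALSE)
  sets <- expand.grid(zshim = zshims, tilt = tilts, polarity = polarities,
                      stringsAsFactors = FALSE)
  ord <- order(abs(sets$zshim), abs(sets$tilt),
               match(sets$polarity, c("positive", "negative")),
               -sets$zshim, -sets$tilt)
  sets <- sets[ord, ]
  for (r in seq_len(nrow(sets))) {
    m <- sets$zshim[r]
    loss <- 1 - oracle_bs(0, 0, 0, m, "positive", pr)
    if (loss > max_loss + 1e-12) next
    p <- oracle_project_transverse(gx, gy, gz, sets$tilt[r])
    bs <- oracle_bs_vec(p$g_ro, p$g_pe, p$g_sl, m, sets$polarity[r], pr)
    upd <- bs > best_bs
    best_bs[upd] <- bs[upd]
    best$zshim[upd] <- m
    best$tilt[upd] <- sets$tilt[r]
    best$polarity[upd] <- sets$polarity[r]
  }
  best$bs <- best_bs
  best
}

## small helpers for building in-memory gradient fields in tests
make_gf <- function(gx, gy, gz, voxel_size = c(3, 3, 3), mask = NULL) {
  structure(list(gx = gx, gy = gy, gz = gz, voxel_size = voxel_size,
                 axes = c("x", "y", "z"), mask = mask),
            class = "gradient_field")
}

## a compact phantom for optimizer tests: a box of voxels whose gradient
## vectors are drawn smoothly, scaled to stay mostly inside the dropout region
test_gradient_box <- function(dims = c(10, 10, 10), scale = 60, seed = 42) {
  set.seed(seed)
  n <- prod(dims)
  smooth3 <- function() {
    a <- array(stats::rnorm(n), dims)
    (a + 0.5 * (a[c(1, seq_len(dims[1] - 1)), , ] +
                  a[, c(1, seq_len(dims[2] - 1)), ])) / 2
  }
  make_gf(scale * smooth3() / 2, scale * smooth3() / 2, scale * smooth3() / 2,
          voxel_size = c(3, 3, 3))
}

expect_same_optimum <- function(vw, oracle, mask_idx) {
  expect_equal(as.vector(vw$zshim)[mask_idx], oracle$zshim)
  expect_equal(as.vector(vw$tilt)[mask_idx], oracle$tilt)
  expect_equal(ifelse(as.vector(vw$polarity)[mask_idx] > 0, "positive",
                      "negative"), oracle$polarity)
  expect_equal(as.vector(vw$bs_opt)[mask_idx], oracle$bs, tolerance = 1e-12)
}
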