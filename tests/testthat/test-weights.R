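test_that("smooth transition function matches its closed form", {
  expect_equal(smooth_s(0), 0)
  expect_equal(smooth_s(1), 1)
  expect_equal(smooth_s(-1), -1)
  expect_equal(smooth_s(0.5), sin(pi / 4))
  expect_equal(smooth_s(3), 1)   # clamped
  expect_equal(smooth_s(-7), -1)
})

test_that("offset-detector weight is piecewise correct and complementary", {
  gm <- 0.22
  wp <- weight_params(gm, gamma_t = 0.15, gamma_s = 0.06)
  # fully truncated side
  expect_equal(offset_detector_weight(wp, c(-0.22, -0.151, -0.15)),
               c(0, 0, 0), tolerance = 1e-12)
  # center is self-complementary
  expect_equal(offset_detector_weight(wp, 0), 0.5)
  # plateau 1/2 on (-gamma_s, gamma_s), 1 beyond +gamma_t
  expect_equal(offset_detector_weight(wp, c(-0.05, 0.05)), c(0.5, 0.5))
  expect_equal(offset_detector_weight(wp, c(0.151, 0.2)), c(1, 1))
  # continuity at the break points
  eps <- 1e-9
  for (gbp in c(-0.15, -0.06, 0, 0.06, 0.15)) {
    expect_equal(offset_detector_weight(wp, gbp - eps),
                 offset_detector_weight(wp, gbp + eps), tolerance = 1e-6)
  }
  # pair sums are exactly 1
  set.seed(1)
  gam <- runif(200, -gm, gm)
  expect_lt(max(abs(offset_detector_weight(wp, gam) +
                    offset_detector_weight(wp, -gam) - 1)), 1e-12)

  # literal printed quarter-scale: w_L in {0, 1/4(1+s), 1/2}, w_R = 2 - w_L(-g),
  # pair sums 2
  wl <- weight_params(gm, gamma_t = 0.15, gamma_s = 0.06,
                      normalization = "literal")
  expect_equal(offset_detector_weight(wl, -0.02), 0.5)
  expect_equal(offset_detector_weight(wl, 0.2), 2)
  expect_lt(max(abs(offset_detector_weight(wl, gam) +
                    offset_detector_weight(wl, -gam) - 2)), 1e-12)
  expect_error(weight_params(gm, gamma_t = 0.1, gamma_s = 0.2))
})

test_that("Parker weight satisfies pair sums, boundary continuity, plateau", {
  gm <- 0.218
  for (arc_deg in c(206, 240, 270, 330)) {
    arc <- arc_deg * pi / 180
    set.seed(arc_deg)
    b <- runif(3000, 0, arc); g <- runif(3000, -gm, gm)
    w1 <- parker_weight(b, g, arc, gm)
    bc <- b + pi + 2 * g
    paired <- bc <= arc
    w2 <- parker_weight(bc[paired], -g[paired], arc, gm)
    expect_lt(max(abs(w1[paired] + w2 - 1)), 1e-12)
    # rays with no acquired complement carry full weight
    unpaired <- bc > arc & (b - pi + 2 * g) < 0
    expect_true(all(w1[unpaired] == 1))
    # boundary continuity: weight vanishes at the arc ends
    gg <- seq(-gm + 1e-3, gm - 1e-3, length.out = 50)
    expect_lt(max(parker_weight(rep(1e-9, 50), gg, arc, gm)), 1e-3)
    expect_lt(max(parker_weight(rep(arc - 1e-9, 50), gg, arc, gm)), 1e-3)
    expect_true(all(w1 >= 0 & w1 <= 1))
  }
  # half-weight plateau appears exactly under over-scan: its width per fan
  # angle is the over-scan amount arc - (pi + 2 gm)
  arc_min <- pi + 2 * gm
  bgrid <- seq(0, arc_min, length.out = 4001)
  w_min <- parker_weight(bgrid, 0.05, arc_min, gm)
  expect_lt(sum(abs(w_min - 0.5) < 1e-9) / length(bgrid), 0.001)
  arc_over <- arc_min + 30 * pi / 180
  bgrid2 <- seq(0, arc_over, length.out = 4001)
  w_over <- parker_weight(bgrid2, 0.05, arc_over, gm)
  plateau_frac <- sum(abs(w_over - 0.5) < 1e-9) / length(bgrid2)
  expect_gt(plateau_frac * arc_over, 0.9 * (30 * pi / 180))
  # full scan: constant 1/2 (no arc boundary, pure redundancy averaging)
  expect_true(all(parker_weight(seq(0, 2 * pi, length.out = 100), 0.1,
                                2 * pi, gm) == 0.5))
  expect_error(parker_weight(0.1, 0, pi, gm), "insufficient")
})

test_that("weight maps satisfy the unit pair-sum condition on dense grids", {
  g <- centered_geom(scale = 8, n_views = 120)
  wp <- parker_weight_map(g, 270)
  expect_lt(verify_complementarity(wp, method = "analytic"), 1e-6)
  wo <- offset_weight_map(g, n_trunc_cols = 32)
  expect_lt(verify_complementarity(wo, method = "analytic"), 1e-12)
  expect_lt(verify_complementarity(wo, method = "interp"), 1e-12)
  # all-0.5 map on a full scan: deviation 0
  w360 <- parker_weight_map(g, 360)
  expect_true(all(w360$w == 0.5))
  expect_lt(verify_complementarity(w360, method = "interp"), 1e-12)
  # the product of both weights breaks complementarity (the failing baseline)
  wb <- combined_weight_map(wp, wo)
  expect_gt(verify_complementarity(wb, method = "analytic"), 0.2)
  # interpolated-map deviation for the Parker family is limited by the
  # transition width (gamma_max - gamma) versus the view spacing; with a
  # dense view grid and away from the outermost columns the lookup agrees
  # with the analytic family
  gd <- centered_geom(scale = 8, n_views = 600)
  wpd <- parker_weight_map(gd, 270)
  lk <- cbctafn:::.lookup_weight
  gam <- gamma_of_column(gd)
  inner <- gam[abs(gam) < 0.5 * gamma_max(gd)]
  set.seed(4)
  bs <- pi / 2 - 0.45 * pi + runif(400) * 0.9 * pi  # mid-arc views
  gs <- sample(inner, 400, TRUE)
  expect_lt(max(abs(lk(wpd, bs, gs) -
                    cbctafn:::.weight_fun(wpd, bs, gs))), 0.02)
  expect_error(parker_weight_map(g, 190))
})

test_that("insufficient-arc and grid-mismatch inputs error", {
  g <- centered_geom(scale = 16, n_views = 30)
  expect_error(parker_weight_map(g, 200))
  g2 <- centered_geom(scale = 8, n_views = 30)
  expect_error(combined_weight_map(parker_weight_map(g, 270),
                                   offset_weight_map(g2, n_trunc_cols = 8)))
})

test_that("unit-pair weighted full-scan FDK equals unweighted FDK", {
  sc <- sphere_scene()
  w360 <- parker_weight_map(sc$geom, 360)
  rec_w <- fdk_reconstruct(sc$ps, w360, sc$rp)
  denom <- max(abs(sc$rec$values))
  expect_lt(max(abs(rec_w$values - sc$rec$values)) / denom, 1e-6)
})
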