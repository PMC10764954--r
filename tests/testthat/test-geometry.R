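test_that("source trajectory lies on the scan circle", {
  g <- geom_kbct1000()
  expect_equal(drop(source_position(g, 0)), c(x = 650, y = 0, z = 0))
  expect_equal(drop(source_position(g, pi)), c(x = -650, y = 0, z = 0),
               tolerance = 1e-12)
  expect_equal(drop(source_position(g, pi / 2)), c(x = 0, y = 650, z = 0),
               tolerance = 1e-12)
})

test_that("detector pixel positions follow the grid and offset conventions", {
  g <- cone_beam_geometry(650, 898, 9, 5, 2, 2, n_views = 8,
                          det_origin_v = 5)  # odd n_u: column 4 is central
  ctr <- drop(detector_pixel_position(g, 0, 4, 2))
  expect_equal(unname(ctr), c(650 - 898, 0, 0), tolerance = 1e-12)
  # one column from center: displaced by pitch_u along the u axis
  nxt <- drop(detector_pixel_position(g, 0, 5, 2))
  expect_equal(sqrt(sum((nxt - ctr)^2)), g$pitch_u, tolerance = 1e-12)
  # lateral offset displaces the same pixel by the offset along u
  g2 <- g; g2$lateral_offset <- 7
  off <- drop(detector_pixel_position(g2, 0, 4, 2))
  expect_equal(sqrt(sum((off - ctr)^2)), 7, tolerance = 1e-12)
  expect_error(detector_pixel_position(g, 0, 9, 0), "u <")
})

test_that("fan angle of a column matches its closed form and is monotone", {
  g <- geom_kbct1000()
  gam <- gamma_of_column(g)
  expect_true(all(diff(gam) > 0))
  # edge column of the centered 1024-column, 0.388 mm pitch panel
  expect_equal(gamma_of_column(g, 1023), atan(198.462 / 898),
               tolerance = 1e-9)
  # symmetric detector: center of the column set has zero fan angle
  expect_equal(gamma_of_column(g, 511) + gamma_of_column(g, 512), 0,
               tolerance = 1e-12)
  # in-plane displacement equal to d_sd -> fan angle atan(1) = 45 degrees
  g3 <- cone_beam_geometry(650, 898, 2, 2, 2 * 898, 1, n_views = 4)
  expect_equal(gamma_of_column(g3, 1), pi / 4, tolerance = 1e-12)
})

test_that("make_ray clips to the FOV cylinder like a brute-force solver", {
  g <- centered_geom(scale = 8, n_views = 36)
  R <- 110; fz <- c(-90, 90)
  brute <- function(s, d) {
    tt <- seq(0, 1, length.out = 20001)
    px <- s[1] + tt * (d[1] - s[1]); py <- s[2] + tt * (d[2] - s[2])
    pz <- s[3] + tt * (d[3] - s[3])
    inside <- px^2 + py^2 <= R^2 & pz >= fz[1] & pz <= fz[2]
    if (!any(inside)) return(c(0, 0))
    range(tt[inside])
  }
  set.seed(42)
  worst <- 0
  for (i in 1:300) {
    u <- sample(0:(g$n_u - 1), 1); v <- sample(0:(g$n_v - 1), 1)
    b <- runif(1, 0, 2 * pi)
    r <- make_ray(g, b, u, v, R, fz)
    bf <- brute(r$source, r$det_point)
    if (r$exit_t > r$entry_t) {
      worst <- max(worst, abs(r$entry_t - bf[1]), abs(r$exit_t - bf[2]))
    } else {
      # miss: brute-force interval must be empty or a sliver
      expect_lt(diff(bf), 2e-4)
    }
  }
  expect_lt(worst, 1e-4)  # brute-force grid resolution 5e-5

  # central ray chord equals the FOV diameter
  rc <- make_ray(centered_geom(), 0, 63, 47, 100)
  chord <- (rc$exit_t - rc$entry_t) * ray_length(rc)
  expect_equal(chord, 200, tolerance = 1e-3)
})

test_that("exact ray-cylinder entry/exit match the quadratic roots", {
  g <- centered_geom(scale = 8, n_views = 36)
  R <- 120
  set.seed(7)
  for (i in 1:1000) {
    u <- sample(0:(g$n_u - 1), 1); v <- sample(0:(g$n_v - 1), 1)
    b <- runif(1, 0, 2 * pi)
    r <- make_ray(g, b, u, v, R)
    e <- r$det_point - r$source
    a2 <- sum(e[1:2]^2); b2 <- 2 * sum(r$source[1:2] * e[1:2])
    c2 <- sum(r$source[1:2]^2) - R^2
    disc <- b2^2 - 4 * a2 * c2
    if (disc > 0) {
      t0 <- max((-b2 - sqrt(disc)) / (2 * a2), 0)
      t1 <- min((-b2 + sqrt(disc)) / (2 * a2), 1)
      if (t1 > t0) {
        expect_equal(r$entry_t, t0, tolerance = 1e-9)
        expect_equal(r$exit_t, t1, tolerance = 1e-9)
      } else expect_identical(r$entry_t, r$exit_t)
    } else expect_identical(r$entry_t, r$exit_t)
  }
})

test_that("short-scan + offset emulation reproduces the clinical counts", {
  g <- cone_beam_geometry(650, 898, 1024, 1, 0.388, 0.388, n_views = 300)
  ps <- projection_set(array(0, c(1024, 1, 300)), g)
  e <- emulate_short_scan_offset(ps, 270, n_trunc_cols = 256)
  expect_identical(sum(apply(e$mask, 3, any)), 225L)
  expect_equal(undersampling_rate(e), (225 / 300) * (768 / 1024))
  expect_equal(undersampling_rate(e), 9 / 16)

  # a 40 cm panel binned to exactly 1024 columns: 5 cm offset -> 256 columns
  g40 <- cone_beam_geometry(650, 898, 1024, 1, 0.390625, 0.390625,
                            n_views = 300)
  ps40 <- projection_set(array(0, c(1024, 1, 300)), g40)
  e40 <- emulate_short_scan_offset(ps40, 270, offset_mm = 50)
  expect_identical(attr(e40, "n_trunc_cols"), 256L)

  # identity case and idempotency
  e0 <- emulate_short_scan_offset(ps, 360, n_trunc_cols = 0)
  expect_true(all(e0$mask))
  expect_identical(e0$values, ps$values)
  e2 <- emulate_short_scan_offset(e, 270, n_trunc_cols = 256)
  expect_identical(e2$mask, e$mask)

  # masked pixels are flagged, not zeroed
  psv <- projection_set(array(1, c(1024, 1, 300)), g)
  ev <- emulate_short_scan_offset(psv, 270, n_trunc_cols = 256)
  expect_true(all(ev$values == 1))
  expect_error(emulate_short_scan_offset(ps, 270, n_trunc_cols = 1024))
})

test_that("undersampling follows the product rule within rounding granularity", {
  g <- cone_beam_geometry(650, 898, 128, 1, 3.125, 3.125, n_views = 300)
  ps <- projection_set(array(0, c(128, 1, 300)), g)
  for (arc in c(204, 220, 270, 360)) {
    for (fr in c(0, 0.125, 0.25, 0.375)) {
      e <- emulate_short_scan_offset(ps, arc, n_trunc_cols = round(fr * 128))
      expect_equal(undersampling_rate(e), (arc / 360) * (1 - fr),
                   tolerance = 1 / 128 + 1 / 300 + 1e-9)
    }
  }
  expect_equal(analytic_sampling_rate(270, 2.5, 40), 0.65625)
  expect_equal(round(100 * analytic_sampling_rate(204, 7.5, 40), 1), 35.4)
  expect_error(undersampling_rate(logical(0)))
})

test_that("geometry serializes to JSON and back", {
  g <- geom_kbct1000(scale = 8)
  g$lateral_offset <- -12.5
  path <- tempfile(fileext = ".json")
  write_geometry(g, path)
  g2 <- read_geometry(path)
  expect_equal(g2[names(g2) != "view_angles"], g[names(g) != "view_angles"])
  expect_equal(g2$view_angles, g$view_angles, tolerance = 1e-12)
})
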