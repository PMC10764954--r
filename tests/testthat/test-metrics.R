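make_vol <- function(vals, pitch = 1) ct_volume(vals, pitch)

test_that("noise variance matches closed forms and Monte-Carlo truth", {
  v <- make_vol(array(0.2, c(10, 10, 10)))
  roi <- array(TRUE, c(10, 10, 10))
  expect_equal(noise_variance(v, roi), 0)
  # two-point ROI {0.19, 0.21}: unbiased variance of the two values
  vals <- array(0.2, c(4, 4, 4))
  vals[1] <- 0.19; vals[2] <- 0.21
  roi2 <- array(FALSE, c(4, 4, 4)); roi2[1:2] <- TRUE
  expect_equal(noise_variance(make_vol(vals), roi2), var(c(0.19, 0.21)))
  expect_equal(var(c(0.19, 0.21)), 2e-4)
  # Gaussian field: variance within 5% of sigma^2 for a large ROI
  set.seed(31)
  sigma <- 0.015
  big <- array(0.2 + rnorm(24^3, sd = sigma), c(24, 24, 24))
  expect_lt(abs(noise_variance(make_vol(big), array(TRUE, c(24, 24, 24))) -
                sigma^2) / sigma^2, 0.05)
  expect_error(noise_variance(v, array(FALSE, c(10, 10, 10))))
})

test_that("SDNR matches its formula and is shift-invariant", {
  set.seed(12)
  vals <- array(0, c(20, 20, 4))
  fg <- array(FALSE, dim(vals)); ad <- array(FALSE, dim(vals))
  fg[1:10, , ] <- TRUE; ad[11:20, , ] <- TRUE
  vals[fg] <- 0.27; vals[ad] <- 0.20 + rnorm(sum(ad), sd = 0.01)
  v <- make_vol(vals)
  s <- sdnr(v, fg, ad)
  expect_equal(s, (0.27 - mean(vals[ad])) / sd(vals[ad]))
  expect_equal(s, 7, tolerance = 0.2)
  # adding a constant changes nothing
  v2 <- make_vol(vals + 0.1)
  expect_equal(sdnr(v2, fg, ad), s, tolerance = 1e-9)
  # identical ROI statistics give 0
  expect_equal(sdnr(make_vol(array(5, dim(vals)) + array(rnorm(prod(dim(vals)), sd = 1e-3), dim(vals))), fg, fg), 0)
  # pooled denominator option
  expect_true(is.finite(sdnr(v, fg, ad, denominator = "pooled")))
})

test_that("FWHM recovers closed forms for Gaussian and triangular peaks", {
  pitch <- 0.25
  d <- c(81, 9, 81)
  org <- -(d - 1) / 2 * pitch
  xs <- org[1] + (seq_len(d[1]) - 1) * pitch
  zs <- org[3] + (seq_len(d[3]) - 1) * pitch
  sigma <- 0.5
  gx <- exp(-xs^2 / (2 * sigma^2))
  gz <- exp(-zs^2 / (2 * sigma^2))
  vals <- 0.2 + aperm(outer(outer(gx, rep(1, d[2])), gz), c(1, 2, 3))
  v <- ct_volume(array(vals, d), pitch, org)
  fw_ml <- fwhm_profile(v, c(0, 0, 0), "ML", half_window = 8)
  fw_si <- fwhm_profile(v, c(0, 0, 0), "SI", half_window = 8)
  expect_equal(fw_ml, 2 * sqrt(2 * log(2)) * sigma, tolerance = pitch / 2)
  expect_equal(fw_si, 2 * sqrt(2 * log(2)) * sigma, tolerance = pitch / 2)
  # symmetric triangular peak of base 2b has FWHM b
  b <- 2.5
  tri <- pmax(1 - abs(xs) / b, 0)
  vt <- ct_volume(array(0.1 + outer(outer(tri, rep(1, d[2])), rep(1, d[3])),
                        d), pitch, org)
  expect_equal(fwhm_profile(vt, c(0, 0, 0), "ML", half_window = 8), b,
               tolerance = pitch / 2)
  # translation invariance and linear scaling with the coordinate scale
  v_shift <- ct_volume(v$values, pitch, org + c(3 * pitch, 0, 0))
  expect_equal(fwhm_profile(v_shift, c(3 * pitch, 0, 0), "ML", 8), fw_ml,
               tolerance = 1e-9)
  v_scaled <- ct_volume(v$values, 2 * pitch, 2 * org)
  expect_equal(fwhm_profile(v_scaled, c(0, 0, 0), "ML", 16), 2 * fw_ml,
               tolerance = pitch)
  # degenerate profile errors
  expect_error(fwhm_profile(make_vol(array(0.2, c(9, 9, 9))), c(0, 0, 0),
                            "ML", 3), "peak")
})

test_that("paired comparison gates between t-test and Wilcoxon correctly", {
  x <- rnorm(20)
  expect_identical(paired_compare(x, x)$test, "degenerate")
  set.seed(41)
  a <- rnorm(50, mean = 1, sd = 0.2)
  b <- a + rnorm(50, sd = 0.1)
  res <- paired_compare(a, b)
  expect_identical(res$test, "t")
  expect_gt(res$shapiro_p, 0.05)
  expect_identical(paired_compare(a, a + rcauchy(50) * 0.3)$test, "wilcoxon")
  # heavy-tailed differences select the nonparametric branch almost always
  picks <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    aa <- rnorm(50)
    paired_compare(aa, aa + rcauchy(50))$test
  }, character(1))
  expect_gte(mean(picks == "wilcoxon"), 0.9)
  # and well-behaved normal differences select the t branch almost always
  picks_t <- vapply(1:50, function(s) {
    set.seed(2000 + s)
    aa <- rnorm(50)
    paired_compare(aa, aa + rnorm(50, 0.1, 0.3))$test
  }, character(1))
  expect_gte(mean(picks_t == "t"), 0.9)
  expect_error(paired_compare(1:4, 2:5))  # too short
})

test_that("metrics_report assembles the four standard metrics", {
  spec <- phantom_spec(dims = c(48, 48, 36), pitch = 2.5, supersample = 2,
                       n_calcifications = 2, calc_diam_mm = c(5, 7), seed = 3)
  ph <- generate_phantom(spec)
  rep <- metrics_report(ph$volume, ph$annotation, fwhm_half_window = 8)
  expect_named(rep, c("noise_variance", "sdnr", "fwhm_ml", "fwhm_si",
                      "fwhm_ml_each", "fwhm_si_each"))
  expect_gte(rep$noise_variance, 0)
  expect_gt(rep$sdnr, 0)      # fibroglandular brighter than adipose
  cc <- ph$annotation$calcifications
  for (i in seq_len(nrow(cc))) {
    expect_equal(rep$fwhm_ml_each[i], cc$diameter[i],
                 tolerance = 0.5 * spec$pitch)
    expect_equal(rep$fwhm_si_each[i], cc$diameter[i],
                 tolerance = 0.5 * spec$pitch)
  }
})
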