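test_that("stratified samples respect bins and are uniform within them", {
  g <- centered_geom(scale = 16, n_views = 4)
  r <- make_ray(g, 0.3, 20, 10, 120)
  k <- 16
  set.seed(5)
  for (i in 1:50) {
    a <- stratified_samples(r, k)
    expect_length(a, k)
    expect_true(all(diff(a) > 0))
    w <- (r$exit_t - r$entry_t) / k
    bins <- r$entry_t + (seq_len(k) - 1) * w
    expect_true(all(a >= bins & a <= bins + w))
  }
  # deterministic midpoints
  am <- stratified_samples(r, k, jitter = FALSE)
  expect_equal(am, r$entry_t + (seq_len(k) - 0.5) * (r$exit_t - r$entry_t) / k)
  # chi-square uniformity of within-bin positions over many draws
  set.seed(6)
  pos <- replicate(600, (stratified_samples(r, k) -
                           (r$entry_t + (seq_len(k) - 1) * (r$exit_t - r$entry_t) / k)) /
                     ((r$exit_t - r$entry_t) / k))
  cnt <- table(cut(as.numeric(pos), seq(0, 1, by = 0.1)))
  expect_gt(stats::chisq.test(cnt)$p.value, 0.01)
  # zero-extent ray renders nothing
  rmiss <- make_ray(g, 0, 0, 0, 1e-3)
  expect_length(stratified_samples(rmiss, k), 0)
})

test_that("rendering follows the discrete quadrature on constant fields", {
  cfg <- afn_config(levels = 4, log2_table = 10, base_res = 4, finest_res = 16,
                    k = 32, epochs = 1, seed = 2)
  params <- cbctafn:::.afn_init_params(cfg)  # zero last layer -> h = exp(0) = 1
  norm <- list(lo = c(-150, -150, -150), hi = c(150, 150, 150))
  field <- structure(list(params = params, config = cfg, norm = norm,
                          fov_radius = 120, fov_z = c(-120, 120),
                          loss_curve = 0), class = "attenuation_field")
  g <- centered_geom(scale = 16, n_views = 4)
  r <- make_ray(g, 0.7, 25, 12, 120)
  for (k in c(16, 64, 256)) {
    # unit field: rendered value = (exit - alpha_1) * raylen in cm; with
    # midpoint sampling alpha_1 = entry + halfbin, so the quadrature spans
    # the chord minus half a bin
    span <- r$exit_t - r$entry_t
    expected <- (span - span / (2 * k)) * ray_length(r) * 0.1
    expect_equal(render_ray(field, r, k = k), expected, tolerance = 1e-6)
  }
  # a (numerically) zero field renders zero
  p0 <- params; p0$b4 <- -200
  f0 <- field; f0$params <- p0
  expect_lt(render_ray(f0, r, k = 64), 1e-50)
})

test_that("fused training kernel reproduces the double-precision gradients", {
  set.seed(11)
  cfg <- afn_config(levels = 5, log2_table = 11, base_res = 4, finest_res = 24,
                    k = 12, rays_per_batch = 48, epochs = 1, seed = 3)
  params <- cbctafn:::.afn_init_params(cfg)
  params$W4 <- matrix(rnorm(cfg$width) * 0.05, cfg$width, 1)
  params$b4 <- -1.5
  n <- 48; k <- 12; N <- n * k
  coords <- matrix(runif(N * 3), N, 3)
  seg <- matrix(runif(n * k, 0.02, 0.08), n, k)
  p <- runif(n)
  tb <- cbctafn:::cpp_afn_train_batch(coords, params$tables, params$res, 2L,
                                      cbctafn:::.mlp_of(params), seg, p, 15)
  fw <- cbctafn:::.afn_forward(params, cfg, coords, cache = TRUE)
  phat <- rowSums(matrix(fw$h, n, k) * seg)
  expect_equal(as.numeric(tb$phat), unname(phat), tolerance = 1e-5)
  expect_equal(tb$loss, mean((phat - p)^2), tolerance = 1e-5)
  dh <- as.numeric(2 / n * (phat - p) * seg)
  gr <- cbctafn:::.afn_backward(params, cfg, fw, dh)
  rel <- function(a, b) max(abs(a - b)) / max(max(abs(a)), 1e-12)
  expect_lt(rel(gr$W1, tb$W1), 1e-4)
  expect_lt(rel(gr$W4, tb$W4), 1e-4)
  expect_lt(rel(gr$tables[[2]], tb$tables[[2]]), 1e-4)
  expect_lt(rel(gr$tables[[5]], tb$tables[[5]]), 1e-4)

  # central finite-difference check of the rendering loss wrt MLP weights
  lossf <- function(pp) {
    h <- cbctafn:::.afn_forward(pp, cfg, coords)
    mean((rowSums(matrix(h, n, k) * seg) - p)^2)
  }
  eps <- 1e-4
  gmax <- max(abs(gr$W2))
  for (ix in c(which.max(abs(gr$W2)), 30)) {
    pp <- params; pm <- params
    pp$W2[ix] <- pp$W2[ix] + eps
    pm$W2[ix] <- pm$W2[ix] - eps
    fd <- (lossf(pp) - lossf(pm)) / (2 * eps)
    expect_lt(abs(fd - gr$W2[ix]), 0.02 * gmax + 1e-12)
  }
})

test_that("training converges on a tiny scene, deterministically", {
  sc <- tiny_afn_scene()
  cfg <- afn_config(levels = 5, log2_table = 12, base_res = 4, finest_res = 24,
                    k = 32, rays_per_batch = 512, epochs = 40, seed = 21)
  f <- train_afn(sc$ps, cfg)
  expect_length(f$loss_curve, 40)
  expect_lt(tail(f$loss_curve, 1), 0.05 * f$loss_curve[1])
  # deterministic given (config, data, seed); checked on a short schedule
  cfgd <- cfg; cfgd$epochs <- 3
  f2a <- train_afn(sc$ps, cfgd)
  f2b <- train_afn(sc$ps, cfgd)
  expect_identical(f2a$loss_curve, f2b$loss_curve)
  expect_identical(f2a$params$W2, f2b$params$W2)
  # different seed gives a different trajectory
  cfg3 <- cfgd; cfg3$seed <- 22
  f3 <- train_afn(sc$ps, cfg3)
  expect_false(identical(f2a$loss_curve, f3$loss_curve))

  # self-consistency: synthesis at the acquired geometry reproduces the
  # acquired pixels; volume query recovers the interior attenuation
  sy <- synthesize_projections(f, sc$geom)
  m <- sc$ps$values > 0.6
  relerr <- abs(sy$values[m] - sc$ps$values[m]) / sc$ps$values[m]
  expect_lt(stats::median(relerr), 0.05)
  qv <- query_volume(f, dim(sc$vol$values), sc$vol$pitch, sc$vol$origin)
  xs <- voxel_centers(sc$vol, 1); ys <- voxel_centers(sc$vol, 2)
  zs <- voxel_centers(sc$vol, 3)
  interior <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= 30^2
  expect_lt(abs(mean(qv$values[interior]) - 0.25) / 0.25, 0.1)
  expect_true(all(qv$values >= 0))
  # checkpoint round trip preserves the field exactly enough
  path <- tempfile(fileext = ".json")
  write_afn(f, path)
  f4 <- read_afn(path)
  expect_equal(f4$params$W2, f$params$W2, tolerance = 1e-12)
  r <- make_ray(sc$geom, 0.4, 10, 12, f$fov_radius, f$fov_z)
  expect_equal(render_ray(f4, r), render_ray(f, r), tolerance = 1e-10)

  expect_error(train_afn(projection_set(sc$ps$values, sc$geom,
                                        mask = array(FALSE, dim(sc$ps$values))),
                         cfg), "empty acquired set")
})

test_that("an untrained field is the unit constant", {
  cfg <- afn_config(levels = 4, log2_table = 10, base_res = 4, finest_res = 12,
                    k = 8, epochs = 1, seed = 1)
  params <- cbctafn:::.afn_init_params(cfg)
  field <- structure(list(params = params, config = cfg,
                          norm = list(lo = rep(-100, 3), hi = rep(100, 3)),
                          fov_radius = 90, fov_z = c(-90, 90),
                          loss_curve = 0), class = "attenuation_field")
  qv <- query_volume(field, c(8, 8, 8), 10)
  expect_equal(unique(round(as.numeric(qv$values), 10)), 1)
})

test_that("splice keeps acquired pixels and fills the rest", {
  g <- centered_geom(scale = 32, n_views = 4)
  d <- c(g$n_u, g$n_v, 4)
  acq_vals <- array(runif(prod(d)), d)
  syn_vals <- array(runif(prod(d)), d)
  syn <- projection_set(syn_vals, g)
  # all-true mask: output is the acquired data bit-exactly
  full <- projection_set(acq_vals, g)
  expect_identical(splice(full, syn)$values, acq_vals)
  # all-false mask: output equals the synthesized data
  none <- projection_set(acq_vals, g, mask = array(FALSE, d))
  expect_identical(splice(none, syn)$values, syn_vals)
  # checkerboard against an explicit elementwise loop
  mask <- array((slice.index(array(0, d), 1) +
                 slice.index(array(0, d), 2) +
                 slice.index(array(0, d), 3)) %% 2 == 0, d)
  part <- projection_set(acq_vals, g, mask = mask)
  out <- splice(part, syn)
  brute <- array(0, d)
  for (i in seq_len(prod(d)))
    brute[i] <- if (mask[i]) acq_vals[i] else syn_vals[i]
  expect_identical(out$values, brute)
  expect_true(all(out$mask))
  expect_error(splice(part, projection_set(syn_vals[, , 1:3],
                                           centered_geom(scale = 32, n_views = 3))))
})
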