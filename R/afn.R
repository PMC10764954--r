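#' Attenuation field network configuration
#'
#' The attenuation field network (AFN) is a per-scan, self-supervised,
#' coordinate-based representation of the attenuation map: a multiresolution
#' hash-grid encoding followed by a small fully connected network (3 hidden
#' layers of width 64, ReLU), with an exponential output activation enforcing
#' nonnegative attenuation (its derivative is clipped to at most 15 during
#' backpropagation to prevent exploding gradients). It is trained by Adam on
#' the squared error between rendered and acquired line integrals.
#'
#' Defaults follow the clinical-scale training recipe (hash table `2^23`,
#' 512 samples per ray, batches of 2048 rays, 250 epochs, learning rate
#' `1e-3` decayed by one-third every 50 epochs, Adam `beta1 = 0.9`,
#' `beta2 = 0.99`, `eps = 1e-15`, weight decay `1e-6`). For desk-scale
#' phantoms shrink `log2_table`, `levels`, `finest_res`, `k` and `epochs`;
#' these are scale parameters, not method changes.
#'
#' @param levels number of hash-grid resolution levels.
#' @param features features per level.
#' @param log2_table log2 of the hash table size per level.
#' @param base_res,finest_res coarsest / finest grid resolution (cells per
#'   axis of the unit cube); intermediate levels are geometrically spaced.
#' @param width hidden layer width.
#' @param k samples per ray (stratified bins).
#' @param rays_per_batch rays (acquired pixels) per training batch.
#' @param epochs training epochs; each epoch iterates over all acquired views.
#' @param lr,lr_decay,decay_every learning-rate schedule.
#' @param beta1,beta2,eps,weight_decay Adam hyperparameters.
#' @param grad_clip clip on the exponential activation's derivative.
#' @param shuffle_views shuffle view order each epoch (default fixed order).
#' @param seed RNG seed; training is deterministic given (config, data, seed).
#' @return An object of class `afn_config`.
#' @export
afn_config <- function(levels = 16, features = 2, log2_table = 23,
                       base_res = 16, finest_res = 512, width = 64,
                       k = 512, rays_per_batch = 2048, epochs = 250,
                       lr = 1e-3, lr_decay = 1 / 3, decay_every = 50,
                       beta1 = 0.9, beta2 = 0.99, eps = 1e-15,
                       weight_decay = 1e-6, grad_clip = 15,
                       shuffle_views = FALSE, seed = 1) {
  stopifnot(k >= 2, rays_per_batch >= 1, epochs >= 1, lr > 0, levels >= 1,
            features >= 1, base_res >= 1, finest_res >= base_res)
  structure(as.list(environment()), class = "afn_config")
}

# Geometric level resolutions between base and finest.
.afn_resolutions <- function(cfg) {
  if (cfg$levels == 1) return(as.integer(cfg$finest_res))
  b <- exp((log(cfg$finest_res) - log(cfg$base_res)) / (cfg$levels - 1))
  as.integer(pmax(1, floor(cfg$base_res * b^(seq_len(cfg$levels) - 1))))
}

# Initialize all trainable parameters. The output layer starts at zero so the
# untrained field is the unit constant exp(0) = 1.
.afn_init_params <- function(cfg) {
  res <- .afn_resolutions(cfg)
  tsize <- 2^cfg$log2_table
  tables <- lapply(res, function(r) {
    n <- min((r + 1)^3, tsize)
    matrix(stats::runif(n * cfg$features, -1e-4, 1e-4), n, cfg$features)
  })
  d0 <- cfg$levels * cfg$features
  w <- cfg$width
  xavier <- function(m, n) matrix(stats::runif(m * n, -1, 1) * sqrt(6 / (m + n)), m, n)
  list(tables = tables,
       W1 = xavier(d0, w), b1 = numeric(w),
       W2 = xavier(w, w),  b2 = numeric(w),
       W3 = xavier(w, w),  b3 = numeric(w),
       W4 = matrix(0, w, 1), b4 = numeric(1),
       res = res)
}

.addb <- function(Z, b) Z + rep(b, each = nrow(Z))

# Forward pass through encoder + MLP (fused compiled kernels); returns
# attenuation h >= 0 and, when `cache = TRUE`, the intermediates needed for
# backpropagation.
.afn_forward <- function(params, cfg, coords, cache = FALSE) {
  X <- cpp_hash_encode(coords, params$tables, params$res)
  fw <- cpp_mlp_forward(X, params$W1, params$b1, params$W2, params$b2,
                        params$W3, params$b3, params$W4, params$b4, cache)
  if (!cache) return(drop(fw$h))
  list(h = drop(fw$h), X = X, H1 = fw$H1, H2 = fw$H2, H3 = fw$H3,
       Z4 = fw$Z4, coords = coords)
}

# Backpropagate dL/dh through the network; returns gradients for every
# trainable tensor. The exponential activation's derivative exp(z) is clipped
# to `grad_clip`.
.afn_backward <- function(params, cfg, fw, dh) {
  bw <- cpp_mlp_backward(fw$X, fw$H1, fw$H2, fw$H3, fw$Z4, dh,
                         params$W1, params$W2, params$W3, params$W4,
                         cfg$grad_clip)
  gtables <- cpp_hash_encode_grad(fw$coords, bw$dX, params$res,
                                  vapply(params$tables, nrow, 1L),
                                  cfg$features)
  list(tables = gtables, W1 = bw$W1, b1 = as.numeric(bw$b1),
       W2 = bw$W2, b2 = as.numeric(bw$b2),
       W3 = bw$W3, b3 = as.numeric(bw$b3),
       W4 = bw$W4, b4 = as.numeric(bw$b4))
}

# One Adam step over the nested parameter/gradient lists (weight decay on the
# MLP weight matrices only).
.adam_step <- function(state, params, grads, cfg, lr) {
  state$t <- state$t + 1
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  upd <- function(key, p, g, decay) {
    if (decay) g <- g + cfg$weight_decay * p
    m <- cfg$beta1 * state$m[[key]] + (1 - cfg$beta1) * g
    v <- cfg$beta2 * state$v[[key]] + (1 - cfg$beta2) * g * g
    state$m[[key]] <- m
    state$v[[key]] <- v
    p - lr * (m / bc1) / (sqrt(v / bc2) + cfg$eps)
  }
  for (l in seq_along(params$tables))
    params$tables[[l]] <- upd(paste0("T", l), params$tables[[l]],
                              grads$tables[[l]], FALSE)
  for (nm in c("W1", "W2", "W3", "W4"))
    params[[nm]] <- upd(nm, params[[nm]], grads[[nm]], TRUE)
  for (nm in c("b1", "b2", "b3", "b4"))
    params[[nm]] <- upd(nm, params[[nm]], grads[[nm]], FALSE)
  params
}

.adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$m <- list(); st$v <- list()
  zero <- function(p) p * 0
  for (l in seq_along(params$tables)) {
    st$m[[paste0("T", l)]] <- zero(params$tables[[l]])
    st$v[[paste0("T", l)]] <- zero(params$tables[[l]])
  }
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")) {
    st$m[[nm]] <- zero(params[[nm]])
    st$v[[nm]] <- zero(params[[nm]])
  }
  st
}

# World-mm points -> encoder unit cube (per-axis affine with 5% margin).
.to_unit <- function(norm, pts) {
  lo <- norm$lo; hi <- norm$hi
  u <- sweep(sweep(pts, 2, lo), 2, hi - lo, "/")
  0.025 + 0.95 * u
}

# Vectorized FOV clipping of rays s -> D (matrix n x 3): cylinder of radius R
# about z intersected with z in [z0, z1]; returns t0/t1 columns (t0 == t1 on
# a miss).
.clip_rays <- function(s, D, R, z0, z1) {
  ex <- D[, 1] - s[1]; ey <- D[, 2] - s[2]; ez <- D[, 3] - s[3]
  a <- ex^2 + ey^2
  b <- 2 * (s[1] * ex + s[2] * ey)
  cc <- s[1]^2 + s[2]^2 - R^2
  disc <- b^2 - 4 * a * cc
  ok <- disc > 0 & a > 0
  sq <- sqrt(pmax(disc, 0))
  t0 <- pmax((-b - sq) / (2 * a), 0)
  t1 <- pmin((-b + sq) / (2 * a), 1)
  # z slab
  zl <- (z0 - s[3]) / ez
  zh <- (z1 - s[3]) / ez
  zmin <- pmin(zl, zh); zmax <- pmax(zl, zh)
  flat <- abs(ez) < 1e-300
  zmin[flat] <- if (s[3] >= z0 && s[3] <= z1) 0 else 1
  zmax[flat] <- if (s[3] >= z0 && s[3] <= z1) 1 else 0
  t0 <- pmax(t0, zmin); t1 <- pmin(t1, zmax)
  bad <- !ok | t1 <= t0
  t0[bad] <- 0; t1[bad] <- 0
  cbind(t0 = t0, t1 = t1)
}

#' Stratified samples along a ray
#'
#' Partitions the FOV-clipped extent `[entry_t, exit_t]` into `k` evenly
#' spaced bins and draws one uniform sample per bin (strictly increasing).
#' An unclipped (zero-extent) ray yields an empty vector.
#'
#' @param ray a `ct_ray` from [make_ray()].
#' @param k number of bins.
#' @param jitter `TRUE` for stratified random draws (uses the current RNG
#'   stream), `FALSE` for deterministic bin midpoints.
#' @return numeric vector of `k` parameters in `(entry_t, exit_t)`.
#' @export
stratified_samples <- function(ray, k, jitter = TRUE) {
  if (ray$exit_t <= ray$entry_t) return(numeric(0))
  w <- (ray$exit_t - ray$entry_t) / k
  u <- if (jitter) stats::runif(k) else rep(0.5, k)
  ray$entry_t + (seq_len(k) - 1 + u) * w
}

# Stratified (or midpoint) sample coordinates and cm segment lengths for a
# batch of rays sharing a source. Rows of `pts` are ordered ray-major within
# sample blocks (index = ray + n*(sample-1)). Quadrature follows the discrete
# rendering sum h(t_i) |t_{i+1} - t_i| with the final interval closed at the
# exit point.
.sample_ray_points <- function(s, D, tt, k, jitter) {
  n <- nrow(D)
  span <- tt[, 2] - tt[, 1]
  w <- span / k
  u <- if (jitter) matrix(stats::runif(n * k), n, k) else matrix(0.5, n, k)
  alpha <- tt[, 1] + (rep(seq_len(k), each = n) - 1 + u) * w  # n x k
  delta <- cbind(alpha[, -1, drop = FALSE], tt[, 2]) - alpha  # n x k
  raylen <- sqrt((D[, 1] - s[1])^2 + (D[, 2] - s[2])^2 + (D[, 3] - s[3])^2)
  seg_cm <- delta * raylen * 0.1
  pts <- cbind(s[1] + as.numeric(alpha) * rep(D[, 1] - s[1], k),
               s[2] + as.numeric(alpha) * rep(D[, 2] - s[2], k),
               s[3] + as.numeric(alpha) * rep(D[, 3] - s[3], k))
  list(pts = pts, seg_cm = seg_cm, span = span)
}

.mlp_of <- function(params)
  params[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")]

# Batched renderer (inference path, fused single-precision kernel).
.render_batch <- function(params, cfg, norm, s, D, tt, k, jitter) {
  sp <- .sample_ray_points(s, D, tt, k, jitter)
  h <- cpp_afn_infer(.to_unit(norm, sp$pts), params$tables, params$res,
                     cfg$features, .mlp_of(params))
  phat <- rowSums(matrix(h, nrow(D), k) * sp$seg_cm)
  phat[sp$span <= 0] <- 0
  phat
}

#' Render the projection value of a single ray through a trained field
#'
#' Discrete line integral of the queried attenuation along the ray (the
#' rendering sum used in training), with `k` stratified or midpoint samples.
#'
#' @param field an `attenuation_field` from [train_afn()].
#' @param ray a `ct_ray`.
#' @param k samples per ray (default from the field's config).
#' @param jitter stratified random sampling (`TRUE`) or deterministic bin
#'   midpoints (`FALSE`, default at inference).
#' @return rendered projection value (unitless).
#' @export
render_ray <- function(field, ray, k = field$config$k, jitter = FALSE) {
  tt <- matrix(c(ray$entry_t, ray$exit_t), 1, 2)
  .render_batch(field$params, field$config, field$norm, ray$source,
                matrix(ray$det_point, 1, 3), tt, k, jitter)
}

#' Train an attenuation field network on (possibly incomplete) projections
#'
#' Minimizes the squared error between rendered and acquired line integrals
#' over the acquired set only (masked-true pixels). Each epoch iterates over
#' all acquired views in order (optionally shuffled); per view,
#' `rays_per_batch` acquired pixels are drawn without replacement,
#' non-repeating across epochs until the view's pixel pool is exhausted, then
#' reshuffled. Training is deterministic given (config, data, seed).
#'
#' @param ps a [projection_set()]; its mask marks the acquired set.
#' @param config an [afn_config()].
#' @param fov_radius radius (mm) of the cylindrical imaging FOV rays are
#'   clipped to; default is the radius seen by the full detector.
#' @param fov_z `z` extent (mm) of the FOV; default spans the detector rows
#'   scaled to the far side of the FOV.
#' @param verbose print per-epoch mean loss.
#' @return An object of class `attenuation_field`: trained parameters, the
#'   config, the world-to-unit-cube normalization, the FOV, and the per-epoch
#'   training `loss_curve`.
#' @export
train_afn <- function(ps, config = afn_config(), fov_radius = NULL,
                      fov_z = NULL, verbose = FALSE) {
  stopifnot(inherits(ps, "projection_set"), inherits(config, "afn_config"))
  geom <- ps$geom
  if (!any(ps$mask)) stop("empty acquired set")
  if (is.null(fov_radius)) fov_radius <- geom$d_so * sin(gamma_max(geom))
  if (is.null(fov_z)) {
    mag <- geom$d_so / geom$d_sd
    vp <- range(detector_v_offsets(geom)) * mag
    sc <- (geom$d_so + fov_radius) / geom$d_so
    fov_z <- c(vp[1] * sc, vp[2] * sc) + c(-1, 1) * 0.02 * diff(vp) * sc
  }
  norm <- list(lo = c(-fov_radius, -fov_radius, fov_z[1]),
               hi = c(fov_radius, fov_radius, fov_z[2]))

  nview <- length(geom$view_angles)
  acq <- lapply(seq_len(nview), function(ib) which(ps$mask[, , ib]))
  views <- which(vapply(acq, length, 1L) > 0)
  xu <- detector_u_offsets(geom)
  zv <- detector_v_offsets(geom)

  with_preserved_seed(config$seed, {
    params <- .afn_init_params(config)
    state <- .adam_init(params)
    # per-view non-repeating sampling queues
    queue <- lapply(acq, function(ix) if (length(ix)) sample(ix) else ix)
    ptr <- rep(1L, nview)
    loss_curve <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr * config$lr_decay^((epoch - 1) %/% config$decay_every)
      ord <- if (config$shuffle_views) sample(views) else views
      eloss <- 0
      for (ib in ord) {
        pool <- queue[[ib]]
        nb <- min(config$rays_per_batch, length(pool))
        take <- integer(0)
        while (length(take) < nb) {
          avail <- length(pool) - ptr[ib] + 1L
          grab <- min(nb - length(take), avail)
          take <- c(take, pool[ptr[ib]:(ptr[ib] + grab - 1L)])
          ptr[ib] <- ptr[ib] + grab
          if (ptr[ib] > length(pool)) {  # exhausted: reshuffle and continue
            pool <- sample(pool)
            queue[[ib]] <- pool
            ptr[ib] <- 1L
          }
        }
        uv <- arrayInd(take, c(geom$n_u, geom$n_v))
        beta <- geom$view_angles[ib]
        s <- c(geom$d_so * cos(beta), geom$d_so * sin(beta), 0)
        cx <- (geom$d_so - geom$d_sd) * cos(beta)
        cy <- (geom$d_so - geom$d_sd) * sin(beta)
        xuu <- xu[uv[, 1]]
        D <- cbind(cx + xuu * sin(beta), cy - xuu * cos(beta), zv[uv[, 2]])
        tt <- .clip_rays(s, D, fov_radius, fov_z[1], fov_z[2])
        hit <- tt[, 2] > tt[, 1]
        if (!any(hit)) next
        D <- D[hit, , drop = FALSE]; tt <- tt[hit, , drop = FALSE]
        p <- ps$values[, , ib][take][hit]

        sp <- .sample_ray_points(s, D, tt, config$k, jitter = TRUE)
        tb <- cpp_afn_train_batch(.to_unit(norm, sp$pts), params$tables,
                                  params$res, config$features,
                                  .mlp_of(params), sp$seg_cm, p,
                                  config$grad_clip)
        if (!is.finite(tb$loss))
          stop("AFN training diverged (non-finite loss) at epoch ", epoch)
        eloss <- eloss + tb$loss
        grads <- list(tables = tb$tables, W1 = tb$W1, b1 = as.numeric(tb$b1),
                      W2 = tb$W2, b2 = as.numeric(tb$b2),
                      W3 = tb$W3, b3 = as.numeric(tb$b3),
                      W4 = tb$W4, b4 = as.numeric(tb$b4))
        params <- .adam_step(state, params, grads, config, lr)
      }
      loss_curve[epoch] <- eloss / length(ord)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  loss %.5g", epoch, lr,
                        loss_curve[epoch]))
    }

    structure(list(params = params, config = config, norm = norm,
                   fov_radius = fov_radius, fov_z = fov_z,
                   loss_curve = loss_curve),
              class = "attenuation_field")
  })
}

#' @export
print.attenuation_field <- function(x, ...) {
  cat(sprintf("attenuation_field: %d levels x %d features, %d epochs trained\n",
              x$config$levels, x$config$features, length(x$loss_curve)))
  cat(sprintf("  loss %.4g -> %.4g (ratio %.3g)\n", x$loss_curve[1],
              utils::tail(x$loss_curve, 1),
              utils::tail(x$loss_curve, 1) / x$loss_curve[1]))
  invisible(x)
}

#' Query the trained field on a voxel grid
#'
#' Evaluates the attenuation function at voxel centers (no ray sampling
#' involved); the result is nonnegative by construction.
#'
#' @param field an `attenuation_field`.
#' @param dims output dimensions.
#' @param pitch voxel pitch, mm.
#' @param origin center of voxel `(1,1,1)`, mm; default centers the grid in
#'   the field's FOV.
#' @param chunk voxels per evaluation chunk.
#' @return A [ct_volume()].
#' @export
query_volume <- function(field, dims, pitch, origin = NULL, chunk = 65536) {
  dims <- as.integer(dims)
  if (is.null(origin)) {
    origin <- c(-(dims[1] - 1) / 2 * pitch, -(dims[2] - 1) / 2 * pitch,
                mean(field$fov_z) - (dims[3] - 1) / 2 * pitch)
  }
  xs <- origin[1] + (seq_len(dims[1]) - 1) * pitch
  ys <- origin[2] + (seq_len(dims[2]) - 1) * pitch
  zs <- origin[3] + (seq_len(dims[3]) - 1) * pitch
  n <- prod(dims)
  vals <- numeric(n)
  idx <- 1L
  while (idx <= n) {
    hi <- min(idx + chunk - 1L, n)
    ii <- arrayInd(idx:hi, dims)
    pts <- cbind(xs[ii[, 1]], ys[ii[, 2]], zs[ii[, 3]])
    vals[idx:hi] <- cpp_afn_infer(.to_unit(field$norm, pts),
                                  field$params$tables, field$params$res,
                                  field$config$features,
                                  .mlp_of(field$params))
    idx <- hi + 1L
  }
  ct_volume(array(vals, dims), pitch = pitch, origin = origin)
}

#' Synthesize projections for an arbitrary geometry from a trained field
#'
#' Renders every detector pixel of the target geometry through the field.
#' Deterministic bin-midpoint sampling is used by default at inference;
#' stratified sampling can be requested for uncertainty experiments.
#'
#' @param field an `attenuation_field`.
#' @param geom target [cone_beam_geometry()].
#' @param k samples per ray (default from the config).
#' @param jitter stratified random sampling instead of midpoints.
#' @param subset optional logical array `(n_u, n_v, n_views)`: render only
#'   these pixels (others stay 0). Used to synthesize just the unacquired
#'   pixels ahead of splicing.
#' @param chunk rays per chunk.
#' @return A [projection_set()] with an all-true mask.
#' @export
synthesize_projections <- function(field, geom, k = field$config$k,
                                   jitter = FALSE, subset = NULL,
                                   chunk = 8192) {
  nview <- length(geom$view_angles)
  xu <- detector_u_offsets(geom)
  zv <- detector_v_offsets(geom)
  vals <- array(0, c(geom$n_u, geom$n_v, nview))
  grid <- cbind(rep(xu, geom$n_v), rep(zv, each = geom$n_u))
  for (ib in seq_len(nview)) {
    sel <- if (is.null(subset)) seq_len(nrow(grid))
           else which(subset[, , ib])
    if (!length(sel)) next
    beta <- geom$view_angles[ib]
    s <- c(geom$d_so * cos(beta), geom$d_so * sin(beta), 0)
    cx <- (geom$d_so - geom$d_sd) * cos(beta)
    cy <- (geom$d_so - geom$d_sd) * sin(beta)
    D <- cbind(cx + grid[sel, 1] * sin(beta), cy - grid[sel, 1] * cos(beta),
               grid[sel, 2])
    tt <- .clip_rays(s, D, field$fov_radius, field$fov_z[1], field$fov_z[2])
    out <- numeric(length(sel))
    idx <- 1L
    while (idx <= length(sel)) {
      hi <- min(idx + chunk - 1L, length(sel))
      out[idx:hi] <- .render_batch(field$params, field$config, field$norm,
                                   s, D[idx:hi, , drop = FALSE],
                                   tt[idx:hi, , drop = FALSE], k, jitter)
      idx <- hi + 1L
    }
    view <- vals[, , ib]
    view[sel] <- out
    vals[, , ib] <- view
  }
  projection_set(vals, geom)
}

#' Splice acquired and synthesized projections
#'
#' Keeps every acquired (mask-true) pixel of `acquired` and fills the missing
#' pixels from `synthesized`; the result is complete (all-true mask).
#'
#' @param acquired a [projection_set()] whose mask defines the acquired set.
#' @param synthesized a complete [projection_set()] on the identical grid.
#' @return A [projection_set()].
#' @export
splice <- function(acquired, synthesized) {
  stopifnot(identical(dim(acquired$values), dim(synthesized$values)))
  vals <- ifelse(acquired$mask, acquired$values, synthesized$values)
  projection_set(array(vals, dim(acquired$values)), acquired$geom,
                 i0 = acquired$i0)
}

#' Save / load a trained field (config + parameters + normalization)
#'
#' Checkpoints are JSON (plain text); tables and matrices are stored as flat
#' numeric arrays.
#'
#' @param field an `attenuation_field`.
#' @param path file path.
#' @return `read_afn` returns an `attenuation_field`.
#' @export
write_afn <- function(field, path) {
  ser <- list(config = unclass(field$config), norm = field$norm,
              fov_radius = field$fov_radius, fov_z = field$fov_z,
              loss_curve = field$loss_curve,
              res = field$params$res,
              tables = lapply(field$params$tables, as.numeric),
              table_rows = vapply(field$params$tables, nrow, 1L),
              mlp = lapply(field$params[c("W1", "b1", "W2", "b2", "W3", "b3",
                                          "W4", "b4")], as.numeric))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_afn
#' @export
read_afn <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(afn_config, ser$config[setdiff(names(ser$config), NULL)])
  F <- cfg$features; w <- cfg$width; d0 <- cfg$levels * F
  params <- list(
    tables = mapply(function(v, nr) matrix(v, nr, F), ser$tables,
                    ser$table_rows, SIMPLIFY = FALSE),
    W1 = matrix(ser$mlp$W1, d0, w), b1 = ser$mlp$b1,
    W2 = matrix(ser$mlp$W2, w, w), b2 = ser$mlp$b2,
    W3 = matrix(ser$mlp$W3, w, w), b3 = ser$mlp$b3,
    W4 = matrix(ser$mlp$W4, w, 1), b4 = ser$mlp$b4,
    res = as.integer(ser$res))
  structure(list(params = params, config = cfg,
                 norm = list(lo = ser$norm$lo, hi = ser$norm$hi),
                 fov_radius = ser$fov_radius, fov_z = ser$fov_z,
                 loss_curve = ser$loss_curve),
            class = "attenuation_field")
}
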