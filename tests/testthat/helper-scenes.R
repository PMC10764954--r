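# Shared small scenes, built once per test run (memoised in this environment).
.scene_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- builder()
  .scene_cache[[key]]
}

# Desk-scale geometry with the detector centered on the source plane
# (full-cone setup for symmetric phantoms centered at the origin).
centered_geom <- function(scale = 8, n_views = 60) {
  g <- geom_kbct1000(scale = scale, n_views = n_views)
  g$det_origin_v <- g$n_v * g$pitch_v / 2
  g
}

# Partial-volume (supersampled) rasterization of an axis-aligned ellipsoid.
aa_ellipsoid_volume <- function(center, semi, mu0, pitch, dims, ss = 2) {
  org <- -(dims - 1) / 2 * pitch
  ax <- function(i) org[i] + (seq_len(dims[i]) - 1) * pitch
  sub <- function(coord) {
    if (ss == 1) return(coord)
    as.vector(outer(((seq_len(ss)) - 0.5) / ss * pitch - pitch / 2, coord, "+"))
  }
  q <- outer(outer(((sub(ax(1)) - center[1]) / semi[1])^2,
                   ((sub(ax(2)) - center[2]) / semi[2])^2, "+"),
             ((sub(ax(3)) - center[3]) / semi[3])^2, "+")
  if (ss == 1) {
    vals <- array(mu0 * (q <= 1), dims)
  } else {
    m <- array(mu0 * (q <= 1), c(ss, dims[1], ss, dims[2], ss, dims[3]))
    m <- aperm(m, c(1, 3, 5, 2, 4, 6))
    vals <- array(colMeans(matrix(m, nrow = ss^3)), dims)
  }
  ct_volume(vals, pitch, org)
}

# Centered sphere scene with complete projections and an unweighted FDK
# reference; reused by the weight/FDK/acceptance tests.
sphere_scene <- function() {
  memo("sphere", function() {
    g <- centered_geom()
    pitch <- 2; dims <- c(72, 72, 56); R <- 45; mu0 <- 0.25
    vol <- aa_ellipsoid_volume(c(0, 0, 0), rep(R, 3), mu0, pitch, dims, ss = 2)
    ps <- forward_project(vol, g, 256)
    rp <- recon_params(pitch = pitch, dims = dims, origin = vol$origin)
    rec <- fdk_reconstruct(ps, NULL, rp)
    xs <- voxel_centers(vol, 1); ys <- voxel_centers(vol, 2)
    zs <- voxel_centers(vol, 3)
    q <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
    list(geom = g, vol = vol, ps = ps, rp = rp, rec = rec, mu0 = mu0, R = R,
         interior = q <= (R - 10)^2, kz = which.min(abs(zs)))
  })
}

# Tiny AFN training scene: small detector/views, uniform sphere.
tiny_afn_scene <- function() {
  memo("tiny_afn", function() {
    g <- cone_beam_geometry(650, 898, 32, 32, 12.4, 12.4, n_views = 20,
                            det_origin_v = 32 * 12.4 / 2)
    vol <- aa_ellipsoid_volume(c(0, 0, 0), rep(45, 3), 0.25, 4, c(36, 36, 30),
                               ss = 2)
    ps <- forward_project(vol, g, 128)
    list(geom = g, vol = vol, ps = ps)
  })
}

# Desk experiment + reference, shared by pipeline and acceptance tests.
desk_ref <- function() {
  memo("desk_ref", function() {
    cfg <- desk_experiment(master_seed = 11)
    list(cfg = cfg, ref = run_reference(cfg))
  })
}
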