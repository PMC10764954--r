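#' Specification of a synthetic digital breast phantom
#'
#' The phantom emulates the pendant, uncompressed breast of the half-cone
#' acquisition: a half-ellipsoid with its flat chest-wall face in the plane
#' `z = 0` (coinciding with the detector row-0 plane) and the tissue at
#' `z < 0`. It consists of an adipose background, a thin skin shell, soft
#' fibroglandular blobs and small spherical calcifications, each with a
#' configurable attenuation coefficient. Default soft-tissue attenuations
#' (adipose 0.20, fibroglandular 0.27, skin 0.28 1/cm) sit inside the usual
#' breast-CT display window of 0.15 to 0.35 1/cm; calcifications default to
#' 1.20 1/cm. These are configuration, not ground truth of any scanner.
#'
#' @param semi_axes outer half-ellipsoid semi-axes `(a_x, a_y, a_z)`, mm.
#' @param skin_mm skin shell thickness, mm.
#' @param mu_adipose,mu_fibroglandular,mu_skin,mu_calcification attenuation
#'   coefficients, 1/cm (all >= 0; `mu_calcification > mu_fibroglandular`).
#' @param n_glandular_blobs number of fibroglandular blobs.
#' @param blob_mm length-2 range of blob semi-axis sizes, mm.
#' @param n_calcifications number of spherical calcifications.
#' @param calc_diam_mm length-2 range of calcification diameters, mm.
#' @param pitch voxel pitch of the rasterized phantom, mm.
#' @param dims voxel grid dimensions `(n_x, n_y, n_z)`.
#' @param supersample anti-aliasing factor per axis (1 = off; 2 = default);
#'   with supersampling the voxel values are partial-volume averages, giving
#'   soft compartment edges.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(semi_axes = c(55, 55, 70), skin_mm = 2,
                         mu_adipose = 0.20, mu_fibroglandular = 0.27,
                         mu_skin = 0.28, mu_calcification = 1.20,
                         n_glandular_blobs = 10, blob_mm = c(5, 14),
                         n_calcifications = 4, calc_diam_mm = c(4, 7),
                         pitch = 2, dims = c(72, 72, 48),
                         supersample = 2, seed = 1) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), skin_mm >= 0,
            mu_adipose >= 0, mu_fibroglandular >= 0, mu_skin >= 0,
            mu_calcification > mu_fibroglandular,
            pitch > 0, length(dims) == 3, supersample >= 1)
  structure(list(semi_axes = semi_axes, skin_mm = skin_mm,
                 mu_adipose = mu_adipose,
                 mu_fibroglandular = mu_fibroglandular, mu_skin = mu_skin,
                 mu_calcification = mu_calcification,
                 n_glandular_blobs = n_glandular_blobs, blob_mm = blob_mm,
                 n_calcifications = n_calcifications,
                 calc_diam_mm = calc_diam_mm, pitch = pitch,
                 dims = as.integer(dims),
                 supersample = as.integer(supersample), seed = seed),
            class = "phantom_spec")
}

# Labels used in the phantom label map; precedence when compartments overlap:
# calcification > skin > glandular > adipose > air.
.phantom_labels <- c(air = 0L, adipose = 1L, glandular = 2L, skin = 3L,
                     calc = 4L)

# Rasterize the phantom label map on a grid given by axis coordinate vectors.
.phantom_labelmap <- function(spec, xs, ys, zs, blobs, calcs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  ax <- spec$semi_axes
  qx <- (xs / ax[1])^2
  qy <- (ys / ax[2])^2
  qz <- (zs / ax[3])^2
  q <- outer(outer(qx, qy, "+"), qz, "+")
  half <- rep(zs <= 0, each = nx * ny)
  lab <- array(.phantom_labels[["air"]], c(nx, ny, nz))
  outer_in <- q <= 1 & half
  inn <- pmax(ax - spec$skin_mm, 0.1)
  qi <- outer(outer((xs / inn[1])^2, (ys / inn[2])^2, "+"), (zs / inn[3])^2, "+")
  inner_in <- qi <= 1 & half
  lab[outer_in] <- .phantom_labels[["skin"]]
  lab[inner_in] <- .phantom_labels[["adipose"]]

  paint <- function(lab, center, semi, value, clip_to) {
    rng <- function(coord, c0, s) which(coord >= c0 - s & coord <= c0 + s)
    ix <- rng(xs, center[1], semi[1]); iy <- rng(ys, center[2], semi[2])
    iz <- rng(zs, center[3], semi[3])
    if (!length(ix) || !length(iy) || !length(iz)) return(lab)
    qq <- outer(outer(((xs[ix] - center[1]) / semi[1])^2,
                      ((ys[iy] - center[2]) / semi[2])^2, "+"),
                ((zs[iz] - center[3]) / semi[3])^2, "+")
    sub <- lab[ix, iy, iz, drop = FALSE]
    sel <- qq <= 1 & clip_to[ix, iy, iz, drop = FALSE]
    sub[sel] <- value
    lab[ix, iy, iz] <- sub
    lab
  }
  for (b in blobs)
    lab <- paint(lab, b$center, b$semi, .phantom_labels[["glandular"]], inner_in)
  for (cc in calcs)
    lab <- paint(lab, cc$center, rep(cc$diameter / 2, 3),
                 .phantom_labels[["calc"]], inner_in)
  lab
}

#' Generate a synthetic breast phantom with ground-truth annotation
#'
#' Deterministic for a fixed seed. Compartments are clipped to the interior of
#' the breast (never silently enlarged); calcification centers are sampled so
#' that every calcification lies fully inside the breast surface. The
#' annotation records each calcification's center and diameter plus logical
#' compartment masks (air excluded) on the output grid; masks follow the
#' precedence calcification > skin > glandular > adipose and therefore
#' partition the phantom support.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [ct_volume()], values in 1/cm) and
#'   `annotation` (list: `calcifications` data frame with world-mm centers and
#'   diameters, `masks`, `spec`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims; p <- spec$pitch
  origin <- c(-(d[1] - 1) / 2 * p, -(d[2] - 1) / 2 * p, -(d[3] - 0.5) * p)
  xs <- origin[1] + (seq_len(d[1]) - 1) * p
  ys <- origin[2] + (seq_len(d[2]) - 1) * p
  zs <- origin[3] + (seq_len(d[3]) - 1) * p

  inn <- pmax(spec$semi_axes - spec$skin_mm, 0.1)
  objs <- with_preserved_seed(spec$seed, {
    sample_in_half_ellipsoid <- function(semi, zmax = 0) {
      repeat {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) <= 1 && u[3] * semi[3] <= zmax) return(u * semi)
      }
    }
    blobs <- lapply(seq_len(spec$n_glandular_blobs), function(i) {
      list(center = sample_in_half_ellipsoid(0.75 * inn),
           semi = stats::runif(3, spec$blob_mm[1], spec$blob_mm[2]))
    })
    calcs <- lapply(seq_len(spec$n_calcifications), function(i) {
      diam <- stats::runif(1, spec$calc_diam_mm[1], spec$calc_diam_mm[2])
      r <- diam / 2
      repeat {
        c0 <- sample_in_half_ellipsoid(pmax(inn - r, 0.1), zmax = -r)
        if (sum((c0 / pmax(inn - r, 0.1))^2) <= 1 && c0[3] + r <= 0) break
      }
      list(center = c0, diameter = diam)
    })
    list(blobs = blobs, calcs = calcs)
  })

  mus <- c(0, spec$mu_adipose, spec$mu_fibroglandular, spec$mu_skin,
           spec$mu_calcification)

  lab_coarse <- .phantom_labelmap(spec, xs, ys, zs, objs$blobs, objs$calcs)
  ss <- spec$supersample
  if (ss > 1) {
    sub <- function(coord, pitch) {
      off <- ((seq_len(ss) - 0.5) / ss - 0.5) * pitch
      as.vector(outer(off, coord, "+"))
    }
    labf <- .phantom_labelmap(spec, sub(xs, p), sub(ys, p), sub(zs, p),
                              objs$blobs, objs$calcs)
    muf <- array(mus[labf + 1L], dim(labf))
    # average ss^3 blocks back to the coarse grid
    m <- array(muf, c(ss, d[1], ss, d[2], ss, d[3]))
    m <- aperm(m, c(1, 3, 5, 2, 4, 6))
    vals <- array(colMeans(matrix(m, nrow = ss^3)), d)
  } else {
    vals <- array(mus[lab_coarse + 1L], d)
  }

  masks <- list(
    adipose = lab_coarse == .phantom_labels[["adipose"]],
    fibroglandular = lab_coarse == .phantom_labels[["glandular"]],
    skin = lab_coarse == .phantom_labels[["skin"]],
    calcification = lab_coarse == .phantom_labels[["calc"]])
  calc_df <- do.call(rbind, lapply(objs$calcs, function(cc)
    data.frame(x = cc$center[1], y = cc$center[2], z = cc$center[3],
               diameter = cc$diameter)))
  if (is.null(calc_df))
    calc_df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          diameter = numeric(0))

  list(volume = ct_volume(vals, pitch = p, origin = origin),
       annotation = list(calcifications = calc_df, masks = masks,
                         spec = spec))
}

#' Analytic line integral through a homogeneous ellipsoid
#'
#' Closed-form chord length of the segment `s + t (d - s)`, `t` in `[0, 1]`,
#' through an axis-aligned ellipsoid, times the attenuation `mu0`. Serves as
#' the independent oracle for the discretized forward projector.
#'
#' @param center ellipsoid center, mm.
#' @param semi_axes semi-axes `(a, b, c)`, mm (all > 0).
#' @param mu0 attenuation, 1/cm.
#' @param ray a `ct_ray` from [make_ray()] (clipping is ignored; the full
#'   source-to-detector segment is used).
#' @return projection value (unitless, 1/cm times cm); 0 if the ray misses.
#' @export
ellipsoid_line_integral <- function(center, semi_axes, mu0, ray) {
  stopifnot(all(semi_axes > 0))
  s <- (ray$source - center) / semi_axes
  e <- (ray$det_point - ray$source) / semi_axes
  a <- sum(e^2); b <- 2 * sum(s * e); cc <- sum(s^2) - 1
  disc <- b^2 - 4 * a * cc
  if (disc <= 0 || a == 0) return(0)
  t1 <- max((-b - sqrt(disc)) / (2 * a), 0)
  t2 <- min((-b + sqrt(disc)) / (2 * a), 1)
  if (t2 <= t1) return(0)
  chord_mm <- (t2 - t1) * ray_length(ray)
  mu0 * chord_mm * 0.1
}
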