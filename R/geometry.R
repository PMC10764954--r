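#' Cone-beam acquisition geometry
#'
#' Describes a circular cone-beam CT acquisition: the x-ray source rotates in
#' the `xy` plane on a circle of radius `d_so` about the `z` axis, with the
#' flat-panel detector perpendicular to the source-to-isocenter direction at
#' distance `d_sd` from the source. View angles are measured counter-clockwise
#' from `+x` (seen from `+z`). The detector `u` axis lies in the rotation
#' plane along `(sin(beta), -cos(beta), 0)` (so that the complementary-ray
#' relation `f(beta, gamma) = f(beta + pi + 2*gamma, -gamma)` holds with
#' `gamma = atan(x_u / d_sd)`) and may be displaced laterally
#' (fan direction) by `lateral_offset`; the `v` axis is parallel to the
#' rotation axis with row 0 at `det_origin_v` and rows extending toward `-z`
#' (half-cone setup: the chest-wall plane `z = det_origin_v = 0` is the
#' central source plane and the pendant breast hangs below it).
#'
#' Pixel centers sit at half-integer offsets: column `u` (0-based) is centered
#' at `x_u = (u + 0.5) * pitch_u - width/2 + lateral_offset` in-plane, row `v`
#' at `z_v = det_origin_v - (v + 0.5) * pitch_v`.
#'
#' @param d_so source-to-rotation-axis distance, mm.
#' @param d_sd source-to-detector distance, mm (`d_sd > d_so`).
#' @param n_u,n_v detector column / row counts.
#' @param pitch_u,pitch_v detector pixel pitch, mm.
#' @param n_views number of view angles, generated as `beta_j = 2*pi*j/n_views`
#'   scaled to `arc_deg` (`j = 0 .. n_views-1`; no view at the closing angle).
#' @param view_angles optional explicit strictly increasing angles (radians);
#'   overrides `n_views`.
#' @param lateral_offset signed lateral detector shift along `u`, mm.
#' @param arc_deg angular coverage of the generated view angles, degrees.
#' @param det_origin_v world `z` of the detector row-0 edge, mm. Use
#'   `n_v * pitch_v / 2` for a detector centered on the source plane.
#' @return An object of class `cone_beam_geometry`.
#' @seealso [geom_kbct1000()] for the clinical breast-CT preset,
#'   [gamma_of_column()], [source_position()], [detector_pixel_position()].
#' @export
cone_beam_geometry <- function(d_so, d_sd, n_u, n_v, pitch_u, pitch_v,
                               n_views = NULL, view_angles = NULL,
                               lateral_offset = 0, arc_deg = 360,
                               det_origin_v = 0) {
  stopifnot(d_sd > d_so, d_so > 0, pitch_u > 0, pitch_v > 0,
            n_u >= 1, n_v >= 1)
  if (is.null(view_angles)) {
    stopifnot(!is.null(n_views), n_views >= 1, arc_deg > 0, arc_deg <= 360)
    view_angles <- (arc_deg * pi / 180) * (seq_len(n_views) - 1) / n_views
  } else {
    stopifnot(all(diff(view_angles) > 0))
  }
  g <- list(d_so = d_so, d_sd = d_sd, n_u = as.integer(n_u),
            n_v = as.integer(n_v), pitch_u = pitch_u, pitch_v = pitch_v,
            view_angles = view_angles, lateral_offset = lateral_offset,
            arc_deg = arc_deg, det_origin_v = det_origin_v)
  class(g) <- "cone_beam_geometry"
  g
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat("Cone-beam geometry\n")
  cat(sprintf("  d_so %.1f mm, d_sd %.1f mm\n", x$d_so, x$d_sd))
  cat(sprintf("  detector %d x %d px @ %.4g x %.4g mm, lateral offset %.4g mm\n",
              x$n_u, x$n_v, x$pitch_u, x$pitch_v, x$lateral_offset))
  cat(sprintf("  %d views over %.1f deg; half-fan angle %.2f deg\n",
              length(x$view_angles), x$arc_deg, gamma_max(x) * 180 / pi))
  invisible(x)
}

#' Scanner preset: clinical cone-beam breast CT prototype
#'
#' Geometry of the KBCT-1000-class prototype: 650 mm source-to-axis,
#' 898 mm source-to-detector, 1024 x 768 detector at 0.388 mm pitch,
#' 300 views over 360 degrees, half-cone (chest wall at detector row 0).
#'
#' @param scale divide detector pixel counts by this factor while multiplying
#'   the pitch by it, preserving the physical panel size and therefore all
#'   fan/cone angles and redundancy weights; distances are untouched. Use
#'   e.g. `scale = 8` for a desk-scale 128 x 96 detector.
#' @param n_views number of views (default 300).
#' @return A [cone_beam_geometry()].
#' @export
geom_kbct1000 <- function(scale = 1, n_views = 300) {
  cone_beam_geometry(d_so = 650, d_sd = 898,
                     n_u = 1024 / scale, n_v = 768 / scale,
                     pitch_u = 0.388 * scale, pitch_v = 0.388 * scale,
                     n_views = n_views)
}

#' Source position at a view angle
#'
#' The source trajectory is `s(beta) = (d_so cos(beta), d_so sin(beta), 0)`.
#'
#' @param geom a [cone_beam_geometry()].
#' @param beta view angle(s), radians.
#' @return numeric matrix `length(beta) x 3` (mm); a single angle gives 1 row.
#' @export
source_position <- function(geom, beta) {
  cbind(x = geom$d_so * cos(beta), y = geom$d_so * sin(beta), z = 0)
}

#' Signed in-plane displacement of detector column centers
#'
#' World-frame distance of each column center from the source-to-isocenter
#' line, including the lateral detector offset.
#'
#' @param geom a [cone_beam_geometry()].
#' @param u 0-based column index (vectorized); default all columns.
#' @return numeric vector, mm.
#' @export
detector_u_offsets <- function(geom, u = seq_len(geom$n_u) - 1) {
  stopifnot(all(u >= 0), all(u < geom$n_u))
  (u + 0.5) * geom$pitch_u - geom$n_u * geom$pitch_u / 2 + geom$lateral_offset
}

#' World z of detector row centers
#' @inheritParams detector_u_offsets
#' @param v 0-based row index (vectorized); default all rows.
#' @return numeric vector, mm.
#' @export
detector_v_offsets <- function(geom, v = seq_len(geom$n_v) - 1) {
  stopifnot(all(v >= 0), all(v < geom$n_v))
  geom$det_origin_v - (v + 0.5) * geom$pitch_v
}

#' World position of a detector pixel center
#'
#' @inheritParams source_position
#' @param u,v 0-based column / row indices (equal-length vectors).
#' @return numeric matrix `n x 3`, mm.
#' @export
detector_pixel_position <- function(geom, beta, u, v) {
  xu <- detector_u_offsets(geom, u)
  zv <- detector_v_offsets(geom, v)
  cx <- (geom$d_so - geom$d_sd) * cos(beta)
  cy <- (geom$d_so - geom$d_sd) * sin(beta)
  cbind(x = cx + xu * sin(beta), y = cy - xu * cos(beta), z = zv)
}

#' Fan angle of a detector column
#'
#' `gamma = atan(x_u / d_sd)` where `x_u` is the signed in-plane displacement
#' of the column center from the source-to-isocenter line (lateral offset
#' included). Strictly increasing in `u`.
#'
#' @inheritParams detector_u_offsets
#' @return angle(s), radians.
#' @export
gamma_of_column <- function(geom, u = seq_len(geom$n_u) - 1) {
  atan(detector_u_offsets(geom, u) / geom$d_sd)
}

#' Half-fan angle of the detector
#'
#' Largest magnitude of [gamma_of_column()] at the detector edge, derived from
#' the geometry (the outer edge of the outermost pixel, not its center).
#'
#' @param geom a [cone_beam_geometry()].
#' @return angle, radians.
#' @export
gamma_max <- function(geom) {
  half <- geom$n_u * geom$pitch_u / 2
  edges <- c(-half, half) + geom$lateral_offset
  max(abs(atan(edges / geom$d_sd)))
}

#' Construct a field-of-view-clipped ray
#'
#' Builds the ray from the source to a detector pixel center, parameterized as
#' `s + t (d - s)` with `t` in `[0, 1]`, and clips it to the cylindrical
#' reconstruction field of view (axis = rotation axis) intersected with a `z`
#' slab. If the ray misses the FOV, `entry_t == exit_t` and any downstream
#' integration yields 0.
#'
#' @inheritParams source_position
#' @param u,v 0-based pixel indices (scalars).
#' @param fov_radius FOV cylinder radius, mm.
#' @param fov_z length-2 numeric, `z` extent of the FOV, mm.
#' @return An object of class `ct_ray`: list with `source`, `det_point`
#'   (3-vectors, mm), `entry_t`, `exit_t`.
#' @export
make_ray <- function(geom, beta, u, v, fov_radius,
                     fov_z = c(-Inf, Inf)) {
  stopifnot(fov_radius > 0)
  s <- drop(source_position(geom, beta))
  d <- drop(detector_pixel_position(geom, beta, u, v))
  z0 <- max(fov_z[1], -1e30); z1 <- min(fov_z[2], 1e30)
  tt <- cpp_clip_ray(as.numeric(s), as.numeric(d), fov_radius, z0, z1)
  structure(list(source = as.numeric(s), det_point = as.numeric(d),
                 entry_t = tt[1], exit_t = tt[2]),
            class = "ct_ray")
}

#' Length of a ray (source to detector point), mm
#' @param ray a `ct_ray`.
#' @return numeric, mm.
#' @export
ray_length <- function(ray) {
  sqrt(sum((ray$det_point - ray$source)^2))
}

#' Emulate a short-scan, offset-detector acquisition
#'
#' Restricts a full acquisition to a symmetric short arc and one-sidedly
#' truncated detector by editing the acquisition mask; masked pixels are
#' flagged missing, never zeroed, so consumers choose zero-fill vs exclusion.
#'
#' The retained arc is centered on `beta = pi/2` (the head-feet direction;
#' the unacquired gap is centered on `beta = 3*pi/2`). Columns are removed
#' from the low-`u` side of every retained view ("left" truncation, fixed in
#' the detector frame). The number of removed columns is
#' `round(2 * offset_mm / pitch_u)` when a physical lateral offset is given,
#' or may be passed exactly as `n_trunc_cols` (the clinical emulation removes
#' 256 of 1024 columns for a 5 cm shift of a 40 cm-wide panel).
#'
#' The operation is idempotent for fixed arguments.
#'
#' @param ps a [projection_set()] holding the full acquisition.
#' @param arc_deg retained angular coverage, degrees (<= 360).
#' @param offset_mm lateral detector offset, mm (used if `n_trunc_cols` is
#'   `NULL`; twice the offset is removed from the panel width).
#' @param n_trunc_cols exact number of truncated columns (overrides
#'   `offset_mm`).
#' @return A [projection_set()] with an updated mask; attributes `arc_deg` and
#'   `n_trunc_cols` record the emulation.
#' @export
emulate_short_scan_offset <- function(ps, arc_deg, offset_mm = NULL,
                                      n_trunc_cols = NULL) {
  stopifnot(inherits(ps, "projection_set"), arc_deg > 0, arc_deg <= 360)
  geom <- ps$geom
  if (is.null(n_trunc_cols)) {
    if (is.null(offset_mm)) offset_mm <- 0
    n_trunc_cols <- round(2 * offset_mm / geom$pitch_u)
  }
  n_trunc_cols <- as.integer(n_trunc_cols)
  if (n_trunc_cols < 0 || 2 * n_trunc_cols > 2 * geom$n_u)
    stop("truncation exceeds the detector width")
  if (n_trunc_cols >= geom$n_u) stop("truncation removes the whole detector")

  half <- arc_deg / 2 * pi / 180
  dist <- abs(((geom$view_angles - pi / 2 + pi) %% (2 * pi)) - pi)
  keep_view <- dist <= half + 1e-9

  mask <- ps$mask
  mask[, , !keep_view] <- FALSE
  if (n_trunc_cols > 0) mask[seq_len(n_trunc_cols), , ] <- FALSE

  out <- projection_set(ps$values, geom, mask = mask, i0 = ps$i0)
  attr(out, "arc_deg") <- arc_deg
  attr(out, "n_trunc_cols") <- n_trunc_cols
  out
}

#' Empirical undersampling rate of an acquisition mask
#'
#' Fraction of pixels flagged acquired over the full-scan, full-detector grid.
#'
#' @param mask logical array (or a [projection_set()], whose mask is used).
#' @return fraction in `[0, 1]`.
#' @export
undersampling_rate <- function(mask) {
  if (inherits(mask, "projection_set")) mask <- mask$mask
  if (length(mask) == 0) stop("empty mask")
  mean(mask)
}

#' Analytic sampling rate of a short-scan, offset-detector acquisition
#'
#' Product rule `(arc/360) * (1 - 2*offset/width)`: the fraction of the
#' full-scan, full-width sinogram that is acquired.
#'
#' @param arc_deg angular coverage, degrees.
#' @param offset lateral detector offset (any length unit).
#' @param width detector width (same unit as `offset`).
#' @return fraction in `[0, 1]`.
#' @export
analytic_sampling_rate <- function(arc_deg, offset, width) {
  stopifnot(arc_deg > 0, arc_deg <= 360, 2 * offset <= width)
  (arc_deg / 360) * (1 - 2 * offset / width)
}

#' Serialize / deserialize geometry as JSON
#' @param geom a [cone_beam_geometry()].
#' @param path file path.
#' @return `read_geometry` returns a [cone_beam_geometry()].
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(unclass(geom), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  cone_beam_geometry(d_so = g$d_so, d_sd = g$d_sd, n_u = g$n_u, n_v = g$n_v,
                     pitch_u = g$pitch_u, pitch_v = g$pitch_v,
                     view_angles = g$view_angles,
                     lateral_offset = g$lateral_offset,
                     arc_deg = g$arc_deg, det_origin_v = g$det_origin_v)
}
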