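#' Cone-beam forward projection of a volume
#'
#' Computes `p(beta, u, v) = integral of mu along the source-to-pixel ray`
#' by the midpoint rule on `samples_per_ray` uniform bins of the FOV-clipped
#' ray, fetching attenuation by trilinear interpolation (zero outside the
#' volume). Segment lengths are taken in cm so values are consistent with
#' attenuation in 1/cm. Only the primary beam is modeled (no scatter or beam
#' hardening).
#'
#' @param vol a [ct_volume()].
#' @param geom a [cone_beam_geometry()].
#' @param samples_per_ray number of bins per ray (>= 2).
#' @param fov_radius FOV cylinder radius, mm; default encloses the volume's
#'   `x`/`y` extent.
#' @param fov_z FOV `z` extent, mm; default the volume's `z` extent (plus one
#'   voxel of margin).
#' @return A [projection_set()] with an all-true mask.
#' @export
forward_project <- function(vol, geom, samples_per_ray = 256,
                            fov_radius = NULL, fov_z = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(geom, "cone_beam_geometry"),
            samples_per_ray >= 2)
  d <- dim(vol$values)
  if (is.null(fov_radius)) {
    ext_x <- max(abs(vol$origin[1] + c(-0.5, d[1] - 0.5) * vol$pitch))
    ext_y <- max(abs(vol$origin[2] + c(-0.5, d[2] - 0.5) * vol$pitch))
    fov_radius <- sqrt(ext_x^2 + ext_y^2)
  }
  if (is.null(fov_z)) {
    fov_z <- c(vol$origin[3] - vol$pitch, vol$origin[3] + d[3] * vol$pitch)
  }
  vals <- cpp_forward_project(as.numeric(vol$values), d, vol$origin,
                              vol$pitch, geom$view_angles, geom$d_so,
                              geom$d_sd, detector_u_offsets(geom),
                              detector_v_offsets(geom), fov_radius,
                              as.numeric(fov_z), as.integer(samples_per_ray))
  projection_set(vals, geom)
}
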