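#' Stack of cone-beam projections with an acquisition mask
#'
#' Holds log-converted line integrals `p(beta, u, v)` (unitless; attenuation
#' in 1/cm times path length in cm) for every view of a geometry, together
#' with a same-shaped logical acquisition mask marking acquired vs missing
#' pixels. Arrays are stored with dimensions `(n_u, n_v, n_views)` (column,
#' row, view).
#'
#' @param values numeric array `(n_u, n_v, n_views)`.
#' @param geom the [cone_beam_geometry()] the stack was acquired with.
#' @param mask logical array of the same shape; default all acquired.
#' @param i0 optional incident photon count used for intensity realizations.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(values, geom, mask = NULL, i0 = NULL) {
  stopifnot(inherits(geom, "cone_beam_geometry"))
  d <- dim(values)
  stopifnot(length(d) == 3, d[1] == geom$n_u, d[2] == geom$n_v,
            d[3] == length(geom$view_angles))
  if (is.null(mask)) {
    mask <- array(TRUE, d)
  } else {
    stopifnot(identical(dim(mask), d), is.logical(mask))
  }
  stopifnot(all(is.finite(values[mask])))
  structure(list(values = values, mask = mask, geom = geom, i0 = i0),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("projection_set %d x %d px, %d views; %.1f%% acquired\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Beer-Lambert intensity model
#'
#' `to_intensity` maps line integrals to detected intensities
#' `I = I0 exp(-p)`, optionally replacing each pixel with a Poisson draw of
#' that mean (quantum noise). `from_intensity` applies the log conversion
#' `p = -ln(I / I0)`; nonpositive intensities (possible for Poisson draws of
#' zero) are clipped to `min_counts` before the log.
#'
#' @param ps a [projection_set()] of line integrals.
#' @param i0 incident photon count (> 0).
#' @param noise_seed optional integer; if given, Poisson noise is applied
#'   reproducibly.
#' @return `to_intensity`: numeric array of intensities.
#' @export
to_intensity <- function(ps, i0, noise_seed = NULL) {
  stopifnot(i0 > 0)
  intens <- i0 * exp(-ps$values)
  if (!is.null(noise_seed)) {
    intens <- with_preserved_seed(noise_seed, {
      array(stats::rpois(length(intens), lambda = intens), dim(intens))
    })
  }
  intens
}

#' @rdname to_intensity
#' @param intensity numeric array of detected counts.
#' @param geom the acquisition geometry.
#' @param mask optional acquisition mask.
#' @param min_counts floor applied to nonpositive counts before the log
#'   (default 0.5).
#' @return `from_intensity`: a [projection_set()] of line integrals.
#' @export
from_intensity <- function(intensity, i0, geom, mask = NULL, min_counts = 0.5) {
  stopifnot(i0 > 0)
  intensity <- pmax(intensity, min_counts)
  projection_set(-log(intensity / i0), geom, mask = mask, i0 = i0)
}

#' Write / read a projection set (raw float32 + JSON sidecar)
#'
#' `values` and `mask` are stored as little-endian float32 / uint8 alongside a
#' JSON sidecar holding the dimensions, geometry and incident photon count.
#'
#' @param ps a [projection_set()].
#' @param path base path; `<path>.bin`, `<path>.mask.bin` and `<path>.json`
#'   are written.
#' @return `read_projections` returns a [projection_set()].
#' @export
write_projections <- function(ps, path) {
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(ps$values), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(path, ".mask.bin"), "wb")
  writeBin(as.integer(ps$mask), con, size = 1)
  close(con)
  meta <- list(dims = dim(ps$values), geom = unclass(ps$geom), i0 = ps$i0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  n <- prod(d)
  con <- file(paste0(path, ".bin"), "rb")
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  close(con)
  con <- file(paste0(path, ".mask.bin"), "rb")
  msk <- readBin(con, "integer", n = n, size = 1, signed = FALSE)
  close(con)
  g <- meta$geom
  geom <- cone_beam_geometry(d_so = g$d_so, d_sd = g$d_sd, n_u = g$n_u,
                             n_v = g$n_v, pitch_u = g$pitch_u,
                             pitch_v = g$pitch_v, view_angles = g$view_angles,
                             lateral_offset = g$lateral_offset,
                             arc_deg = g$arc_deg,
                             det_origin_v = g$det_origin_v)
  projection_set(array(vals, d), geom, mask = array(msk > 0, d),
                 i0 = meta$i0)
}
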