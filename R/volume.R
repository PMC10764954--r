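#' Attenuation volume on a regular voxel grid
#'
#' A discrete attenuation map `mu(r)` (1/cm) on an isotropic voxel grid with a
#' world-coordinate mapping. `origin` is the world position (mm) of the center
#' of voxel `(1,1,1)` (R indexing); voxel `(i,j,k)` is centered at
#' `origin + (i-1, j-1, k-1) * pitch`.
#'
#' @param values 3D numeric array, attenuation in 1/cm.
#' @param pitch voxel pitch, mm.
#' @param origin numeric length 3, mm. Default centers the grid on the
#'   rotation axis in `x`/`y` and stacks it below `z = 0` (half-cone setup).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, pitch, origin = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3, pitch > 0,
            all(is.finite(values)))
  d <- dim(values)
  if (is.null(origin)) {
    origin <- c(-(d[1] - 1) / 2 * pitch, -(d[2] - 1) / 2 * pitch,
                -(d[3] - 0.5) * pitch)
  }
  structure(list(values = values, pitch = pitch, origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ct_volume %d x %d x %d @ %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              d[1], d[2], d[3], x$pitch, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  mu range [%.4g, %.4g] 1/cm\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel-center world coordinates along one axis
#' @param vol a [ct_volume()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector, mm.
#' @export
voxel_centers <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$pitch
}

#' Trilinear interpolation of a volume at world points
#'
#' Zero outside the grid support (consistent with the forward projector).
#'
#' @param vol a [ct_volume()].
#' @param pts numeric matrix `n x 3`, mm.
#' @return numeric vector of attenuations, 1/cm.
#' @export
interp_volume <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_trilinear(as.numeric(vol$values), dim(vol$values), vol$origin,
                vol$pitch, pts)
}

#' Write / read a volume as NIfTI with correct voxel size
#'
#' The world origin is stored in the NIfTI sform; attenuation values (1/cm)
#' are stored as-is.
#'
#' @param vol a [ct_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [ct_volume()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  p <- vol$pitch
  xf <- rbind(c(p, 0, 0, vol$origin[1]),
              c(0, p, 0, vol$origin[2]),
              c(0, 0, p, vol$origin[3]),
              c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            pitch = xf[1, 1], origin = xf[1:3, 4])
}
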