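#' Transaxial Siddon look-up table
#'
#' Pre-computes, for every transaxial (angle, radial) bin, the exact 2-D
#' Siddon intersections of the crystal-to-crystal ray with the image grid,
#' stored as parametric intervals `[t0, t1]` along the segment from crystal A
#' to crystal B. The same parameter serves the 3-D path of any ring pair
#' because z is linear in t; the axial part is merged on the fly during
#' projection, giving exact 3-D Siddon lengths.
#'
#' @param geom A `pet_geometry`.
#' @param image_spec A `pet_image` (only its grid is used).
#' @return A `pet_tx_lut` list.
#' @export
build_transaxial_lut <- function(geom, image_spec) {
  dm <- img_dim(image_spec)
  corner <- grid_corner(image_spec)
  half_x <- max(abs(c(corner[1], corner[1] + dm[1] * image_spec$voxel_size[1])))
  half_y <- max(abs(c(corner[2], corner[2] + dm[2] * image_spec$voxel_size[2])))
  # square grids may have corners outside the circular FOV, but the grid must
  # not extend beyond the detector ring in any axis direction
  if (min(half_x, half_y) > geom$ring_diameter / 2)
    stop2("transaxial image FOV extends outside the detector ring")
  bm <- build_sino_bin_map(geom)
  xy <- crystal_xy(geom)
  lut <- cpp_tx_lut(bm$k1, bm$k2, xy[, 1], xy[, 2],
                    dm[1], dm[2], image_spec$voxel_size[1], image_spec$voxel_size[2],
                    corner[1], corner[2])
  structure(list(ptr = lut$ptr, col = lut$col, tin = lut$tin, tout = lut$tout,
                 d2 = lut$d2, binmap = bm,
                 dims = dm, voxel_size = image_spec$voxel_size,
                 corner = corner, geom_hash = geometry_hash(geom)),
            class = "pet_tx_lut")
}

check_lut <- function(lut, geom, img = NULL) {
  if (!inherits(lut, "pet_tx_lut")) stop2("not a pet_tx_lut")
  if (!identical(lut$geom_hash, geometry_hash(geom)))
    stop2("LUT geometry hash mismatch")
  if (!is.null(img)) {
    if (!identical(img_dim(img), lut$dims) ||
        max(abs(img$voxel_size - lut$voxel_size)) > 1e-9 ||
        max(abs(grid_corner(img) - lut$corner)) > 1e-6)
      stop2("image grid does not match the LUT grid")
  }
  invisible(lut)
}

subset_bins <- function(geom, subset) {
  if (is.null(subset)) subset <- 0:(geom$n_angles - 1L)
  if (any(subset < 0L | subset >= geom$n_angles)) stop2("angle subset out of range")
  as.integer(rep(subset * geom$n_radial_bins, each = geom$n_radial_bins) +
               0:(geom$n_radial_bins - 1L))
}

#' Forward projection
#'
#' Computes the expected line integrals `q_i = sum_j p_ij n_j` for every
#' span-1 plane and the selected angles; `p_ij` is the exact 3-D Siddon
#' intersection length in mm. Ray tracing is always span-1; compress with
#' [reduce_span()] if needed.
#'
#' @param image A `pet_image` on the LUT grid.
#' @param lut A `pet_tx_lut` from [build_transaxial_lut()].
#' @param geom A `pet_geometry`.
#' @param subset Optional 0-based angle indices (default all angles).
#' @return A span-1 `pet_sinogram`; bins outside the subset are zero.
#' @export
forward_project <- function(image, lut, geom, subset = NULL) {
  check_lut(lut, geom, image)
  if (any(!is.finite(image$values))) stop2("non-finite values in image")
  mi <- michelogram_map(geom)
  z <- ring_z(geom)
  bins <- subset_bins(geom, subset)
  nb <- geom$n_radial_bins * geom$n_angles
  v <- cpp_forward(as.numeric(image$values),
                   lut$dims[1], lut$dims[2], lut$dims[3],
                   image$voxel_size[3], grid_corner(image)[3],
                   lut$ptr, lut$col, lut$tin, lut$tout, lut$d2,
                   z[mi$r0 + 1L], z[mi$r1 + 1L], bins, nb)
  new_sinogram(geom, 1L, array(v, c(geom$n_radial_bins, geom$n_angles, mi$n_planes)))
}

#' Back projection (exact adjoint of [forward_project()])
#'
#' @param sino A span-1 `pet_sinogram`.
#' @inheritParams forward_project
#' @return A `pet_image` on the LUT grid.
#' @export
back_project <- function(sino, lut, geom, subset = NULL) {
  check_lut(lut, geom)
  check_sino(sino, geom, span = 1L)
  mi <- michelogram_map(geom)
  z <- ring_z(geom)
  bins <- subset_bins(geom, subset)
  nb <- geom$n_radial_bins * geom$n_angles
  vox <- lut$voxel_size
  v <- cpp_back(as.numeric(sino),
                lut$dims[1], lut$dims[2], lut$dims[3],
                vox[3], lut$corner[3],
                lut$ptr, lut$col, lut$tin, lut$tout, lut$d2,
                z[mi$r0 + 1L], z[mi$r1 + 1L], bins, nb)
  new_image(array(v, lut$dims), vox, origin = lut$corner + vox / 2)
}

#' Attenuation factor sinogram
#'
#' `AF_i = exp(-sum_j p_ij mu_j / 10)` with `p_ij` in mm and `mu` in cm^-1;
#' factors are in (0, 1] and equal 1 where the ray misses the object.
#'
#' @param mumap A `pet_image` of linear attenuation coefficients (cm^-1).
#' @inheritParams forward_project
#' @return A span-1 `pet_sinogram` of factors.
#' @export
attenuation_factors <- function(mumap, lut, geom, subset = NULL) {
  if (any(mumap$values < 0)) stop2("negative attenuation coefficients")
  p <- forward_project(mumap, lut, geom, subset)
  af <- exp(-p / 10)
  attributes(af) <- attributes(p)
  af
}
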