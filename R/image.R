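#' 3-D image on the scanner grid
#'
#' Voxel container used for emission images, attenuation maps (cm^-1 at
#' 511 keV) and integer parcellations. Values are stored column-major as
#' `[x, y, z]` with per-axis voxel size in mm; `origin` is the mm coordinate
#' of the centre of voxel `[1, 1, 1]` relative to the scanner iso-centre.
#' By default the grid is centred on the iso-centre.
#'
#' @param values 3-D numeric array.
#' @param voxel_size Numeric length-3, mm per axis (x, y, z).
#' @param origin Optional numeric length-3 (mm); default centres the grid.
#' @return A `pet_image`.
#' @export
new_image <- function(values, voxel_size, origin = NULL) {
  if (length(dim(values)) != 3L) stop2("image values must be a 3-D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop2("voxel sizes must be positive")
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * voxel_size
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "pet_image")
}

#' @export
print.pet_image <- function(x, ...) {
  cat(sprintf("pet_image: %s voxels of %s mm, origin (%s) mm, sum %.6g\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", "),
              sum(x$values)))
  invisible(x)
}

img_dim <- function(img) dim(img$values)

# mm coordinate of the *low edge* of the grid on each axis.
grid_corner <- function(img) img$origin - img$voxel_size / 2

# Voxel-centre coordinates along one axis (mm).
axis_centres <- function(img, ax) {
  img$origin[ax] + (seq_len(dim(img$values)[ax]) - 1) * img$voxel_size[ax]
}

check_same_grid <- function(a, b, what = "images") {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$voxel_size - b$voxel_size)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6)
    stop2("%s are not on the same voxel grid", what)
  invisible(TRUE)
}

#' Block-mean image downsampling
#'
#' Reduces each axis by an integer factor using block means, with a centred
#' crop when a dimension is not divisible by the factor. Attenuation maps
#' keep their mean value over the common support; to preserve total activity
#' of emission images multiply by the voxel-volume ratio (`preserve =
#' "sum"` does this for you).
#'
#' @param img A `pet_image`.
#' @param factor Integer >= 1 (scalar, applied to all axes).
#' @param preserve `"mean"` (default; right for mu-maps) or `"sum"`
#'   (total-preserving, for emission images).
#' @return A `pet_image` with dims `floor(dim / factor)`.
#' @export
downsample_image <- function(img, factor, preserve = c("mean", "sum")) {
  preserve <- match.arg(preserve)
  factor <- as.integer(factor)
  if (factor < 1L) stop2("factor must be >= 1")
  dm <- img_dim(img)
  if (any(factor > dm)) stop2("factor larger than an image dimension")
  if (factor == 1L) return(img)
  nd <- dm %/% factor
  # centred crop of the leftover voxels
  off <- (dm - nd * factor) %/% 2L
  v <- img$values[off[1] + seq_len(nd[1] * factor),
                  off[2] + seq_len(nd[2] * factor),
                  off[3] + seq_len(nd[3] * factor), drop = FALSE]
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(v, c(2, 4, 6), mean)
  if (preserve == "sum") out <- out * factor^3
  # low-edge of kept block stays aligned; new centres shift accordingly
  corner <- grid_corner(img) + off * img$voxel_size
  new_vox <- img$voxel_size * factor
  new_image(out, new_vox, origin = corner + new_vox / 2)
}
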