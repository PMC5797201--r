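# Container I/O: NIfTI-1 images, sinogram payload + JSON sidecar,
# normalisation components, and the HU -> mu conversion utility.
#
# No NIfTI package ships with the supported R stack, so a minimal NIfTI-1
# reader/writer (uncompressed .nii, diagonal affine) is implemented here.

NIFTI_DTYPES <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                     `4` = list(what = "integer", size = 2L, signed = TRUE),
                     `8` = list(what = "integer", size = 4L, signed = TRUE),
                     `16` = list(what = "double", size = 4L, signed = TRUE),
                     `64` = list(what = "double", size = 8L, signed = TRUE))

#' Write an image as NIfTI-1
#'
#' Uncompressed single-file `.nii`, little-endian, diagonal sform affine
#' built from the voxel size and origin (mm, scanner iso-centre frame).
#'
#' @param img A `pet_image`.
#' @param path Output file path (`.nii`).
#' @param datatype `"float32"` (default), `"float64"` or `"int16"` (for
#'   integer parcellation labels).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, datatype = c("float32", "float64", "int16")) {
  datatype <- match.arg(datatype)
  code <- switch(datatype, float32 = 16L, float64 = 64L, int16 = 4L)
  bitpix <- switch(datatype, float32 = 32L, float64 = 64L, int16 = 16L)
  dm <- img_dim(img)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                          # sizeof_hdr
  wc(36L)                               # unused through dim_info
  wi(c(3L, dm, 1L, 1L, 1L, 1L), 2L)    # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)           # intent
  wi(code, 2L); wi(bitpix, 2L); wi(0L, 2L)
  wf(c(1, img$voxel_size, 1, 1, 1, 1)) # pixdim[8]
  wf(352)                              # vox_offset
  wf(1); wf(0)                         # scl_slope / scl_inter
  wi(0L, 2L); wc(1L)
  writeBin(as.raw(2L), con)            # xyzt_units: mm
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)
  wc(80L); wc(24L)                     # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)               # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))              # quaternion block
  wf(c(img$voxel_size[1], 0, 0, img$origin[1]))
  wf(c(0, img$voxel_size[2], 0, img$origin[2]))
  wf(c(0, 0, img$voxel_size[3], img$origin[3]))
  wc(16L)                              # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  wc(4L)                               # no extensions
  v <- img$values
  if (datatype == "int16") {
    v <- as.integer(round(v))
    writeBin(v, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = if (datatype == "float32") 4L else 8L,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' Supports the subset written by [write_nifti()]: uncompressed `.nii` with a
#' diagonal affine. Rotated affines are rejected.
#'
#' @param path File path.
#' @return A `pet_image`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 352L) stop2("truncated NIfTI header in %s", path)
  ri <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != 348L) stop2("%s is not a NIfTI-1 file", path)
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop2("unsupported NIfTI magic '%s'", magic)
  dm <- ri(40L, 2L, n = 8L)
  if (dm[1] < 3L) stop2("expected a 3-D NIfTI image")
  nd <- dm[2:4]
  code <- ri(70L, 2L)
  spec <- NIFTI_DTYPES[[as.character(code)]]
  if (is.null(spec)) stop2("unsupported NIfTI datatype code %d", code)
  vox_offset <- rf(108L)
  slope <- rf(112L); inter <- rf(116L)
  if (slope == 0) slope <- 1
  srow <- rbind(rf(280L, 4L), rf(296L, 4L), rf(312L, 4L))
  sform <- ri(254L, 2L)
  if (sform > 0L) {
    offdiag <- srow[1:3, 1:3]; diag(offdiag) <- 0
    if (max(abs(offdiag)) > 1e-6) stop2("rotated NIfTI affines are not supported")
    voxel <- abs(diag(srow[1:3, 1:3]))
    origin <- srow[, 4L]
  } else {
    voxel <- rf(76L, 8L)[2:4]
    origin <- -(nd - 1) / 2 * voxel
  }
  seek(con, where = vox_offset, origin = "start")
  n <- prod(nd)
  v <- readBin(con, spec$what, n = n, size = spec$size, signed = spec$signed,
               endian = "little")
  if (length(v) < n) stop2("truncated NIfTI payload in %s", path)
  v <- v * slope + inter
  new_image(array(v, nd), voxel, origin = origin)
}

# --- sinogram container -----------------------------------------------------

#' Write / read a sinogram container
#'
#' Flat little-endian float64 payload (radial fastest, then angle, then plane
#' in the canonical Michelogram order) plus a `.json` sidecar carrying the
#' geometry hash, span, dims and frame. Reads are rejected when the geometry
#' hash does not match.
#'
#' @param sino A `pet_sinogram`.
#' @param path Payload path; the sidecar is `paste0(path, ".json")`.
#' @param geom A `pet_geometry`.
#' @return `write_sinogram`: `path` invisibly; `read_sinogram`: a
#'   `pet_sinogram`.
#' @export
write_sinogram <- function(sino, path) {
  if (!inherits(sino, "pet_sinogram")) stop2("not a pet_sinogram")
  side <- list(format = "petquant-sinogram", version = 1L,
               geometry_hash = attr(sino, "geom_hash"),
               span = sino_span(sino),
               plane_order = "segment-major-z",
               dtype = "float64", dims = dim(sino),
               frame = attr(sino, "frame"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  writeBin(as.numeric(sino), con, size = 8L, endian = "little")
  close(con)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path, geom) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "petquant-sinogram")) stop2("not a sinogram container")
  if (!identical(side$geometry_hash, geometry_hash(geom)))
    stop2("sinogram geometry hash mismatch (file %s, geometry %s)",
          side$geometry_hash, geometry_hash(geom))
  if (!identical(side$dtype, "float64")) stop2("unsupported sinogram dtype %s", side$dtype)
  dm <- as.integer(side$dims)
  n <- prod(dm)
  con <- file(path, "rb")
  v <- readBin(con, "double", n = n, size = 8L, endian = "little")
  close(con)
  if (length(v) < n) stop2("truncated sinogram payload")
  span <- side$span
  if (!identical(span, "ssr")) span <- as.integer(span)
  new_sinogram(geom, span, array(v, dm), frame = side$frame)
}

# --- normalisation component container -------------------------------------

#' Write / read normalisation components
#'
#' JSON container (full precision) with the named datasets of
#' [norm_components()].
#' @param comp A `norm_components` list.
#' @param path File path (`.json`).
#' @param geom A `pet_geometry`.
#' @export
write_norm <- function(comp, path, geom) {
  obj <- unclass(comp)
  obj$.format <- "petquant-norm"
  obj$.geometry_hash <- geometry_hash(geom)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_norm
#' @export
read_norm <- function(path, geom) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$.format, "petquant-norm")) stop2("not a norm container")
  if (!identical(obj$.geometry_hash, geometry_hash(geom)))
    stop2("norm geometry hash mismatch")
  obj$.format <- NULL; obj$.geometry_hash <- NULL
  # absent optional components serialise as empty lists
  obj <- obj[!vapply(obj, function(x) is.null(x) || (is.list(x) && !length(x)), TRUE)]
  if (!is.null(obj$crystal_interference) && is.null(dim(obj$crystal_interference)))
    obj$crystal_interference <- matrix(obj$crystal_interference, geom$n_radial_bins)
  if (!is.null(obj$crystal_efficiencies) && is.null(dim(obj$crystal_efficiencies)))
    obj$crystal_efficiencies <- matrix(obj$crystal_efficiencies, geom$n_crystal_positions)
  do.call(norm_components, c(obj, list(geom = geom)))
}

# --- HU -> mu utility -------------------------------------------------------

#' Piecewise-linear HU to linear attenuation conversion
#'
#' Converts CT-like images in Hounsfield units to 511 keV linear attenuation
#' coefficients (cm^-1) through a piecewise-linear table. The default table
#' maps air (-1000 HU) to 0 and water (0 HU) to 0.096 cm^-1, with a reduced
#' slope above water as is standard for 511 keV.
#'
#' @param ct A `pet_image` in HU.
#' @param breakpoints Data frame or list with `hu` (monotone increasing) and
#'   `mu` columns.
#' @return A `pet_image` (mu-map, cm^-1).
#' @export
hu_to_mu <- function(ct, breakpoints = NULL) {
  if (is.null(breakpoints))
    breakpoints <- list(hu = c(-1000, 0, 1000, 3000),
                        mu = c(0, 0.096, 0.146, 0.246))
  hu <- as.numeric(breakpoints$hu); mu <- as.numeric(breakpoints$mu)
  if (is.unsorted(hu, strictly = TRUE)) stop2("HU breakpoints must be strictly increasing")
  v <- stats::approx(hu, mu, xout = pmax(pmin(as.numeric(ct$values), max(hu)), min(hu)),
                     rule = 2)$y
  out <- ct
  out$values <- array(pmax(v, 0), img_dim(ct))
  out
}
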