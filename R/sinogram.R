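#' Sinogram set
#'
#' Projection data container: a 3-D array `[radial, angle, plane]` with the
#' axial planes in the canonical Michelogram order of [michelogram_map()]
#' (for span-S, per-segment axial order; for `"ssr"`, by `r0 + r1`). Carries
#' the span and the geometry fingerprint so containers cannot be mixed across
#' geometries.
#'
#' @param geom A `pet_geometry`.
#' @param span Odd integer span or `"ssr"`.
#' @param data Optional array or scalar fill (default 0).
#' @param frame Optional numeric `c(t0, t1)` in seconds.
#' @return A `pet_sinogram` (numeric array with attributes `span`,
#'   `geom_hash`, `frame`).
#' @export
new_sinogram <- function(geom, span = geom$span, data = 0, frame = NULL) {
  np <- count_sinograms(geom, span)
  dm <- c(geom$n_radial_bins, geom$n_angles, np)
  if (length(data) == 1L) data <- array(data, dm)
  if (!identical(as.integer(dim(data)), as.integer(dm)))
    stop2("sinogram data dims [%s] do not match geometry/span [%s]",
          paste(dim(data), collapse = ","), paste(dm, collapse = ","))
  structure(data, span = span, geom_hash = geometry_hash(geom),
            frame = frame, class = "pet_sinogram")
}

sino_span <- function(s) attr(s, "span")

check_sino <- function(s, geom, span = NULL, what = "sinogram") {
  if (!inherits(s, "pet_sinogram")) stop2("%s is not a pet_sinogram", what)
  if (!identical(attr(s, "geom_hash"), geometry_hash(geom)))
    stop2("%s geometry hash mismatch", what)
  if (!is.null(span) && !identical(sino_span(s), span))
    stop2("%s span is %s, expected %s", what, sino_span(s), span)
  invisible(s)
}

#' @export
print.pet_sinogram <- function(x, ...) {
  cat(sprintf("pet_sinogram: %d radial x %d angles x %d planes, span %s, total %.6g\n",
              dim(x)[1], dim(x)[2], dim(x)[3], as.character(sino_span(x)), sum(x)))
  invisible(x)
}

#' Axial compression of a span-1 sinogram
#'
#' Sums span-1 planes into span-S groups or single-slice-rebinned planes
#' according to [span_group_map()]. Ray tracing in this package is always
#' performed in span-1; compressed outputs are formed by plane summation.
#'
#' @param sino A span-1 `pet_sinogram`.
#' @param geom A `pet_geometry`.
#' @param span Target: odd integer span or `"ssr"`.
#' @return A `pet_sinogram` with the target span.
#' @export
reduce_span <- function(sino, geom, span) {
  check_sino(sino, geom, span = 1L)
  map <- span_group_map(geom, span)
  dm <- dim(sino)
  out <- array(0, c(dm[1], dm[2], map$n_planes_out))
  for (p in seq_len(dm[3])) {
    g <- map$group_of_plane1[p] + 1L
    out[, , g] <- out[, , g] + sino[, , p]
  }
  new_sinogram(geom, span, out, frame = attr(sino, "frame"))
}

# Per-plane totals of a sinogram (vector over planes).
plane_totals <- function(sino) apply(sino, 3L, sum)
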