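#' Cylindrical PET scanner geometry
#'
#' Builds a validated description of a cylindrical PET scanner: detector ring
#' stack, transaxial crystal layout (including dead "gap" positions between
#' blocks), sinogram dimensions and the axial compression (span) convention.
#' All sinogram/Michelogram index algebra in the package derives from this
#' object.
#'
#' @param config Either a preset name (`"mmr"` for the 64-ring large
#'   axial-FOV PET/MR scanner, or `"mmr-reduced:<n>"` for a contiguous
#'   `n`-ring subset of it), or a named list with fields `n_rings`,
#'   `ring_pitch` (mm), `ring_diameter` (mm), `n_blocks_tx`,
#'   `crystals_per_block`, `gaps_per_block`, and optionally `gap_offset`
#'   (0-based in-block index where the dead run starts; default
#'   `crystals_per_block`, i.e. gaps trail each block), `n_radial_bins`,
#'   `max_ring_diff`, `span` (odd integer or `"ssr"`), `buckets_axial`,
#'   `buckets_tx`, `tau` (coincidence window, seconds).
#'
#' @return An object of class `pet_geometry`.
#'
#' @details The transaxial crystal positions are indexed `0 .. n_crystal_positions-1`
#' around the ring; `n_crystal_positions = n_blocks_tx * (crystals_per_block +
#' gaps_per_block)` and `n_angles = n_crystal_positions / 2`. Crystals are
#' modelled as points at the face centre on the ring of diameter
#' `ring_diameter`. Rings are centred axially so ring `r` sits at
#' `(r - (n_rings-1)/2) * ring_pitch` mm.
#'
#' The 64-ring preset uses 56 transaxial blocks of 8 crystals plus one dead
#' position, 504 crystal positions, 252 angles, 344 radial bins, maximum ring
#' difference 60 and 8 x 28 = 224 dead-time buckets. The in-block position of
#' the dead crystal is a convention of this package (trailing position of each
#' 9-position block); the resulting live-bin count is checked in the test
#' suite against the published figure for this scanner.
#'
#' @export
build_geometry <- function(config) {
  if (is.character(config)) config <- geometry_preset(config)
  req <- c("n_rings", "ring_pitch", "ring_diameter", "n_blocks_tx",
           "crystals_per_block", "gaps_per_block", "n_radial_bins",
           "max_ring_diff")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop2("geometry config missing fields: %s", paste(miss, collapse = ", "))

  g <- list(
    n_rings            = as.integer(config$n_rings),
    ring_pitch         = as.numeric(config$ring_pitch),
    ring_diameter      = as.numeric(config$ring_diameter),
    n_blocks_tx        = as.integer(config$n_blocks_tx),
    crystals_per_block = as.integer(config$crystals_per_block),
    gaps_per_block     = as.integer(config$gaps_per_block),
    gap_offset         = as.integer(config$gap_offset %||% config$crystals_per_block),
    n_radial_bins      = as.integer(config$n_radial_bins),
    max_ring_diff      = as.integer(config$max_ring_diff),
    span               = config$span %||% 1L,
    buckets_axial      = as.integer(config$buckets_axial %||% 1L),
    buckets_tx         = as.integer(config$buckets_tx %||% 1L),
    tau                = as.numeric(config$tau %||% 5.85e-9)
  )
  counts <- c(g$n_rings, g$ring_pitch, g$ring_diameter, g$n_blocks_tx,
              g$crystals_per_block, g$n_radial_bins)
  if (any(counts <= 0)) stop2("geometry counts and sizes must be positive")
  if (g$gaps_per_block < 0) stop2("gaps_per_block must be >= 0")
  per_block <- g$crystals_per_block + g$gaps_per_block
  g$n_crystal_positions <- g$n_blocks_tx * per_block
  if (g$n_crystal_positions %% 2L != 0L)
    stop2("n_crystal_positions (%d) must be even", g$n_crystal_positions)
  g$n_angles <- g$n_crystal_positions %/% 2L
  if (g$n_angles * 2L != g$n_crystal_positions)
    stop2("inconsistent counts: n_angles x 2 != n_crystal_positions")
  if (g$max_ring_diff > g$n_rings - 1L)
    stop2("max_ring_diff (%d) exceeds n_rings - 1 (%d)", g$max_ring_diff, g$n_rings - 1L)
  if (g$n_radial_bins > g$n_crystal_positions)
    stop2("n_radial_bins cannot exceed n_crystal_positions")
  if (!identical(g$span, "ssr")) {
    g$span <- as.integer(g$span)
    if (g$span %% 2L == 0L) stop2("span must be odd (or \"ssr\"); got %d", g$span)
  }
  class(g) <- "pet_geometry"
  g
}

geometry_preset <- function(name) {
  if (identical(name, "mmr")) {
    return(list(n_rings = 64L, ring_pitch = 4.0625, ring_diameter = 656,
                n_blocks_tx = 56L, crystals_per_block = 8L, gaps_per_block = 1L,
                n_radial_bins = 344L, max_ring_diff = 60L, span = 11L,
                buckets_axial = 8L, buckets_tx = 28L, tau = 5.85e-9))
  }
  m <- regmatches(name, regexec("^mmr-reduced:([0-9]+)$", name))[[1]]
  if (length(m) == 2L) {
    n <- as.integer(m[2])
    if (n < 1L || n > 64L) stop2("reduced ring count must be in 1..64")
    p <- geometry_preset("mmr")
    p$n_rings <- n
    p$max_ring_diff <- min(60L, n - 1L)
    p$buckets_axial <- as.integer(ceiling(n / 8))
    return(p)
  }
  stop2("unknown geometry preset '%s'", name)
}

#' @export
print.pet_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "pet_geometry: %d rings (pitch %.4g mm), ring diameter %.4g mm\n",
    "  %d tx blocks x (%d crystals + %d gaps) = %d positions, %d angles, %d radial bins\n",
    "  max ring difference %d, span %s, %d x %d dead-time buckets, tau %.3g s\n"),
    x$n_rings, x$ring_pitch, x$ring_diameter,
    x$n_blocks_tx, x$crystals_per_block, x$gaps_per_block,
    x$n_crystal_positions, x$n_angles, x$n_radial_bins,
    x$max_ring_diff, as.character(x$span), x$buckets_axial, x$buckets_tx, x$tau))
  invisible(x)
}

#' Geometry fingerprint
#'
#' Short hash of the fields that determine index algebra; stamped into every
#' data container so mismatched files are rejected on read.
#' @param geom A `pet_geometry`.
#' @return 8-character hex string.
#' @export
geometry_hash <- function(geom) {
  key <- paste(geom$n_rings, signif(geom$ring_pitch, 10), signif(geom$ring_diameter, 10),
               geom$n_blocks_tx, geom$crystals_per_block, geom$gaps_per_block,
               geom$gap_offset, geom$n_radial_bins, geom$max_ring_diff,
               sep = "|")
  fnv1a32(key)
}

# --- crystal layout ---------------------------------------------------------

# Logical vector over 0-based crystal positions: TRUE if live.
live_positions <- function(geom) {
  per_block <- geom$crystals_per_block + geom$gaps_per_block
  inblk <- (0:(geom$n_crystal_positions - 1L)) %% per_block
  if (geom$gaps_per_block == 0L) return(rep(TRUE, geom$n_crystal_positions))
  dead_idx <- (geom$gap_offset + 0:(geom$gaps_per_block - 1L)) %% per_block
  !(inblk %in% dead_idx)
}

# Face-centre coordinates of transaxial positions (mm), 0-based position k
# at angle 2*pi*(k + 0.5)/N on the detector circle.
crystal_xy <- function(geom) {
  N <- geom$n_crystal_positions
  a <- 2 * pi * ((0:(N - 1)) + 0.5) / N
  R <- geom$ring_diameter / 2
  cbind(x = R * cos(a), y = R * sin(a))
}

# Axial centres of rings (mm), centred on the iso-centre.
ring_z <- function(geom) {
  (0:(geom$n_rings - 1) - (geom$n_rings - 1) / 2) * geom$ring_pitch
}

# Dead-time bucket id (0-based) for a crystal at (tx position, ring), both 0-based.
bucket_of <- function(geom, tx, ring) {
  per_block <- geom$crystals_per_block + geom$gaps_per_block
  block <- tx %/% per_block
  blocks_per_bucket <- max(1L, as.integer(ceiling(geom$n_blocks_tx / geom$buckets_tx)))
  rings_per_bucket <- max(1L, as.integer(ceiling(geom$n_rings / geom$buckets_axial)))
  btx <- block %/% blocks_per_bucket
  bax <- ring %/% rings_per_bucket
  bax * geom$buckets_tx + btx
}

n_buckets <- function(geom) geom$buckets_axial * geom$buckets_tx

# --- span / segment algebra -------------------------------------------------

# Ordered signed segment ids: 0, +1, -1, +2, -2, ...
segment_order <- function(n_seg_side) {
  if (n_seg_side == 0L) return(0L)
  c(0L, as.vector(rbind(seq_len(n_seg_side), -seq_len(n_seg_side))))
}

# Ring-difference band [d_min, d_max] (absolute values) of segment |k| for span S.
span_band <- function(span, k, max_ring_diff) {
  h <- (span - 1L) %/% 2L
  if (k == 0L) return(c(0L, min(h, max_ring_diff)))
  d_min <- h + 1L + (k - 1L) * span
  d_max <- min(h + k * span, max_ring_diff)
  c(d_min, d_max)
}

n_segments_side <- function(span, max_ring_diff) {
  h <- (span - 1L) %/% 2L
  if (max_ring_diff <= h) return(0L)
  as.integer(ceiling((max_ring_diff - h) / span))
}

#' Count sinogram planes for a span
#'
#' Number of stored axial planes for the given axial compression: span-1
#' counts every allowed ring pair, span-S sums per-segment plane counts
#' `2*n_rings - 1 - 2*d_min`, and `"ssr"` (single-slice rebinning) gives
#' `2*n_rings - 1`.
#'
#' @param geom A `pet_geometry`.
#' @param span Odd integer span or `"ssr"`; defaults to the geometry's span.
#' @return Integer plane count.
#' @export
count_sinograms <- function(geom, span = geom$span) {
  if (identical(span, "ssr")) return(2L * geom$n_rings - 1L)
  span <- as.integer(span)
  if (span %% 2L == 0L) stop2("span must be odd; got %d", span)
  if (span == 1L) {
    n <- geom$n_rings
    d <- geom$max_ring_diff
    # pairs (r0, r1) with |r1 - r0| <= d
    return(as.integer(n + 2L * sum(pmax(0L, n - seq_len(d)))))
  }
  sum(segment_table(geom, span)$n_planes)
}

#' Segment table
#'
#' Ordered table of signed segments (0, +1, -1, +2, -2, ...) for a span, with
#' their absolute ring-difference band and stored plane counts. Per-segment
#' plane counts sum to [count_sinograms()].
#'
#' @inheritParams count_sinograms
#' @return `data.frame` with columns `segment`, `d_min`, `d_max`, `n_planes`.
#' @export
segment_table <- function(geom, span = geom$span) {
  if (identical(span, "ssr"))
    return(data.frame(segment = 0L, d_min = 0L, d_max = geom$max_ring_diff,
                      n_planes = 2L * geom$n_rings - 1L))
  span <- as.integer(span)
  if (span %% 2L == 0L) stop2("span must be odd; got %d", span)
  n <- geom$n_rings
  if (span == 1L) {
    segs <- segment_order(geom$max_ring_diff)
    return(data.frame(segment = segs, d_min = abs(segs), d_max = abs(segs),
                      n_planes = n - abs(segs)))
  }
  ks <- segment_order(n_segments_side(span, geom$max_ring_diff))
  rows <- lapply(ks, function(k) {
    band <- span_band(span, abs(k), geom$max_ring_diff)
    data.frame(segment = k, d_min = band[1], d_max = band[2],
               n_planes = 2L * n - 1L - 2L * band[1])
  })
  do.call(rbind, rows)
}

#' Single-slice-rebinned plane id
#'
#' @param geom A `pet_geometry`.
#' @param r0,r1 0-based ring indices (vectorised).
#' @return 0-based SSR plane id `r0 + r1`, in `0 .. 2*n_rings-2`.
#' @export
ssr_plane <- function(geom, r0, r1) {
  if (any(r0 < 0 | r0 >= geom$n_rings | r1 < 0 | r1 >= geom$n_rings))
    stop2("ring index out of range 0..%d", geom$n_rings - 1L)
  if (any(abs(r1 - r0) > geom$max_ring_diff))
    stop2("ring difference exceeds max_ring_diff (%d)", geom$max_ring_diff)
  as.integer(r0 + r1)
}

#' Michelogram plane map (span-1)
#'
#' Enumerates all span-1 planes in the package's canonical order:
#' segment-major (0, +1, -1, +2, -2, ...; segment = signed ring difference
#' `r1 - r0`), within a segment ordered by `r0 + r1`. The ordering is fixed so
#' sinogram files are bit-reproducible.
#'
#' @param geom A `pet_geometry`.
#' @return List with `n_planes`, integer vectors `r0`, `r1` (0-based ring pair
#'   of each plane), `segment` (signed per plane), and matrix `plane_of`
#'   (`n_rings x n_rings`, 0-based plane id or `NA` outside the ring
#'   difference limit).
#' @export
michelogram_map <- function(geom) {
  n <- geom$n_rings
  segs <- segment_order(geom$max_ring_diff)
  r0 <- integer(0); r1 <- integer(0); segment <- integer(0)
  for (s in segs) {
    a <- max(0L, -s); b <- (n - 1L) - max(0L, s)
    rr0 <- a:b
    r0 <- c(r0, rr0); r1 <- c(r1, rr0 + s)
    segment <- c(segment, rep.int(s, length(rr0)))
  }
  plane_of <- matrix(NA_integer_, n, n)
  plane_of[cbind(r0 + 1L, r1 + 1L)] <- seq_along(r0) - 1L
  list(n_planes = length(r0), r0 = r0, r1 = r1, segment = segment,
       plane_of = plane_of)
}

#' Span grouping of span-1 planes
#'
#' Maps every span-1 plane to its span-S (or SSR) group. For span-S, a group
#' is a (segment, axial position) cell: segment 0 covers ring differences
#' `|RD| <= (S-1)/2` and segment +-k the next S-wide bands; within a segment,
#' planes sharing `r0 + r1` are summed into one stored plane. Group sizes are
#' the `N_uv` multiplicities used in span-1 axial factor decoding.
#'
#' @param geom A `pet_geometry`.
#' @param span Odd integer span (> 1) or `"ssr"`.
#' @return List with `n_planes_out`, integer vector `group_of_plane1` (0-based
#'   output plane per span-1 plane, canonical segment-major order), and
#'   `group_size` (`N_uv` per output plane).
#' @export
span_group_map <- function(geom, span = geom$span) {
  mi <- michelogram_map(geom)
  if (identical(span, "ssr")) {
    gid <- mi$r0 + mi$r1
    nout <- 2L * geom$n_rings - 1L
  } else {
    span <- as.integer(span)
    if (span %% 2L == 0L) stop2("span must be odd; got %d", span)
    if (span == 1L) {
      return(list(n_planes_out = mi$n_planes,
                  group_of_plane1 = seq_len(mi$n_planes) - 1L,
                  group_size = rep.int(1L, mi$n_planes)))
    }
    st <- segment_table(geom, span)
    n <- geom$n_rings
    # output plane ids in the same segment-major, z-ordered convention
    seg_start <- cumsum(c(0L, head(st$n_planes, -1L)))
    names(seg_start) <- as.character(st$segment)
    rd <- mi$r1 - mi$r0
    h <- (span - 1L) %/% 2L
    seg_out <- ifelse(abs(rd) <= h, 0L,
                      sign(rd) * as.integer(ceiling((abs(rd) - h) / span)))
    z <- mi$r0 + mi$r1
    d_min <- st$d_min[match(seg_out, st$segment)]
    gid <- seg_start[as.character(seg_out)] + (z - d_min)
    nout <- sum(st$n_planes)
  }
  gid <- as.integer(gid)
  list(n_planes_out = as.integer(nout),
       group_of_plane1 = gid,
       group_size = as.integer(tabulate(gid + 1L, nbins = nout)))
}

# --- transaxial sinogram bin map -------------------------------------------

#' Transaxial sinogram bin map
#'
#' Standard interleaved binning of transaxial crystal pairs into
#' (angle, radial) sinogram bins: each bin corresponds to exactly one
#' unordered crystal-position pair; consecutive radial bins of an angle come
#' alternately from the two native half-angle classes. A bin is *active* when
#' both of its crystal positions are live.
#'
#' @param geom A `pet_geometry`.
#' @return List with per-bin 0-based vectors `k1`, `k2` (crystal positions;
#'   bin id = `angle * n_radial_bins + radial`), logical `active`, logical
#'   `live` per crystal position, matrix `pair2bin`
#'   (`n_pos x n_pos`, 0-based bin id or `NA` if outside the radial
#'   acceptance), and logical matrix `aligned` (TRUE at `[a+1, b+1]` when
#'   crystal `a` plays the k1 role of the bin construction).
#' @export
build_sino_bin_map <- function(geom) {
  N <- geom$n_crystal_positions
  n_ang <- geom$n_angles
  n_rad <- geom$n_radial_bins
  ang <- rep(0:(n_ang - 1L), each = n_rad)
  r <- rep(0:(n_rad - 1L), times = n_ang)
  u <- r - n_rad %/% 2L
  # class parity is opposite to radial-offset parity (interleave)
  p <- ifelse(((u %% 2L) + 2L) %% 2L == 0L, 1L, 0L)
  cc <- 2L * ang + p
  delta <- N %/% 2L - u
  k1 <- ((cc - 1L - delta) %/% 2L) %% N
  k2 <- (k1 + delta) %% N
  bin <- ang * n_rad + r              # 0-based bin id, radial fastest
  ord <- order(bin)
  k1 <- as.integer(k1[ord]); k2 <- as.integer(k2[ord])

  live <- live_positions(geom)
  active <- live[k1 + 1L] & live[k2 + 1L]

  pair2bin <- matrix(NA_integer_, N, N)
  aligned <- matrix(FALSE, N, N)
  ids <- 0:(length(k1) - 1L)
  pair2bin[cbind(k1 + 1L, k2 + 1L)] <- ids
  pair2bin[cbind(k2 + 1L, k1 + 1L)] <- ids
  aligned[cbind(k1 + 1L, k2 + 1L)] <- TRUE
  # self-pairs are impossible; keep diagonal NA
  diag(pair2bin) <- NA_integer_

  list(k1 = k1, k2 = k2, active = active, live = live,
       pair2bin = pair2bin, aligned = aligned,
       n_active = sum(active))
}
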