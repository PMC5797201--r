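# Fully 3-D voxel-driven single-scatter model (VSM): every emission voxel is
# treated independently; for each sampled detector A receiving the
# unscattered photon, scattering patches along the opposite ray are scored
# towards each sampled detector B with the Klein-Nishina cross-section.

R_E_CM <- 2.8179403e-13  # classical electron radius, cm

#' Klein-Nishina differential cross-section at 511 keV
#'
#' For incident photon energy 511 keV (alpha = 1) and unpolarised radiation:
#' the scattered/incident energy ratio is `P = 1/(2 - cos theta)` and
#' `d sigma_e / d Omega = (r_e^2 / 2) P^2 (P + 1/P - sin^2 theta)` (cm^2/sr).
#'
#' @param cos_theta Scattering-angle cosine(s) in `[-1, 1]`.
#' @return List with `dsdo` (cm^2/sr) and `energy_ratio`.
#' @export
kn_differential <- function(cos_theta) {
  if (any(cos_theta < -1 | cos_theta > 1)) stop2("cos_theta must be in [-1, 1]")
  P <- 1 / (2 - cos_theta)
  sin2 <- 1 - cos_theta^2
  list(dsdo = 0.5 * R_E_CM^2 * P^2 * (P + 1 / P - sin2), energy_ratio = P)
}

# Total Klein-Nishina electronic cross-section at alpha = E/m_e c^2.
kn_total_sigma <- function(alpha = 1) {
  a <- alpha
  2 * pi * R_E_CM^2 *
    ((1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
       log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2)
}

# Water linear attenuation (cm^-1) vs photon energy (keV); used for the
# energy scaling c_B = mu(E') / mu(511 keV) of the scattered photon.
WATER_MU <- data.frame(
  kev = c(100, 150, 200, 300, 400, 500, 511, 600),
  mu = c(0.1707, 0.1505, 0.1370, 0.1186, 0.1061, 0.0969, 0.0959, 0.0896))

water_cb_table <- function() {
  er <- WATER_MU$kev / 511
  cb <- WATER_MU$mu / WATER_MU$mu[WATER_MU$kev == 511]
  o <- order(er)
  list(eratio = er[o], cb = cb[o])
}

#' Scatter model configuration
#'
#' @param emission_downsample,mumap_downsample Integer image down-scaling
#'   factors (defaults 3 and 2, the routine brain-imaging settings).
#' @param axial_sampling Ring stride for sampled detectors (default 8, i.e.
#'   1:8 axial sampling).
#' @param tx_sampling Stride over *live* crystal positions (default 7).
#' @param emission_threshold Fraction of the emission maximum below which
#'   voxels are skipped (default 0.01).
#' @param patch_threshold mu (cm^-1) above which voxels act as scattering
#'   patches (default 0.02).
#' @param af_mask_threshold Attenuation-factor threshold defining the
#'   scatter-and-randoms-only region used for scaling (default 0.95).
#' @param node_angle_stride,node_radial_stride Node strides of the regular
#'   interpolation grid the sampled bins are collected on (default 2).
#' @return A `scatter_config` list.
#' @export
scatter_config <- function(emission_downsample = 3L, mumap_downsample = 2L,
                           axial_sampling = 8L, tx_sampling = 7L,
                           emission_threshold = 0.01, patch_threshold = 0.02,
                           af_mask_threshold = 0.95,
                           node_angle_stride = 2L, node_radial_stride = 2L) {
  if (emission_threshold < 0 || emission_threshold >= 1)
    stop2("emission_threshold must be in [0, 1)")
  structure(list(emission_downsample = as.integer(emission_downsample),
                 mumap_downsample = as.integer(mumap_downsample),
                 axial_sampling = as.integer(axial_sampling),
                 tx_sampling = as.integer(tx_sampling),
                 emission_threshold = emission_threshold,
                 patch_threshold = patch_threshold,
                 af_mask_threshold = af_mask_threshold,
                 node_angle_stride = as.integer(node_angle_stride),
                 node_radial_stride = as.integer(node_radial_stride)),
            class = "scatter_config")
}

# Sampled detector set: every axial_sampling-th ring and every
# tx_sampling-th live crystal position (always including the ends).
sampled_detectors <- function(geom, cfg, bm = build_sino_bin_map(geom)) {
  rings <- unique(as.integer(round(seq(0, geom$n_rings - 1,
                                       by = max(1L, cfg$axial_sampling)))))
  if (rings[length(rings)] != geom$n_rings - 1L) rings <- c(rings, geom$n_rings - 1L)
  live <- which(bm$live) - 1L
  tx <- live[seq(1L, length(live), by = max(1L, cfg$tx_sampling))]
  list(rings = rings, tx = tx)
}

#' Scatter ray look-up tables
#'
#' Pre-computes the mu line integrals (optical depths, cm^-1 mm) from every
#' above-threshold emission voxel to every sampled detector, and from every
#' patch-eligible mu voxel to every sampled detector, plus detector
#' coordinates. These are the only expensive ray tracings of the model; the
#' per-(voxel, detector) survival probabilities are `exp(-depth/10)`.
#'
#' @param emission_ds,mumap_ds Downsampled `pet_image`s.
#' @param geom A `pet_geometry`.
#' @param cfg A `scatter_config`.
#' @return A `scatter_lut`.
#' @export
build_scatter_lut <- function(emission_ds, mumap_ds, geom, cfg) {
  bm <- build_sino_bin_map(geom)
  det <- sampled_detectors(geom, cfg, bm)
  xy <- crystal_xy(geom)
  zr <- ring_z(geom)
  ndet_tx <- length(det$tx); ndet_ax <- length(det$rings)
  dtx <- rep(det$tx, times = ndet_ax)
  drg <- rep(det$rings, each = ndet_tx)
  pos <- cbind(xy[dtx + 1L, 1L], xy[dtx + 1L, 2L], zr[drg + 1L])

  emax <- max(emission_ds$values)
  esel <- which(emission_ds$values > cfg$emission_threshold * emax)
  em_pos <- voxel_centres(emission_ds, esel)
  musel <- which(mumap_ds$values >= cfg$patch_threshold)
  patch_row <- rep(-1L, prod(img_dim(mumap_ds)))
  patch_row[musel] <- seq_along(musel) - 1L
  patch_centres <- voxel_centres(mumap_ds, musel)

  muv <- as.numeric(mumap_ds$values)
  dims <- img_dim(mumap_ds); vox <- mumap_ds$voxel_size; corner <- grid_corner(mumap_ds)
  li <- function(P1) {
    n1 <- nrow(P1); nd <- nrow(pos)
    if (n1 == 0L) return(matrix(0, 0, nd))
    A <- P1[rep(seq_len(n1), times = nd), , drop = FALSE]
    B <- pos[rep(seq_len(nd), each = n1), , drop = FALSE]
    matrix(cpp_line_integrals(A, B, muv, dims, vox, corner), n1, nd)
  }
  structure(list(det_pos = pos, det_tx = dtx, det_ring = drg,
                 em_sel = esel, em_pos = em_pos,
                 patch_row = patch_row, patch_centres = patch_centres,
                 lutA = li(em_pos), lutB = li(patch_centres),
                 sampled = det, geom_hash = geometry_hash(geom)),
            class = "scatter_lut")
}

voxel_centres <- function(img, linear_idx) {
  dm <- img_dim(img)
  i <- (linear_idx - 1L) %% dm[1]
  j <- ((linear_idx - 1L) %/% dm[1]) %% dm[2]
  k <- (linear_idx - 1L) %/% (dm[1] * dm[2])
  cbind(img$origin[1] + i * img$voxel_size[1],
        img$origin[2] + j * img$voxel_size[2],
        img$origin[3] + k * img$voxel_size[3])
}

#' Voxel-driven single-scatter simulation
#'
#' For each emission voxel E above threshold and each sampled detector A:
#' the unscattered-side probability `P_i(SEA) = eps_A exp(-int mu)` along the
#' path through E up to each scattering patch S on the opposite ray; the
#' patch scatter probability `P_s(SEA) = P_i (1 - exp(-mu_S l_S))`; and for
#' each sampled detector B the detected-scatter probability
#' `P_s(BSEA) = P_s (Omega_B / sigma_e) (d sigma_e / d Omega) exp(-c_B int mu)`
#' with `c_B` the water attenuation scaling at the scattered photon energy.
#' Contributions are weighted by the voxel activity and binned on the (A, B)
#' LOR, giving a span-1 sinogram that is nonzero only on sampled
#' detector-pair bins.
#'
#' @param emission_ds,mumap_ds Downsampled `pet_image`s (same as the LUT).
#' @param lut A `scatter_lut`.
#' @param geom A `pet_geometry`.
#' @param cfg A `scatter_config`.
#' @return A span-1 `pet_sinogram` (sparse in the sampled-pair sense).
#' @export
vsm_single_scatter <- function(emission_ds, mumap_ds, lut, geom, cfg) {
  if (!inherits(lut, "scatter_lut") || !identical(lut$geom_hash, geometry_hash(geom)))
    stop2("scatter LUT does not match the geometry")
  bm <- build_sino_bin_map(geom)
  mi <- michelogram_map(geom)
  nb <- geom$n_radial_bins * geom$n_angles
  if (length(lut$em_sel) == 0L) {
    warning("no emission voxels above threshold; zero scatter")
    return(new_sinogram(geom, 1L))
  }
  tab <- water_cb_table()
  # crystal face area: tx pitch x axial pitch (mm^2)
  area <- (pi * geom$ring_diameter / geom$n_crystal_positions) * geom$ring_pitch
  v <- cpp_vsm(lut$em_pos, as.numeric(emission_ds$values[lut$em_sel]),
               as.numeric(mumap_ds$values), img_dim(mumap_ds),
               mumap_ds$voxel_size, grid_corner(mumap_ds),
               lut$patch_centres, lut$patch_row,
               lut$det_pos, lut$det_tx, lut$det_ring,
               lut$det_pos, lut$det_tx, lut$det_ring,
               lut$lutA, lut$lutB,
               area, geom$ring_diameter / 2,
               cfg$patch_threshold, R_E_CM^2, kn_total_sigma(1),
               tab$eratio, tab$cb,
               bm$pair2bin, bm$aligned, geom$n_crystal_positions,
               mi$plane_of, geom$n_rings,
               nb, mi$n_planes)
  out <- new_sinogram(geom, 1L, array(v, c(geom$n_radial_bins, geom$n_angles,
                                           mi$n_planes)))
  attr(out, "sampled") <- lut$sampled
  out
}

# --- interpolation to the full sinogram ------------------------------------

# Collect sampled-pair bin values onto a regular node grid
# [radial nodes x angle nodes x sampled rA x sampled rB].
scatter_nodes <- function(sparse, geom, cfg,
                          bm = build_sino_bin_map(geom),
                          mi = michelogram_map(geom)) {
  det <- attr(sparse, "sampled")
  if (is.null(det)) stop2("sparse sinogram lacks sampling information")
  n_rad <- geom$n_radial_bins; n_ang <- geom$n_angles
  rn <- unique(c(seq(0L, n_rad - 1L, by = cfg$node_radial_stride), n_rad - 1L))
  an <- unique(c(seq(0L, n_ang - 1L, by = cfg$node_angle_stride), n_ang - 1L))
  # sampled tx-pair bins
  tx <- det$tx
  grid <- expand.grid(a = tx, b = tx)
  grid <- grid[grid$a < grid$b, ]
  bins <- bm$pair2bin[cbind(grid$a + 1L, grid$b + 1L)]
  bins <- bins[!is.na(bins)]
  smask_tx <- logical(n_rad * n_ang); smask_tx[bins + 1L] <- TRUE
  # nearest node of every sampled bin
  r_of <- bins %% n_rad; a_of <- bins %/% n_rad
  nearest <- function(x, nodes) {
    idx <- findInterval(x, nodes, all.inside = TRUE)
    lo <- nodes[idx]; hi <- nodes[idx + 1L]
    ifelse(x - lo <= hi - x, idx, idx + 1L)
  }
  rnode <- nearest(r_of, rn); anode <- nearest(a_of, an)
  nsr <- length(det$rings)
  vals <- array(0, c(length(rn), length(an), nsr, nsr))
  wts <- array(0, c(length(rn), length(an), nsr, nsr))
  for (ia in seq_len(nsr)) for (ib in seq_len(nsr)) {
    p <- mi$plane_of[det$rings[ia] + 1L, det$rings[ib] + 1L]
    if (is.na(p)) next
    pl <- sparse[, , p + 1L]
    v <- pl[bins + 1L]
    acc <- rowsum(cbind(v, 1), group = (anode - 1L) * length(rn) + rnode)
    key <- as.integer(rownames(acc))
    ridx <- (key - 1L) %% length(rn) + 1L
    aidx <- (key - 1L) %/% length(rn) + 1L
    vals[cbind(ridx, aidx, ia, ib)] <- acc[, 1] / acc[, 2]
    wts[cbind(ridx, aidx, ia, ib)] <- acc[, 2]
  }
  structure(list(values = vals, radial_nodes = rn, angle_nodes = an,
                 rings = det$rings, geom_hash = geometry_hash(geom)),
            class = "scatter_nodes")
}

# 1-D linear interpolation weights of x onto node coordinates.
lin_weights <- function(x, nodes) {
  idx <- findInterval(x, nodes, all.inside = TRUE)
  w <- (x - nodes[idx]) / (nodes[idx + 1L] - nodes[idx])
  w <- pmin(pmax(w, 0), 1)
  list(lo = idx, hi = idx + 1L, w = w)
}

#' Interpolate sampled scatter to the full sinogram
#'
#' Separable cubic-spline interpolation across (radial, angle) on each
#' sampled ring-pair plane (the bicubic in-sinogram step), followed by
#' bilinear interpolation across the Michelogram (r0, r1) ring grid.
#' Node values are reproduced exactly; negative spline overshoot is
#' clipped to zero.
#'
#' @param nodes A `scatter_nodes` object (internally produced from the VSM
#'   output; see [estimate_scatter()]).
#' @param geom A `pet_geometry`.
#' @return A full span-1 `pet_sinogram`.
#' @export
interpolate_scatter <- function(nodes, geom) {
  if (!inherits(nodes, "scatter_nodes") ||
      !identical(nodes$geom_hash, geometry_hash(geom)))
    stop2("nodes do not match the geometry")
  rn <- nodes$radial_nodes; an <- nodes$angle_nodes
  if (length(rn) < 4L || length(an) < 4L)
    stop2("sampling too sparse for bicubic interpolation (< 4 nodes per axis)")
  n_rad <- geom$n_radial_bins; n_ang <- geom$n_angles
  nsr <- length(nodes$rings)
  mi <- michelogram_map(geom)
  # in-plane separable spline for every sampled ring pair
  full_tx <- array(0, c(n_rad, n_ang, nsr, nsr))
  for (ia in seq_len(nsr)) for (ib in seq_len(nsr)) {
    if (is.na(mi$plane_of[nodes$rings[ia] + 1L, nodes$rings[ib] + 1L])) next
    m <- nodes$values[, , ia, ib]
    tmp <- matrix(0, n_rad, length(an))
    for (j in seq_along(an))
      tmp[, j] <- stats::spline(rn, m[, j], xout = 0:(n_rad - 1L),
                                method = "natural")$y
    out <- matrix(0, n_rad, n_ang)
    for (i in seq_len(n_rad))
      out[i, ] <- stats::spline(an, tmp[i, ], xout = 0:(n_ang - 1L),
                                method = "natural")$y
    full_tx[, , ia, ib] <- out
  }
  # Michelogram bilinear across the sampled ring grid
  w0 <- lin_weights(mi$r0, nodes$rings)
  w1 <- lin_weights(mi$r1, nodes$rings)
  out <- array(0, c(n_rad, n_ang, mi$n_planes))
  for (p in seq_len(mi$n_planes)) {
    a <- w0$lo[p]; b <- w0$hi[p]; wa <- w0$w[p]
    c_ <- w1$lo[p]; d_ <- w1$hi[p]; wc <- w1$w[p]
    pl <- (1 - wa) * (1 - wc) * full_tx[, , a, c_] +
          wa * (1 - wc) * full_tx[, , b, c_] +
          (1 - wa) * wc * full_tx[, , a, d_] +
          wa * wc * full_tx[, , b, d_]
    out[, , p] <- pl
  }
  out[out < 0] <- 0
  new_sinogram(geom, 1L, out)
}

#' Scale the scatter estimate to the prompt data
#'
#' Weighted-least-squares scaling in the scatter-and-randoms-only region
#' (bins with attenuation factor above the mask threshold, i.e. rays missing
#' the object): one multiplicative factor per single-slice-rebinned axial
#' group minimising `sum w (prompts - randoms - k * scatter)^2` with
#' `w = 1/max(prompts, 1)`, applied to all planes of the group. If
#' scatter-specific axial factors are supplied they are applied afterwards.
#'
#' @param scatter,prompts,randoms,af,norm Span-1 `pet_sinogram`s on the same
#'   geometry (`norm` defines the active bins; pass factors from
#'   [build_norm_sinogram()] or `NULL` to use all bins).
#' @param geom A `pet_geometry`.
#' @param af_threshold Mask threshold on the attenuation factors.
#' @param axial_factors Optional per-plane scatter normalisation factors.
#' @return The scaled scatter `pet_sinogram`; attribute `"k"` carries the
#'   per-SSR-group factors.
#' @export
scale_scatter <- function(scatter, prompts, randoms, af, norm = NULL, geom,
                          af_threshold = 0.95, axial_factors = NULL) {
  for (s in list(scatter, prompts, randoms, af)) check_sino(s, geom, span = 1L)
  mi <- michelogram_map(geom)
  z <- mi$r0 + mi$r1
  nb <- geom$n_radial_bins * geom$n_angles
  active <- if (is.null(norm)) rep(TRUE, nb) else {
    # a bin is active if its factor is positive on any plane
    rowSums(matrix(norm > 0, nb)) > 0
  }
  kvec <- rep(NA_real_, 2L * geom$n_rings - 1L)
  out <- unclass(scatter)
  any_mask <- FALSE
  for (zz in sort(unique(z))) {
    pls <- which(z == zz)
    p <- as.numeric(prompts[, , pls]); r <- as.numeric(randoms[, , pls])
    s <- as.numeric(scatter[, , pls]); a <- as.numeric(af[, , pls])
    act <- rep(active, times = length(pls))
    mask <- a > af_threshold & act
    if (!any(mask)) next
    any_mask <- TRUE
    w <- 1 / pmax(p[mask], 1)
    sw <- sum(w * s[mask]^2)
    if (sw <= 0) stop2("scatter is identically zero on the scaling mask (SSR group %d)", zz)
    k <- sum(w * s[mask] * (p[mask] - r[mask])) / sw
    kvec[zz + 1L] <- k
    out[, , pls] <- out[, , pls] * k
  }
  if (!any_mask)
    stop2("empty scaling mask: no bins with AF > %.2f; lower af_threshold", af_threshold)
  # groups without their own mask reuse the global WLS factor
  if (any(is.na(kvec))) {
    kg <- mean(kvec, na.rm = TRUE)
    for (zz in which(is.na(kvec)) - 1L) {
      pls <- which(z == zz)
      if (length(pls)) out[, , pls] <- out[, , pls] * kg
    }
  }
  if (!is.null(axial_factors)) {
    if (length(axial_factors) != mi$n_planes)
      stop2("scatter axial factors must have one value per span-1 plane")
    for (p in seq_len(mi$n_planes)) out[, , p] <- out[, , p] * axial_factors[p]
  }
  res <- new_sinogram(geom, 1L, out)
  attr(res, "k") <- kvec
  res
}

#' One-call scatter estimation
#'
#' Downsamples the emission and mu-map images, builds the ray LUTs, runs the
#' voxel-driven single-scatter model on the sampled detectors, interpolates
#' to the full span-1 sinogram (skipped when sampling is complete) and
#' scales the result to the prompt data.
#'
#' @param emission,mumap `pet_image`s on the reconstruction grid.
#' @param geom A `pet_geometry`.
#' @param cfg A `scatter_config`.
#' @param prompts,randoms,af,norm Span-1 sinograms for the scaling step;
#'   pass `scale = FALSE` to return the unscaled shape.
#' @param scale Logical; perform WLS scaling (default TRUE).
#' @param axial_factors Optional scatter-specific axial factors.
#' @return A span-1 `pet_sinogram` of expected scatter.
#' @export
estimate_scatter <- function(emission, mumap, geom, cfg = scatter_config(),
                             prompts = NULL, randoms = NULL, af = NULL,
                             norm = NULL, scale = TRUE, axial_factors = NULL) {
  em <- downsample_image(emission, cfg$emission_downsample, preserve = "sum")
  mu <- downsample_image(mumap, cfg$mumap_downsample, preserve = "mean")
  lut <- build_scatter_lut(em, mu, geom, cfg)
  sparse <- vsm_single_scatter(em, mu, lut, geom, cfg)
  full_sampling <- cfg$axial_sampling <= 1L && cfg$tx_sampling <= 1L &&
    cfg$node_angle_stride <= 1L && cfg$node_radial_stride <= 1L
  est <- if (full_sampling) sparse
         else interpolate_scatter(scatter_nodes(sparse, geom, cfg), geom)
  if (!scale) return(est)
  scale_scatter(est, prompts, randoms, af, norm, geom,
                af_threshold = cfg$af_mask_threshold,
                axial_factors = axial_factors)
}
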