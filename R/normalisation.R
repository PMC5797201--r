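#' Normalisation component set
#'
#' Per-component multiplicative detection-efficiency factors: transaxial
#' geometric effects (per radial bin, replicated over angles), crystal
#' interference (per radial bin x in-block position), per-crystal
#' efficiencies, axial factors per plane (span-S and decoded span-1),
#' scatter-specific axial factors, and per-bucket dead-time parameters
#' (paralysable tau_p and non-paralysable tau_n, seconds). Efficiencies of
#' dead crystal positions are forced to zero.
#'
#' @param geometric Numeric, length `n_radial_bins`.
#' @param crystal_interference Matrix `n_radial_bins x positions_per_block`.
#' @param crystal_efficiencies Matrix `n_crystal_positions x n_rings`.
#' @param axial_factors_spanS Numeric per span-S plane (optional).
#' @param axial_factors_span1 Numeric per span-1 plane (optional).
#' @param scatter_axial_factors Numeric per plane (optional).
#' @param deadtime_tau_p,deadtime_tau_n Numeric per bucket (seconds).
#' @param geom A `pet_geometry`.
#' @return A `norm_components`.
#' @export
norm_components <- function(geometric, crystal_interference, crystal_efficiencies,
                            axial_factors_spanS = NULL, axial_factors_span1 = NULL,
                            scatter_axial_factors = NULL,
                            deadtime_tau_p = NULL, deadtime_tau_n = NULL,
                            geom) {
  per_block <- geom$crystals_per_block + geom$gaps_per_block
  if (length(geometric) != geom$n_radial_bins)
    stop2("geometric factors must have length n_radial_bins (%d)", geom$n_radial_bins)
  ci <- as.matrix(crystal_interference)
  if (!all(dim(ci) == c(geom$n_radial_bins, per_block)))
    stop2("crystal_interference must be %d x %d", geom$n_radial_bins, per_block)
  ce <- as.matrix(crystal_efficiencies)
  if (!all(dim(ce) == c(geom$n_crystal_positions, geom$n_rings)))
    stop2("crystal_efficiencies must be %d x %d", geom$n_crystal_positions, geom$n_rings)
  ce[!live_positions(geom), ] <- 0
  vals <- c(geometric, ci, ce, axial_factors_spanS, axial_factors_span1,
            scatter_axial_factors)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop2("normalisation factors must be finite and >= 0")
  nb <- n_buckets(geom)
  tp <- deadtime_tau_p %||% rep(0, nb)
  tn <- deadtime_tau_n %||% rep(0, nb)
  if (length(tp) != nb || length(tn) != nb)
    stop2("dead-time parameters must have one value per bucket (%d)", nb)
  structure(list(geometric = as.numeric(geometric), crystal_interference = ci,
                 crystal_efficiencies = ce,
                 axial_factors_spanS = axial_factors_spanS,
                 axial_factors_span1 = axial_factors_span1,
                 scatter_axial_factors = scatter_axial_factors,
                 deadtime_tau_p = as.numeric(tp), deadtime_tau_n = as.numeric(tn)),
            class = "norm_components")
}

#' Dead-time correction factor
#'
#' Combined paralysable/non-paralysable model driven by the measured singles
#' rate n: the live-time fractions are `exp(-n tau_p)` and `1/(1 + n tau_n)`,
#' so the multiplicative correction is `exp(n tau_p) * (1 + n tau_n)` (>= 1,
#' equal to 1 at rate 0, non-decreasing in n).
#'
#' @param rate Singles rate (counts/s), vectorised.
#' @param tau_p,tau_n Paralysable / non-paralysable time constants (s).
#' @return Multiplicative factor(s) >= 1.
#' @export
deadtime_factor <- function(rate, tau_p, tau_n) {
  if (any(rate < 0)) stop2("singles rate must be >= 0")
  exp(rate * tau_p) * (1 + rate * tau_n)
}

#' Decode span-1 axial factors from span-S factors
#'
#' Given the provided span-S axial factors and a high-statistics uniform
#' acquisition histogrammed in both span-1 and span-S, the span-1 factor of
#' plane (u, v) is `eps1 = N_uv * epsS * P1 / PS`, where `N_uv` is the
#' number of span-1 planes in the span-S group containing (u, v) and P are
#' plane-summed counts.
#'
#' @param eps_spanS Numeric span-S axial factors (canonical plane order).
#' @param prompts_span1 Span-1 `pet_sinogram` of the reference acquisition.
#' @param prompts_spanS Span-S `pet_sinogram` of the same acquisition.
#' @param geom A `pet_geometry`.
#' @param span Odd span S of the provided factors (default geometry span).
#' @return Numeric span-1 axial factors.
#' @export
decode_span1_axial <- function(eps_spanS, prompts_span1, prompts_spanS, geom,
                               span = geom$span) {
  check_sino(prompts_span1, geom, span = 1L)
  check_sino(prompts_spanS, geom, span = span)
  map <- span_group_map(geom, span)
  if (length(eps_spanS) != map$n_planes_out)
    stop2("expected %d span-%s axial factors", map$n_planes_out, span)
  P1 <- plane_totals(prompts_span1)
  if (any(P1 <= 0))
    stop2("zero-count span-1 plane(s): %s",
          paste(which(P1 <= 0) - 1L, collapse = ", "))
  PS <- plane_totals(prompts_spanS)
  g <- map$group_of_plane1 + 1L
  map$group_size[g] * eps_spanS[g] * P1 / PS[g]
}

# Frame-averaged bucket singles rates from a time x bucket matrix.
frame_bucket_rates <- function(bucket_singles, frame_s = NULL) {
  if (is.null(bucket_singles)) return(NULL)
  m <- as.matrix(bucket_singles)
  if (!is.null(frame_s)) {
    sec <- seq_len(nrow(m)) - 1L
    keep <- sec >= frame_s[1] & sec < frame_s[2]
    m <- m[keep, , drop = FALSE]
  }
  r <- colMeans(m, na.rm = TRUE)
  r[!is.finite(r)] <- 0
  r
}

#' Assemble the normalisation factor sinogram
#'
#' Per-bin factor = geometric(radial) x interference(radial, in-block
#' position of crystal A) x efficiency(crystal A) x efficiency(crystal B) x
#' axial(plane) x dead-time(bucket A) x dead-time(bucket B), with bucket
#' singles rates averaged over the frame. Bins touching dead positions get
#' factor 0. The factors are applied multiplicatively on the *model* side of
#' the reconstruction (see [osem()]).
#'
#' @param comp A `norm_components`.
#' @param bucket_singles Time x bucket singles matrix (counts/s), or `NULL`
#'   to disable dead-time correction.
#' @param frame `c(t0, t1)` seconds within the singles matrix, or `NULL`.
#' @param geom A `pet_geometry`.
#' @param span Output span (1 or the geometry's span-S; axial factors of
#'   that span must be present).
#' @return A `pet_sinogram` of multiplicative factors.
#' @export
build_norm_sinogram <- function(comp, bucket_singles = NULL, frame = NULL, geom,
                                span = 1L) {
  if (!inherits(comp, "norm_components")) stop2("comp must be norm_components")
  mi <- michelogram_map(geom)
  if (identical(span, 1L) || identical(span, 1)) {
    ax <- comp$axial_factors_span1
    n_pl <- mi$n_planes
    r0 <- mi$r0; r1 <- mi$r1
    if (is.null(ax)) stop2("missing component: axial_factors_span1")
    if (length(ax) != n_pl) stop2("axial_factors_span1 must have length %d", n_pl)
  } else {
    stop2("build_norm_sinogram emits span-1 factors; reduce data, not factors")
  }
  bm <- build_sino_bin_map(geom)
  per_block <- geom$crystals_per_block + geom$gaps_per_block
  cib <- bm$k1 %% per_block                    # in-block position of crystal A
  rad <- rep(0:(geom$n_radial_bins - 1L), times = geom$n_angles)
  tx_part <- comp$geometric[rad + 1L] *
    comp$crystal_interference[cbind(rad + 1L, cib + 1L)]

  dtr <- frame_bucket_rates(bucket_singles, frame)
  if (is.null(dtr)) dtf <- rep(1, n_buckets(geom))
  else dtf <- deadtime_factor(dtr, comp$deadtime_tau_p, comp$deadtime_tau_n)

  E <- comp$crystal_efficiencies
  nb <- geom$n_radial_bins * geom$n_angles
  out <- array(0, c(geom$n_radial_bins, geom$n_angles, n_pl))
  for (p in seq_len(n_pl)) {
    ra <- r0[p]; rb <- r1[p]
    f <- tx_part * E[bm$k1 + 1L, ra + 1L] * E[bm$k2 + 1L, rb + 1L] * ax[p] *
      dtf[bucket_of(geom, bm$k1, ra) + 1L] * dtf[bucket_of(geom, bm$k2, rb) + 1L]
    out[, , p] <- f
  }
  new_sinogram(geom, 1L, out, frame = frame)
}

#' Scatter-specific axial factors
#'
#' Ratios between the single-slice-rebinned (SSR) prediction and the
#' observed per-plane totals of a uniform reference acquisition: a plane's
#' predicted total is an equal share of its SSR plane total among the
#' sinogram planes feeding that SSR plane; the factor is predicted/observed.
#' Applying the factors to the reference data reproduces an SSR-consistent
#' axial profile exactly.
#'
#' @param ssr_ref `"ssr"`-span `pet_sinogram` of the reference acquisition.
#' @param span1_ref Span-1 `pet_sinogram` of the same acquisition.
#' @param geom A `pet_geometry`.
#' @return Numeric factor per span-1 plane (finite, > 0).
#' @export
scatter_axial_factors <- function(ssr_ref, span1_ref, geom) {
  check_sino(ssr_ref, geom, span = "ssr")
  check_sino(span1_ref, geom, span = 1L)
  map <- span_group_map(geom, "ssr")
  obs <- plane_totals(span1_ref)
  ssr_tot <- plane_totals(ssr_ref)
  if (any(obs <= 0) || any(ssr_tot <= 0)) stop2("zero plane totals in reference data")
  g <- map$group_of_plane1 + 1L
  pred <- ssr_tot[g] / map$group_size[g]
  pred / obs
}
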