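# Fixture generator: digital phantoms, synthetic normalisation components
# and a list-mode acquisition simulator with Poisson statistics, attenuation,
# detector efficiencies, randoms and scatter. Everything is seeded, so every
# module of the package is testable without scanner data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration
#'
#' @param duration_s Acquisition duration (s).
#' @param randoms_fraction,scatter_fraction Expected randoms / scatter
#'   totals as fractions of the expected trues total (in `[0, 1)`).
#' @param seed Mandatory integer seed.
#' @param scatter_cfg `scatter_config` used to generate the scatter shape.
#' @param deadtime Logical; apply the bucket dead-time live-time loss to the
#'   expected counts (default FALSE).
#' @return A `sim_config`.
#' @export
sim_config <- function(duration_s, randoms_fraction = 0, scatter_fraction = 0,
                       seed, scatter_cfg = NULL, deadtime = FALSE) {
  if (missing(seed)) stop2("a seed is mandatory")
  if (randoms_fraction < 0 || randoms_fraction >= 1 ||
      scatter_fraction < 0 || scatter_fraction >= 1)
    stop2("fractions must be in [0, 1)")
  structure(list(duration_s = duration_s, randoms_fraction = randoms_fraction,
                 scatter_fraction = scatter_fraction, seed = as.integer(seed),
                 scatter_cfg = scatter_cfg, deadtime = deadtime),
            class = "sim_config")
}

# sub-voxel in-plane area fraction of a disc on the voxel grid
disc_fraction <- function(xc, yc, cx, cy, radius, vox, sub = 3L) {
  off <- (seq_len(sub) - (sub + 1) / 2) / sub
  frac <- 0
  for (ox in off) for (oy in off) {
    inside <- outer((xc + ox * vox[1] - cx)^2, (yc + oy * vox[2] - cy)^2, `+`) <= radius^2
    frac <- frac + inside
  }
  frac / sub^2
}

#' Digital phantoms
#'
#' `"uniform_cylinder"`: an axially full-length cylinder of given diameter
#' and activity with water attenuation inside (the long uniform-phantom
#' acquisition emulated at desk scale); edge voxels carry anti-aliased area
#' fractions so the voxelised volume matches the analytic one. `"brain_like"`:
#' a background cylinder (ratio 1) with two embedded discs whose activities
#' encode the requested regional ratios exactly; the parcellation labels the
#' regions 1..3 (0 = background air).
#'
#' @param geom A `pet_geometry`.
#' @param type `"uniform_cylinder"` or `"brain_like"`.
#' @param diameter_mm Cylinder diameter (default 200, the 20 cm phantom).
#' @param activity Activity value per voxel in the base region.
#' @param mu_water Water attenuation at 511 keV (default 0.096 cm^-1).
#' @param region_ratios Activity ratios of the three brain-like regions
#'   (default `c(1, 1.4, 0.8)`).
#' @param dims,voxel_size Image grid (defaults: in-plane grid covering 1.3 x
#'   the diameter with 32 voxels, axial `2*n_rings - 1` voxels of half the
#'   ring pitch).
#' @return List with `emission`, `mumap`, `parcellation` (`pet_image`s).
#' @export
make_phantom <- function(geom, type = c("uniform_cylinder", "brain_like"),
                         diameter_mm = 200, activity = 1, mu_water = 0.096,
                         region_ratios = c(1, 1.4, 0.8),
                         dims = NULL, voxel_size = NULL) {
  type <- match.arg(type)
  if (is.null(dims)) dims <- c(32L, 32L, 2L * geom$n_rings - 1L)
  if (is.null(voxel_size))
    voxel_size <- c(rep(1.3 * diameter_mm / dims[1], 2), geom$ring_pitch / 2)
  if (diameter_mm / 2 > min(dims[1] * voxel_size[1], dims[2] * voxel_size[2]) / 2)
    stop2("phantom exceeds the image FOV")
  if (diameter_mm >= geom$ring_diameter) stop2("phantom exceeds the detector ring")
  proto <- new_image(array(0, dims), voxel_size)
  xc <- axis_centres(proto, 1); yc <- axis_centres(proto, 2)
  r <- diameter_mm / 2
  frac <- disc_fraction(xc, yc, 0, 0, r, voxel_size)
  em <- array(rep(frac, dims[3]), dims)
  if (type == "uniform_cylinder") {
    emission <- em * activity
    mumap <- em * mu_water
    par <- array(rep((frac > 0.5) * 1L, dims[3]), dims)
  } else {
    inner <- r * 0.45
    hard1 <- outer((xc + r * 0.35)^2, yc^2, `+`) <= inner^2
    hard2 <- outer((xc - r * 0.35)^2, yc^2, `+`) <= inner^2
    base <- frac > 0.5
    lab2d <- ifelse(hard1, 2L, ifelse(hard2, 3L, ifelse(base, 1L, 0L)))
    act2d <- c(0, activity * region_ratios)[lab2d + 1L]
    emission <- array(rep(act2d, dims[3]), dims)
    mumap <- em * mu_water
    par <- array(rep(lab2d, dims[3]), dims)
  }
  list(emission = new_image(emission, voxel_size),
       mumap = new_image(mumap, voxel_size),
       parcellation = new_image(par, voxel_size))
}

#' Synthetic normalisation components
#'
#' Self-consistent component set: a smooth radial geometric profile, a
#' periodic in-block interference pattern, log-normal crystal efficiencies
#' with the requested coefficient of variation, mild per-plane axial
#' factors, unit scatter axial factors, and optional bucket dead-time
#' constants.
#'
#' @param geom A `pet_geometry`.
#' @param efficiency_cv CV of the crystal efficiencies (default 0.05).
#' @param axial_cv Amplitude of the axial per-plane variation (default 0.03).
#' @param seed Integer seed.
#' @param tau_p,tau_n Per-bucket dead-time constants (s; scalars recycled).
#' @return A `norm_components`.
#' @export
synthetic_norm_components <- function(geom, efficiency_cv = 0.05,
                                      axial_cv = 0.03, seed = 1L,
                                      tau_p = 0, tau_n = 0) {
  with_seed(seed, {
    n_rad <- geom$n_radial_bins
    per_block <- geom$crystals_per_block + geom$gaps_per_block
    geometric <- 1 + 0.15 * cos(pi * (seq_len(n_rad) - (n_rad + 1) / 2) / n_rad)
    interf <- outer(rep(1, n_rad), 1 + 0.05 * sin(2 * pi * seq_len(per_block) / per_block))
    eff <- matrix(exp(rnorm(geom$n_crystal_positions * geom$n_rings,
                            -efficiency_cv^2 / 2, efficiency_cv)),
                  geom$n_crystal_positions, geom$n_rings)
    mi <- michelogram_map(geom)
    ax1 <- 1 + axial_cv * sin(2 * pi * seq_len(mi$n_planes) / 16)
    nb <- n_buckets(geom)
    norm_components(geometric, interf, eff,
                    axial_factors_span1 = ax1,
                    scatter_axial_factors = rep(1, mi$n_planes),
                    deadtime_tau_p = rep(tau_p, length.out = nb),
                    deadtime_tau_n = rep(tau_n, length.out = nb),
                    geom = geom)
  })
}

#' Simulate a list-mode acquisition
#'
#' Expected trues are the attenuated, efficiency-weighted forward projection
#' of the emission image times the duration. Randoms come from a per-crystal
#' singles model (`R_ij = 2 tau S_i S_j`, singles proportional to crystal
#' efficiency and scaled to the requested randoms fraction of trues), so
#' maximum-likelihood singles recovery is testable; delayeds are an
#' independent Poisson realisation of the same expectation. Scatter adds a
#' voxel-driven single-scatter shape scaled to the requested fraction.
#' Per-bin Poisson draws are converted to timestamped events with uniform
#' arrival times; bucket singles records (every 2 s) are consistent with the
#' randoms rates.
#'
#' @param emission,mumap `pet_image`s on the same grid.
#' @param norm A `norm_components` (or `NULL` for uniform efficiency).
#' @param cfg A `sim_config`.
#' @param geom A `pet_geometry`.
#' @param lut Optional prebuilt `pet_tx_lut` for the emission grid.
#' @param t_offset_ms Offset added to event times (for piecewise dynamic or
#'   motion studies).
#' @return A `pet_listmode`; attribute `"truth"` carries the expected-count
#'   sinograms and the singles rates used.
#' @export
simulate_listmode <- function(emission, mumap, norm = NULL, cfg, geom,
                              lut = NULL, t_offset_ms = 0L) {
  if (!inherits(cfg, "sim_config")) stop2("cfg must be a sim_config")
  check_same_grid(emission, mumap, "emission and mu-map")
  if (is.null(lut)) lut <- build_transaxial_lut(geom, emission)
  if (is.null(norm)) {
    mi0 <- michelogram_map(geom)
    norm <- norm_components(rep(1, geom$n_radial_bins),
                            matrix(1, geom$n_radial_bins,
                                   geom$crystals_per_block + geom$gaps_per_block),
                            matrix(1, geom$n_crystal_positions, geom$n_rings),
                            axial_factors_span1 = rep(1, mi0$n_planes),
                            geom = geom)
  }
  dur <- cfg$duration_s
  af <- attenuation_factors(mumap, lut, geom)
  nf <- build_norm_sinogram(norm, NULL, NULL, geom, span = 1L)
  trues_exp <- unclass(forward_project(emission, lut, geom)) * unclass(af) *
    unclass(nf) * dur
  tot_trues <- sum(trues_exp)
  if (!is.finite(tot_trues)) stop2("expectation overflow in simulated trues")
  if (sum(nf) == 0) stop2("normalisation is zero everywhere")

  bm <- build_sino_bin_map(geom)
  mi <- michelogram_map(geom)

  # per-crystal singles proportional to efficiency, scaled to the randoms target
  E <- norm$crystal_efficiencies
  randoms_exp <- array(0, dim(trues_exp))
  S <- E * 0
  if (cfg$randoms_fraction > 0 && tot_trues > 0) {
    raw <- unclass(randoms_sinogram(
      structure(list(S = E, tau = geom$tau), class = "pet_singles"), geom, dur))
    s0 <- sqrt(cfg$randoms_fraction * tot_trues / sum(raw))
    S <- s0 * E
    randoms_exp <- raw * s0^2
  }

  scatter_exp <- array(0, dim(trues_exp))
  if (cfg$scatter_fraction > 0 && tot_trues > 0) {
    scfg <- cfg$scatter_cfg %||% scatter_config()
    shape <- unclass(estimate_scatter(emission, mumap, geom, scfg, scale = FALSE))
    # scatter is only detectable on live-crystal bins
    act <- array(rep(bm$active, dim(shape)[3]), dim(shape))
    shape[!act] <- 0
    if (sum(shape) > 0)
      scatter_exp <- shape * (cfg$scatter_fraction * tot_trues / sum(shape))
  }

  prompts_exp <- trues_exp + randoms_exp + scatter_exp
  if (cfg$deadtime && any(norm$deadtime_tau_p > 0 | norm$deadtime_tau_n > 0)) {
    bid_all <- bucket_of(geom, rep(0:(geom$n_crystal_positions - 1L), geom$n_rings),
                         rep(0:(geom$n_rings - 1L), each = geom$n_crystal_positions))
    brate <- as.numeric(rowsum(as.numeric(S), bid_all)[, 1])
    dtf <- deadtime_factor(brate, norm$deadtime_tau_p, norm$deadtime_tau_n)
    for (p in seq_len(dim(prompts_exp)[3])) {
      lt <- 1 / (dtf[bucket_of(geom, bm$k1, mi$r0[p]) + 1L] *
                   dtf[bucket_of(geom, bm$k2, mi$r1[p]) + 1L])
      prompts_exp[, , p] <- prompts_exp[, , p] * lt
      randoms_exp[, , p] <- randoms_exp[, , p] * lt
    }
  }

  draw_events <- function(exp_counts, delayed) {
    n <- stats::rpois(length(exp_counts), as.numeric(exp_counts))
    tot <- sum(n)
    if (tot == 0) return(NULL)
    nz <- which(n > 0)
    reps <- n[nz]
    nbins <- geom$n_radial_bins * geom$n_angles
    bin_tx <- (nz - 1L) %% nbins
    plane <- (nz - 1L) %/% nbins
    list(time_ms = as.integer(floor(stats::runif(tot, 0, dur * 1000))),
         txa = rep(bm$k1[bin_tx + 1L], reps),
         ringa = rep(mi$r0[plane + 1L], reps),
         txb = rep(bm$k2[bin_tx + 1L], reps),
         ringb = rep(mi$r1[plane + 1L], reps),
         delayed = rep(delayed, tot))
  }

  lm <- with_seed(cfg$seed, {
    pe <- draw_events(prompts_exp, FALSE)
    de <- draw_events(randoms_exp, TRUE)
    ev <- list(time_ms = c(pe$time_ms, de$time_ms),
               txa = c(pe$txa, de$txa), ringa = c(pe$ringa, de$ringa),
               txb = c(pe$txb, de$txb), ringb = c(pe$ringb, de$ringb),
               delayed = c(pe$delayed, de$delayed))
    o <- order(ev$time_ms, method = "radix")
    ev <- lapply(ev, function(v) v[o])
    ev$time_ms <- ev$time_ms + as.integer(t_offset_ms)
    # bucket singles: total rate per bucket, reported every other second
    bid <- bucket_of(geom, rep(0:(geom$n_crystal_positions - 1L), geom$n_rings),
                     rep(0:(geom$n_rings - 1L), each = geom$n_crystal_positions))
    brate <- as.numeric(rowsum(as.numeric(S), bid)[, 1])
    ts <- seq(0, max(0, dur - 1), by = 2) * 1000 + t_offset_ms
    singles <- data.frame(time_ms = rep(as.integer(ts), each = n_buckets(geom)),
                          bucket = rep(0:(n_buckets(geom) - 1L), length(ts)),
                          rate = rep(brate, length(ts)))
    new_listmode(ev, singles, dur * 1000 + t_offset_ms, geom)
  })
  attr(lm, "truth") <- list(trues = trues_exp, randoms = randoms_exp,
                            scatter = scatter_exp, singles = S,
                            af = af, norm_sino = nf)
  lm
}
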