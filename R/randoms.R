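# Reduced-variance random-event estimation: per-crystal singles rates are
# recovered from delayed fan sums by a maximum-likelihood fixed point, then
# expected randoms per LOR follow from R_ij ~= 2 tau S_i S_j.

# Transaxial fan membership: live pairs within the radial acceptance.
tx_fan_matrix <- function(geom, bm = build_sino_bin_map(geom)) {
  f <- !is.na(bm$pair2bin)
  f[!bm$live, ] <- FALSE
  f[, !bm$live] <- FALSE
  storage.mode(f) <- "double"
  f
}

# Ring-window sums over |r' - r| <= max_ring_diff for each column of S.
ring_window_sums <- function(S, max_ring_diff) {
  nr <- ncol(S)
  cs <- cbind(0, t(apply(S, 1L, cumsum)))
  lo <- pmax(seq_len(nr) - max_ring_diff, 1L)
  hi <- pmin(seq_len(nr) + max_ring_diff, nr)
  cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
}

#' Maximum-likelihood singles rates from delayed fan sums
#'
#' Iterates the damped fixed point
#' `S_i <- S_i/2 + (sum_j d_ij) / (2 * sum_j 2 tau S_j)` over all crystals,
#' where the sums run over each crystal's coincidence fan (transaxial
#' acceptance x rings within the maximum ring difference) and `d` are the
#' delayed fan sums expressed as rates (counts divided by the acquisition
#' time). At the fixed point the modelled fan sums `sum_j 2 tau S_i S_j`
#' reproduce the measured ones.
#'
#' @param fansums Matrix `n_crystal_positions x n_rings` of delayed fan-sum
#'   counts (as produced by [histogram_listmode()]).
#' @param geom A `pet_geometry`.
#' @param tau Coincidence window (s); default from the geometry.
#' @param acq_time Acquisition (frame) duration in seconds.
#' @param n_iter Maximum iterations (default 10).
#' @param tol Early-stop threshold on the fan-sum residual (default 1e-7).
#' @param init Optional initial rates; default `sqrt(d_i / (2 tau F_i))`
#'   with `F_i` the fan size.
#' @return List (class `pet_singles`) with `S` (matrix of rates, counts/s;
#'   0 at dead positions), `tau`, `iterations`, `fansum_residual`, `note`.
#' @export
estimate_singles <- function(fansums, geom, tau = geom$tau, acq_time,
                             n_iter = 10L, tol = 1e-7, init = NULL) {
  if (any(fansums < 0)) stop2("fan sums must be >= 0")
  if (tau <= 0) stop2("tau must be positive")
  if (acq_time <= 0) stop2("acq_time must be positive")
  bm <- build_sino_bin_map(geom)
  Ftx <- tx_fan_matrix(geom, bm)
  d <- fansums / acq_time
  live <- bm$live
  d[!live, ] <- 0
  if (all(d == 0)) {
    return(structure(list(S = d * 0, tau = tau, iterations = 0L,
                          fansum_residual = 0,
                          note = "all-zero fan sums; returning S = 0"),
                     class = "pet_singles"))
  }
  fan_tx_size <- as.numeric(Ftx %*% rep(1, nrow(Ftx)))
  win <- pmin(seq_len(geom$n_rings) + geom$max_ring_diff, geom$n_rings) -
         pmax(seq_len(geom$n_rings) - geom$max_ring_diff, 1L) + 1L
  Fsize <- outer(fan_tx_size, win)
  S <- init %||% sqrt(d / pmax(2 * tau * Fsize, .Machine$double.eps))
  S[!live, ] <- 0
  res <- Inf
  it <- 0L
  while (it < n_iter) {
    it <- it + 1L
    denom <- 2 * tau * (Ftx %*% ring_window_sums(S, geom$max_ring_diff))
    bad <- denom == 0 & d > 0
    if (any(bad)) stop2("zero fan denominator with nonzero fan sum at %d crystal(s)",
                        sum(bad))
    Snew <- 0.5 * S + 0.5 * ifelse(denom > 0, d / denom, 0)
    Snew[!live, ] <- 0
    S <- Snew
    model <- S * (2 * tau * (Ftx %*% ring_window_sums(S, geom$max_ring_diff)))
    nz <- d > 0
    res <- max(abs(model[nz] - d[nz]) / d[nz])
    if (res < tol) break
  }
  structure(list(S = S, tau = tau, iterations = it, fansum_residual = res,
                 note = NULL),
            class = "pet_singles")
}

#' @export
print.pet_singles <- function(x, ...) {
  cat(sprintf("pet_singles: %d x %d rates, %d iterations, fan-sum residual %.3g\n",
              nrow(x$S), ncol(x$S), x$iterations, x$fansum_residual))
  if (!is.null(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' Expected randoms sinogram from singles rates
#'
#' Per span-1 bin, expected random counts `2 tau S_i S_j * duration` for the
#' crystal pair of that bin and the plane's ring pair.
#'
#' @param singles A `pet_singles` from [estimate_singles()].
#' @param geom A `pet_geometry`.
#' @param frame_duration Frame duration (s).
#' @return A span-1 `pet_sinogram` of expected randoms counts.
#' @export
randoms_sinogram <- function(singles, geom, frame_duration) {
  S <- singles$S
  bm <- build_sino_bin_map(geom)
  mi <- michelogram_map(geom)
  nb <- geom$n_radial_bins * geom$n_angles
  out <- array(0, c(geom$n_radial_bins, geom$n_angles, mi$n_planes))
  base <- 2 * singles$tau * frame_duration
  for (p in seq_len(mi$n_planes)) {
    out[, , p] <- base * S[bm$k1 + 1L, mi$r0[p] + 1L] * S[bm$k2 + 1L, mi$r1[p] + 1L]
  }
  new_sinogram(geom, 1L, out)
}
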