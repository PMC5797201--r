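#' Balanced angle subsets
#'
#' Interleaved assignment of sinogram angles to ordered subsets: angle `a`
#' goes to subset `a mod N`, so each subset holds `n_angles / N` angles
#' spread uniformly over the half-turn.
#'
#' @param geom A `pet_geometry`.
#' @param n_subsets Number of subsets; must divide `n_angles`.
#' @return List of 0-based angle index vectors.
#' @export
partition_subsets <- function(geom, n_subsets) {
  n_subsets <- as.integer(n_subsets)
  if (n_subsets < 1L) stop2("n_subsets must be >= 1")
  if (geom$n_angles %% n_subsets != 0L) {
    div <- which(geom$n_angles %% seq_len(geom$n_angles) == 0L)
    stop2("n_angles (%d) not divisible by %d subsets; valid counts: %s",
          geom$n_angles, n_subsets, paste(div, collapse = ", "))
  }
  lapply(0:(n_subsets - 1L), function(s)
    seq(s, geom$n_angles - 1L, by = n_subsets))
}

#' Reconstruction configuration
#'
#' @param n_subsets Ordered subsets (default 14, balanced over the angles).
#' @param n_iterations Full OSEM iterations (default 4).
#' @param update_scatter_each_iteration Re-estimate scatter from the current
#'   image before every iteration (default TRUE when a scatter provider is
#'   given).
#' @param epsilon Non-negativity guard for divisions (default 1e-20).
#' @return A `recon_config`.
#' @export
recon_config <- function(n_subsets = 14L, n_iterations = 4L,
                         update_scatter_each_iteration = TRUE,
                         epsilon = 1e-20) {
  structure(list(n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations),
                 update_scatter_each_iteration = update_scatter_each_iteration,
                 epsilon = epsilon),
            class = "recon_config")
}

#' OSEM reconstruction
#'
#' Ordered-subsets expectation maximisation with the acquisition model
#' `E[m_i] = n_i af_i (A x)_i + r_i + s_i`: normalisation and attenuation
#' factors multiply the model, randoms and scatter enter as additive terms.
#' The subset update is
#' `x <- x / Abt_s(n af) * Abt_s[(n af) m / ((n af)(A_s x) + r + s)]`,
#' which keeps voxels with zero sensitivity at zero and the image
#' non-negative throughout. With one subset this is exactly MLEM.
#'
#' @param prompts Span-1 `pet_sinogram` of measured prompts.
#' @param norm Span-1 factor sinogram ([build_norm_sinogram()]), or `NULL`
#'   for unit factors on all bins.
#' @param af Span-1 attenuation factors ([attenuation_factors()]), or `NULL`.
#' @param randoms Span-1 expected randoms ([randoms_sinogram()]), or `NULL`.
#' @param scatter_provider `NULL`, a fixed span-1 `pet_sinogram`, or a
#'   `function(image)` returning one; a function is re-evaluated before each
#'   iteration when the configuration asks for it.
#' @param lut A `pet_tx_lut` defining the image grid.
#' @param geom A `pet_geometry`.
#' @param cfg A `recon_config`.
#' @param verbose Print per-iteration log-likelihood.
#' @return A `pet_image`; attribute `"loglik"` has the per-update Poisson
#'   log-likelihood trace.
#' @export
osem <- function(prompts, norm = NULL, af = NULL, randoms = NULL,
                 scatter_provider = NULL, lut, geom, cfg = recon_config(),
                 verbose = FALSE) {
  check_sino(prompts, geom, span = 1L)
  if (any(prompts < 0) || any(!is.finite(prompts))) stop2("prompts must be finite and >= 0")
  eps <- cfg$epsilon
  nb <- geom$n_radial_bins * geom$n_angles
  np <- dim(prompts)[3]
  fac <- array(1, dim(prompts))
  if (!is.null(norm)) { check_sino(norm, geom, 1L); fac <- fac * unclass(norm) }
  if (!is.null(af)) { check_sino(af, geom, 1L); fac <- fac * unclass(af) }
  if (any(!is.finite(fac))) stop2("non-finite normalisation/attenuation factors")
  add <- array(0, dim(prompts))
  if (!is.null(randoms)) { check_sino(randoms, geom, 1L); add <- add + unclass(randoms) }

  subsets <- partition_subsets(geom, cfg$n_subsets)
  m <- unclass(prompts)

  # subset sensitivities Abt_s(n af)
  sens <- lapply(subsets, function(ss) {
    s <- back_project(new_sinogram(geom, 1L, fac), lut, geom, subset = ss)
    s$values
  })
  dims <- lut$dims
  tot_blind <- Reduce(`+`, sens) <= 0
  if (all(tot_blind)) stop2("zero sensitivity everywhere; check norm/af factors")
  x <- array(1, dims)
  x[tot_blind] <- 0                # voxels unseen by the scanner stay 0
  x_img <- new_image(x, lut$voxel_size, origin = lut$corner + lut$voxel_size / 2)

  scatter_fun <- if (is.function(scatter_provider)) scatter_provider else NULL
  if (!is.null(scatter_provider) && !is.function(scatter_provider)) {
    check_sino(scatter_provider, geom, 1L)
    add <- add + unclass(scatter_provider)
  }

  loglik <- numeric(0)
  for (it in seq_len(cfg$n_iterations)) {
    if (!is.null(scatter_fun) &&
        (cfg$update_scatter_each_iteration || it == 1L)) {
      sc <- scatter_fun(x_img)
      check_sino(sc, geom, 1L)
      add_it <- add + unclass(sc)
    } else add_it <- add
    for (ss_i in seq_along(subsets)) {
      ss <- subsets[[ss_i]]
      bins <- subset_bins(geom, ss)
      proj <- forward_project(x_img, lut, geom, subset = ss)
      model <- fac * unclass(proj) + add_it
      ratio <- array(0, dim(model))
      sel <- slice_bins(bins, nb, np)
      ratio[sel] <- fac[sel] * m[sel] / pmax(model[sel], eps)
      bp <- back_project(new_sinogram(geom, 1L, ratio), lut, geom, subset = ss)
      s <- sens[[ss_i]]
      upd <- x_img$values * bp$values / pmax(s, eps)
      upd[s <= 0] <- x_img$values[s <= 0]  # unchanged where this subset is blind
      upd[tot_blind] <- 0
      x_img$values <- upd
      ll <- sum(m[sel] * log(pmax(model[sel], eps)) - model[sel])
      loglik <- c(loglik, ll)
      if (verbose) message(sprintf("iter %d subset %d loglik %.6g", it, ss_i, ll))
    }
  }
  attr(x_img, "loglik") <- loglik
  x_img
}

# linear indices of the bins of a subset across all planes
slice_bins <- function(bins, nb, np) {
  as.vector(outer(bins + 1L, (0:(np - 1L)) * nb, `+`))
}
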