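unit_components <- function(g, ...) {
  mi <- petquant:::michelogram_map(g)
  norm_components(rep(1, g$n_radial_bins),
                  matrix(1, g$n_radial_bins, g$crystals_per_block + g$gaps_per_block),
                  matrix(1, g$n_crystal_positions, g$n_rings),
                  axial_factors_span1 = rep(1, mi$n_planes), geom = g, ...)
}

test_that("span-1 axial decoding follows the N * eps * P1/PS rule", {
  g <- toy_geom(n_rings = 8L, max_ring_diff = 7L)
  map <- span_group_map(g, 11L)
  mi <- petquant:::michelogram_map(g)
  nb <- g$n_radial_bins * g$n_angles

  # uniform counts: P1 = PS / N for all group members -> eps1 == epsS
  p1 <- new_sinogram(g, 1L, array(2, c(g$n_radial_bins, g$n_angles, mi$n_planes)))
  pS <- reduce_span(p1, g, 11L)
  epsS <- seq(0.5, 1.5, length.out = map$n_planes_out)
  eps1 <- decode_span1_axial(epsS, p1, pS, g, span = 11L)
  expect_equal(eps1, epsS[map$group_of_plane1 + 1L], tolerance = 1e-12)

  # direct arithmetic: a 5-plane group with counts (10,10,10,10,60), epsS = 2
  gid <- which(map$group_size == 5L)[2]
  members <- which(map$group_of_plane1 + 1L == gid)
  expect_length(members, 5L)
  v <- array(0, c(g$n_radial_bins, g$n_angles, mi$n_planes))
  v[, , ] <- 1  # keep all planes nonzero
  counts <- c(10, 10, 10, 10, 60)
  for (i in seq_along(members)) v[, , members[i]] <- counts[i] / nb
  p1b <- new_sinogram(g, 1L, v)
  pSb <- reduce_span(p1b, g, 11L)
  epsSb <- rep(1, map$n_planes_out); epsSb[gid] <- 2
  eps1b <- decode_span1_axial(epsSb, p1b, pSb, g, span = 11L)
  expect_equal(eps1b[members], c(1, 1, 1, 1, 6), tolerance = 1e-12)

  # scale invariance: doubling both span-1 and span-S counts leaves eps1 fixed
  p1c <- new_sinogram(g, 1L, unclass(p1b) * 2)
  eps1c <- decode_span1_axial(epsSb, p1c, reduce_span(p1c, g, 11L), g, span = 11L)
  expect_equal(eps1c, eps1b, tolerance = 1e-12)

  # zero-count plane is reported by plane id
  v0 <- unclass(p1b); v0[, , 3] <- 0
  expect_error(decode_span1_axial(epsSb, new_sinogram(g, 1L, v0),
                                  pSb, g, span = 11L), "zero-count span-1 plane")

  # regrouping consistency: sum over a group of P1/eps1 recovers PS/epsS
  w <- plane_totals(p1b) / eps1b
  regrouped <- rowsum(w, map$group_of_plane1)[, 1]
  expect_equal(as.numeric(regrouped), plane_totals(pSb) / epsSb, tolerance = 1e-9)
})

test_that("dead-time factor has the right closed forms and monotonicity", {
  expect_equal(deadtime_factor(0, 1e-6, 1e-6), 1)
  expect_equal(deadtime_factor(1e5, 0, 1e-6), 1.1, tolerance = 1e-12)
  expect_equal(deadtime_factor(1e5, 1e-6, 0), exp(0.1), tolerance = 1e-12)
  n <- seq(0, 1e6, length.out = 50)
  f <- deadtime_factor(n, 2e-7, 5e-7)
  expect_true(all(diff(f) > 0))
  expect_error(deadtime_factor(-1, 0, 0), ">= 0")
})

test_that("norm sinogram assembly is multiplicative with the right fans", {
  g <- toy_geom(n_rings = 4L, n_blocks_tx = 4L, crystals_per_block = 4L,
                gaps_per_block = 1L, n_radial_bins = 12L, max_ring_diff = 3L)
  comp <- unit_components(g)
  nf <- build_norm_sinogram(comp, NULL, NULL, g)
  bm <- build_sino_bin_map(g)
  # unit components: 1 on active bins, 0 on bins touching the dead positions
  act <- array(rep(bm$active, dim(nf)[3]), dim(nf))
  expect_true(all(nf[act] == 1))
  expect_true(all(nf[!act] == 0))

  # doubling one crystal's efficiency doubles exactly its fan of bins
  comp2 <- comp
  k_tx <- which(bm$live)[3] - 1L; k_ring <- 1L
  comp2$crystal_efficiencies[k_tx + 1L, k_ring + 1L] <- 2
  nf2 <- build_norm_sinogram(comp2, NULL, NULL, g)
  mi <- petquant:::michelogram_map(g)
  ratio <- unclass(nf2) / unclass(nf)
  ratio[unclass(nf) == 0] <- 1
  # fan enumeration oracle: bins whose pair contains (k_tx, k_ring)
  expected <- array(1, dim(nf))
  for (p in seq_len(mi$n_planes)) {
    hit <- (bm$k1 == k_tx & mi$r0[p] == k_ring) |
           (bm$k2 == k_tx & mi$r1[p] == k_ring)
    expected[, , p][hit & bm$active] <- 2
  }
  expect_equal(as.vector(ratio), as.vector(expected), tolerance = 1e-12)

  # missing component errors by name
  comp3 <- comp; comp3$axial_factors_span1 <- NULL
  expect_error(build_norm_sinogram(comp3, NULL, NULL, g), "axial_factors_span1")

  # frame-averaged dead time: constant singles over split frames match
  nbk <- petquant:::n_buckets(g)
  compd <- unit_components(g, deadtime_tau_p = rep(1e-6, nbk),
                           deadtime_tau_n = rep(1e-6, nbk))
  bs <- matrix(5e4, nrow = 10, ncol = nbk)
  a <- build_norm_sinogram(compd, bs, c(0, 10), g)
  b1 <- build_norm_sinogram(compd, bs, c(0, 5), g)
  b2 <- build_norm_sinogram(compd, bs, c(5, 10), g)
  expect_equal(as.vector(unclass(a)), as.vector(unclass(b1)), tolerance = 1e-12)
  expect_equal(as.vector(unclass(b1)), as.vector(unclass(b2)), tolerance = 1e-12)
  expect_true(all(a[act] > 1))  # dead time inflates factors
})

test_that("scatter axial factors reproduce an SSR-consistent profile", {
  g <- toy_geom(n_rings = 6L, max_ring_diff = 5L)
  mi <- petquant:::michelogram_map(g)
  set.seed(11)
  v <- array(rexp(g$n_radial_bins * g$n_angles * mi$n_planes) + 0.5,
             c(g$n_radial_bins, g$n_angles, mi$n_planes))
  s1 <- new_sinogram(g, 1L, v)
  ssr <- reduce_span(s1, g, "ssr")
  f <- scatter_axial_factors(ssr, s1, g)
  expect_true(all(is.finite(f) & f > 0))
  # applying the factors makes per-plane totals an equal share of SSR totals
  map <- span_group_map(g, "ssr")
  corrected <- plane_totals(s1) * f
  pred <- plane_totals(ssr)[map$group_of_plane1 + 1L] /
    map$group_size[map$group_of_plane1 + 1L]
  expect_lt(sqrt(mean((corrected / pred - 1)^2)), 1e-12)

  # data already axially uniform per the SSR prediction -> all factors 1
  u <- array(1, dim(v))
  for (p in seq_len(mi$n_planes))
    u[, , p] <- 1 / map$group_size[map$group_of_plane1[p] + 1L]
  su <- new_sinogram(g, 1L, u)
  fu <- scatter_axial_factors(reduce_span(su, g, "ssr"), su, g)
  expect_equal(fu, rep(1, mi$n_planes), tolerance = 1e-12)

  # halved counts on one plane double its factor
  vh <- v; vh[, , 4] <- v[, , 4] / 2
  sh <- new_sinogram(g, 1L, vh)
  fh <- scatter_axial_factors(ssr, sh, g)  # SSR prediction from original
  expect_equal(fh[4] / f[4], 2, tolerance = 1e-12)
})

test_that("norm container round-trips through JSON", {
  g <- tiny_geom()
  comp <- synthetic_norm_components(g, seed = 5, tau_p = 1e-7, tau_n = 2e-7)
  path <- file.path(tempdir(), "norm.json")
  write_norm(comp, path, g)
  comp2 <- read_norm(path, g)
  expect_equal(comp$crystal_efficiencies, comp2$crystal_efficiencies, tolerance = 1e-14)
  expect_equal(comp$geometric, comp2$geometric, tolerance = 1e-14)
  expect_equal(comp$deadtime_tau_n, comp2$deadtime_tau_n)
  expect_error(read_norm(path, toy_geom()), "hash mismatch")
})
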