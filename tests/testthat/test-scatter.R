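test_that("Klein-Nishina closed forms, monotonicity and energy bookkeeping", {
  re2 <- (2.8179403e-13)^2
  fwd <- kn_differential(1)           # theta = 0
  expect_equal(fwd$dsdo, re2, tolerance = 1e-12)
  expect_equal(fwd$energy_ratio, 1)
  bwd <- kn_differential(-1)          # theta = pi
  expect_equal(bwd$dsdo, (10 / 54) * re2, tolerance = 1e-12)
  expect_equal(bwd$energy_ratio, 1 / 3)
  # at 511 keV the differential cross-section falls steeply from forward
  # scatter, reaches a shallow minimum near ~115 degrees and rises slightly
  # towards backscatter
  th <- seq(0, pi, length.out = 400)
  ds <- kn_differential(cos(th))$dsdo
  expect_true(all(diff(ds[th <= 2.0][-1]) < 0))
  expect_lt(ds[400], ds[1] / 5)            # backscatter well below forward
  # energy bookkeeping: P * (1 + alpha (1 - cos theta)) == 1
  er <- kn_differential(cos(th))$energy_ratio
  expect_equal(er * (1 + (1 - cos(th))), rep(1, 400), tolerance = 1e-12)
  expect_error(kn_differential(1.2), "cos_theta")
})

test_that("block-mean downsampling preserves means/totals and crops centred", {
  img <- new_image(array(stats::runif(20 * 18 * 9), c(20, 18, 9)), c(2, 2, 2))
  expect_identical(downsample_image(img, 1L), img)
  u <- new_image(array(3, c(8, 8, 8)), 2)
  expect_true(all(downsample_image(u, 2L)$values == 3))
  d <- downsample_image(img, 2L, preserve = "sum")
  expect_equal(dim(d$values), c(10L, 9L, 4L))
  # total preserved over the cropped region (z loses one slab of 1 voxel)
  expect_equal(sum(d$values), sum(img$values[, , 1:8]), tolerance = 1e-12)
  expect_equal(d$voxel_size, c(4, 4, 4))
  expect_error(downsample_image(u, 9L), "factor larger")
  # the published example sizes: 127 -> 63 axial, 344 -> 172 transaxial
  expect_equal(dim(downsample_image(new_image(array(0, c(344, 344, 127)), 2), 2L)$values),
               c(172L, 172L, 63L))
})

test_that("VSM equals the LUT-free brute-force evaluation of the scatter equations", {
  g <- build_geometry(list(n_rings = 3, ring_pitch = 4, ring_diameter = 120,
                           n_blocks_tx = 5, crystals_per_block = 4,
                           gaps_per_block = 0, n_radial_bins = 12,
                           max_ring_diff = 2, span = 1))
  em <- new_image(array(0, c(7, 7, 5)), c(8, 8, 2))
  em$values[4, 4, 3] <- 5; em$values[3, 5, 2] <- 2
  mu <- new_image(array(0, c(7, 7, 5)), c(8, 8, 2))
  mu$values[4, 4, 3] <- 0.096; mu$values[5, 3, 3] <- 0.08; mu$values[3, 4, 2] <- 0.05
  cfg <- scatter_config(emission_downsample = 1, mumap_downsample = 1,
                        axial_sampling = 1, tx_sampling = 1,
                        emission_threshold = 0, patch_threshold = 0.02,
                        node_angle_stride = 1, node_radial_stride = 1)
  lut <- build_scatter_lut(em, mu, g, cfg)
  vs <- vsm_single_scatter(em, mu, lut, g, cfg)
  expect_true(all(vs >= 0 & vs <= 1))
  oracle <- oracle_vsm(em, mu, g, cfg$patch_threshold)
  expect_gt(sum(oracle), 0)
  expect_lt(max(abs(unclass(vs) - oracle)) / max(oracle), 1e-8)

  # linearity in emission; mu = 0 kills the scatter entirely
  em2 <- em; em2$values <- em2$values * 2
  vs2 <- vsm_single_scatter(em2, mu, build_scatter_lut(em2, mu, g, cfg), g, cfg)
  expect_equal(unclass(vs2), 2 * unclass(vs), tolerance = 1e-12)
  mu0 <- mu; mu0$values[] <- 0
  expect_warning(
    vs0 <- vsm_single_scatter(em, mu0, build_scatter_lut(em, mu0, g, cfg), g, cfg),
    NA)
  expect_equal(sum(vs0), 0)
})

test_that("scatter interpolation is exact at nodes and accurate on smooth shapes", {
  g <- toy_geom(n_rings = 8L, n_blocks_tx = 8L, crystals_per_block = 4L,
                n_radial_bins = 29L, max_ring_diff = 7L)
  rings <- c(0L, 3L, 5L, 7L)
  rn <- unique(c(seq(0L, 28L, by = 7L), 28L))
  an <- unique(c(seq(0L, 15L, by = 3L), 15L))
  # smooth separable test function over (radial, angle, r0, r1)
  fsep <- function(r, a, r0, r1)
    (1.2 + sin(pi * r / 28)) * (1.1 + 0.3 * cos(2 * pi * a / 16)) *
    (1 + 0.1 * (r0 / 7)) * (1 + 0.2 * (r1 / 7)^2)
  vals <- array(0, c(length(rn), length(an), length(rings), length(rings)))
  for (i in seq_along(rings)) for (j in seq_along(rings))
    vals[, , i, j] <- outer(rn, an, fsep, r0 = rings[i], r1 = rings[j])
  nodes <- structure(list(values = vals, radial_nodes = rn, angle_nodes = an,
                          rings = rings, geom_hash = petquant:::geometry_hash(g)),
                     class = "scatter_nodes")
  full <- interpolate_scatter(nodes, g)
  expect_true(all(full >= 0))
  mi <- petquant:::michelogram_map(g)
  # exact at nodes
  for (i in seq_along(rings)) for (j in seq_along(rings)) {
    p <- mi$plane_of[rings[i] + 1L, rings[j] + 1L]
    if (is.na(p)) next
    expect_equal(full[rn + 1L, an + 1L, p + 1L], vals[, , i, j], tolerance = 1e-9)
  }
  # accurate between nodes for the smooth separable shape
  truth <- array(0, dim(full))
  for (p in seq_len(mi$n_planes))
    truth[, , p] <- outer(0:28, 0:15, fsep, r0 = mi$r0[p], r1 = mi$r1[p])
  rel <- abs(full - truth) / truth
  expect_lt(max(rel), 0.02)
  # constant nodes give a constant sinogram
  nodes$values[] <- 4
  fc <- interpolate_scatter(nodes, g)
  expect_equal(range(unclass(fc)), c(4, 4), tolerance = 1e-10)
  # too-sparse sampling is rejected
  nodes2 <- nodes; nodes2$radial_nodes <- c(0L, 28L)
  nodes2$values <- nodes$values[c(1, 5), , , , drop = FALSE]
  expect_error(interpolate_scatter(nodes2, g), "sparse")
})

test_that("WLS scaling recovers exact and Poisson factors and flags degeneracy", {
  g <- tiny_geom()
  ph <- make_phantom(g, "uniform_cylinder", diameter_mm = 90, activity = 1,
                     dims = c(14L, 14L, 7L), voxel_size = c(8, 8, 4))
  lut <- build_transaxial_lut(g, ph$emission)
  af <- attenuation_factors(ph$mumap, lut, g)
  scfg <- scatter_config(emission_downsample = 1, mumap_downsample = 1,
                         axial_sampling = 1, tx_sampling = 1,
                         emission_threshold = 0.05,
                         node_angle_stride = 1, node_radial_stride = 1)
  shape <- estimate_scatter(ph$emission, ph$mumap, g, scfg, scale = FALSE)
  tr <- unclass(forward_project(ph$emission, lut, g)) * unclass(af)
  rnd <- new_sinogram(g, 1L, array(0.5, dim(tr)))
  pr <- new_sinogram(g, 1L, unclass(rnd) + 3 * unclass(shape))
  sc <- scale_scatter(shape, pr, rnd, af, NULL, g)
  k <- attr(sc, "k")
  expect_lt(max(abs(k[!is.na(k)] - 3)), 1e-9)

  # Poisson recovery of k = 1.7 at ~1e6 counts
  set.seed(9)
  sshape <- unclass(shape) / sum(shape) * 3e5
  lam <- tr * (7e5 / sum(tr)) + 1.7 * sshape + 0.2
  prom <- new_sinogram(g, 1L, array(stats::rpois(length(lam), lam), dim(lam)))
  rnds <- new_sinogram(g, 1L, array(0.2, dim(lam)))
  sc2 <- scale_scatter(new_sinogram(g, 1L, sshape), prom, rnds, af, NULL, g)
  khat <- mean(attr(sc2, "k"), na.rm = TRUE)
  expect_lt(abs(khat - 1.7), 0.1)

  # zero scatter on the mask is flagged
  expect_error(scale_scatter(new_sinogram(g, 1L, array(0, dim(tr))), pr, rnd,
                             af, NULL, g), "identically zero")
  # impossible mask threshold is flagged
  expect_error(scale_scatter(shape, pr, rnd, af, NULL, g, af_threshold = 2),
               "empty scaling mask")
})

test_that("sampled-then-interpolated scatter approximates the full evaluation", {
  g <- toy_geom(n_rings = 8L, n_blocks_tx = 8L, crystals_per_block = 4L,
                n_radial_bins = 29L, max_ring_diff = 7L)
  ph <- make_phantom(g, "uniform_cylinder", diameter_mm = 110, activity = 1,
                     dims = c(15L, 15L, 15L), voxel_size = c(10, 10, 2))
  full_cfg <- scatter_config(emission_downsample = 1, mumap_downsample = 1,
                             axial_sampling = 1, tx_sampling = 1,
                             emission_threshold = 0.05,
                             node_angle_stride = 1, node_radial_stride = 1)
  smp_cfg <- scatter_config(emission_downsample = 1, mumap_downsample = 1,
                            axial_sampling = 2, tx_sampling = 2,
                            emission_threshold = 0.05,
                            node_angle_stride = 2, node_radial_stride = 3)
  full <- estimate_scatter(ph$emission, ph$mumap, g, full_cfg, scale = FALSE)
  appr <- estimate_scatter(ph$emission, ph$mumap, g, smp_cfg, scale = FALSE)
  # the scaling step consumes SSR-aggregated shapes: those must agree closely
  pt <- function(s) apply(unclass(s), 3, sum)
  expect_gt(cor(pt(reduce_span(full, g, "ssr")), pt(reduce_span(appr, g, "ssr"))),
            0.999)
  # radial profile and total preserved within the interpolation error budget
  expect_gt(cor(apply(unclass(full), 1, sum), apply(unclass(appr), 1, sum)), 0.99)
  expect_lt(abs(sum(appr) / sum(full) - 1), 0.15)
})
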