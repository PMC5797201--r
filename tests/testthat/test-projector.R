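make_grid <- function(dims = c(16L, 16L, 15L), vox = c(6, 6, 2), fill = 0) {
  new_image(array(fill, dims), vox)
}

test_that("transaxial LUT conserves chord lengths against the analytic circle", {
  g <- toy_geom()
  img <- make_grid(fill = 1)
  lut <- build_transaxial_lut(g, img)
  xy <- petquant:::crystal_xy(g)
  bm <- lut$binmap
  # analytic chord of each 2-D ray through the square image support
  corner <- lut$corner
  hi <- corner[1:2] + lut$dims[1:2] * img$voxel_size[1:2]
  nb <- length(bm$k1)
  sum2d <- vapply(seq_len(nb), function(b) {
    i0 <- lut$ptr[b] + 1L; i1 <- lut$ptr[b + 1L]
    if (i1 < i0) return(0)
    sum(lut$tout[i0:i1] - lut$tin[i0:i1]) * lut$d2[b]
  }, 1)
  # box-clipped analytic chord
  chord <- vapply(seq_len(nb), function(b) {
    p1 <- xy[bm$k1[b] + 1L, ]; p2 <- xy[bm$k2[b] + 1L, ]
    d <- p2 - p1; t0 <- 0; t1 <- 1
    for (a in 1:2) {
      if (abs(d[a]) < 1e-12) { if (p1[a] < corner[a] || p1[a] > hi[a]) return(0) }
      else {
        ta <- (corner[a] - p1[a]) / d[a]; tb <- (hi[a] - p1[a]) / d[a]
        t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
      }
    }
    max(t1 - t0, 0) * sqrt(sum(d^2))
  }, 1)
  expect_lt(max(abs(sum2d - chord)), 1e-9)
})

test_that("axis-aligned and diagonal rays give textbook Siddon lengths", {
  # one-block toy with crystals aligned so a ray runs along the y axis
  g <- toy_geom(n_rings = 2L, n_blocks_tx = 4L, crystals_per_block = 4L,
                n_radial_bins = 12L, max_ring_diff = 1L)
  img <- new_image(array(1, c(5L, 5L, 3L)), c(4, 4, 4))
  lut <- build_transaxial_lut(g, img)
  bm <- lut$binmap
  xy <- petquant:::crystal_xy(g)
  for (b in seq_along(bm$k1)) {
    i0 <- lut$ptr[b] + 1L; i1 <- lut$ptr[b + 1L]
    if (i1 < i0) next
    p1 <- xy[bm$k1[b] + 1L, ]; p2 <- xy[bm$k2[b] + 1L, ]
    if (abs(p1[1] - p2[1]) < 1e-9) {
      # vertical ray: every crossed voxel contributes exactly the voxel height
      lens <- (lut$tout[i0:i1] - lut$tin[i0:i1]) * lut$d2[b]
      expect_equal(lens, rep(4, length(lens)), tolerance = 1e-12)
    }
  }
  # 45-degree segment through one square voxel: length s * sqrt(2)
  one <- new_image(array(1, c(1L, 1L, 1L)), c(4, 4, 4))
  li <- petquant:::cpp_line_integrals(matrix(c(-4, -4, 0), 1),
                                      matrix(c(4, 4, 0), 1),
                                      as.numeric(one$values), dim(one$values),
                                      one$voxel_size, petquant:::grid_corner(one))
  expect_equal(li, 4 * sqrt(2), tolerance = 1e-12)
})

test_that("forward projection matches the brute-force 3-D Siddon oracle", {
  g <- tiny_geom()
  set.seed(4)
  img <- new_image(array(runif(10 * 10 * 7), c(10, 10, 7)), c(8, 8, 4))
  lut <- build_transaxial_lut(g, img)
  q <- forward_project(img, lut, g)
  mi <- petquant:::michelogram_map(g)
  nb <- g$n_radial_bins * g$n_angles
  set.seed(5)
  picks <- cbind(sample(0:(nb - 1L), 60, replace = TRUE),
                 sample(0:(mi$n_planes - 1L), 60, replace = TRUE))
  for (i in seq_len(nrow(picks))) {
    expected <- oracle_forward_bin(img, g, picks[i, 1], picks[i, 2])
    got <- q[picks[i, 1] %% g$n_radial_bins + 1L,
             picks[i, 1] %/% g$n_radial_bins + 1L, picks[i, 2] + 1L]
    expect_equal(got, expected, tolerance = 1e-7)
  }
  # zero image projects to zero
  expect_equal(sum(forward_project(make_grid(c(10L, 10L, 7L), c(8, 8, 4)),
                                   build_transaxial_lut(g, make_grid(c(10L, 10L, 7L), c(8, 8, 4))),
                                   g)), 0)
})

test_that("back projection is the exact adjoint and subsets decompose", {
  g <- toy_geom()
  set.seed(7)
  img <- new_image(array(runif(16 * 16 * 15), c(16, 16, 15)), c(6, 6, 2))
  lut <- build_transaxial_lut(g, img)
  np <- count_sinograms(g, 1L)
  y <- new_sinogram(g, 1L, array(runif(20 * 14 * np), c(20, 14, np)))
  Ax <- forward_project(img, lut, g)
  Aty <- back_project(y, lut, g)
  lhs <- sum(unclass(Ax) * unclass(y))
  rhs <- sum(img$values * Aty$values)
  expect_lt(abs(lhs - rhs) / lhs, 1e-10)
  # double counting identity: sum(At 1) == sum(A 1)
  ones_s <- new_sinogram(g, 1L, array(1, dim(y)))
  ones_i <- new_image(array(1, dim(img$values)), img$voxel_size)
  expect_equal(sum(back_project(ones_s, lut, g)$values),
               sum(forward_project(ones_i, lut, g)), tolerance = 1e-10)
  # unit sinogram on one bin backprojects that ray's lengths
  one <- new_sinogram(g, 1L, array(0, dim(y)))
  one[11, 3, 5] <- 1
  bp <- back_project(new_sinogram(g, 1L, unclass(one)), lut, g)
  expect_equal(sum(bp$values), oracle_forward_bin(img_unit <- ones_i, g,
                                                  (3 - 1) * 20 + (11 - 1), 5 - 1),
               tolerance = 1e-9)
  # subset decomposition is exact
  ss <- partition_subsets(g, 7L)
  parts <- lapply(ss, function(s) forward_project(img, lut, g, subset = s))
  expect_equal(unclass(Reduce(`+`, parts)), unclass(Ax), tolerance = 0)
})

test_that("attenuation factors follow the closed form and monotonicity", {
  g <- toy_geom()
  ph <- make_phantom(g, "uniform_cylinder", diameter_mm = 80, activity = 1,
                     mu_water = 0.1, dims = c(32L, 32L, 15L), voxel_size = c(3, 3, 2))
  lut <- build_transaxial_lut(g, ph$mumap)
  af <- attenuation_factors(ph$mumap, lut, g)
  expect_true(all(af > 0 & af <= 1))
  # central direct-plane bin: exp(-mu * diameter) = exp(-0.8)
  mi <- petquant:::michelogram_map(g)
  p0 <- mi$plane_of[5, 5] + 1L
  centre <- af[g$n_radial_bins %/% 2 + 1L, 1, p0]
  expect_equal(centre, exp(-0.8), tolerance = 0.01)
  # mu = 0 gives factors 1; scaling mu up is monotone
  zero <- ph$mumap; zero$values[] <- 0
  expect_true(all(attenuation_factors(zero, lut, g) == 1))
  mu2 <- ph$mumap; mu2$values <- mu2$values * 2
  expect_true(all(attenuation_factors(mu2, lut, g) <= af + 1e-15))
  expect_error(attenuation_factors(new_image(array(-1, c(32, 32, 15)), c(3, 3, 2)),
                                   lut, g), "negative")
})
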