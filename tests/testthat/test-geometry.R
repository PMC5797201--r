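test_that("preset and toy geometry combinatorics are consistent", {
  g <- build_geometry("mmr")
  expect_equal(g$n_crystal_positions, 504L)
  expect_equal(g$n_angles, 252L)
  expect_equal(g$buckets_axial * g$buckets_tx, 224L)
  expect_equal(count_sinograms(g, 1L), 4084L)
  expect_equal(count_sinograms(g, 11L), 837L)
  expect_equal(count_sinograms(g, "ssr"), 127L)

  toy <- toy_geom(n_rings = 8L, n_blocks_tx = 4L, crystals_per_block = 4L,
                  n_radial_bins = 12L)
  expect_equal(toy$n_angles, 8L)
  expect_equal(count_sinograms(toy, 1L), 64L)  # 8^2 ring pairs, full ring diff

  gr <- build_geometry("mmr-reduced:16")
  expect_equal(gr$n_rings, 16L)
  expect_equal(gr$max_ring_diff, 15L)

  expect_error(build_geometry(list(n_rings = 4, ring_pitch = 4, ring_diameter = 100,
                                   n_blocks_tx = 3, crystals_per_block = 3,
                                   gaps_per_block = 0, n_radial_bins = 6,
                                   max_ring_diff = 3)),
               "even")
  expect_error(count_sinograms(build_geometry("mmr"), 4L), "odd")
  expect_error(build_geometry(list(n_rings = 4, ring_pitch = 4, ring_diameter = 100,
                                   n_blocks_tx = 4, crystals_per_block = 4,
                                   gaps_per_block = 0, n_radial_bins = 6,
                                   max_ring_diff = 5)),
               "max_ring_diff")
})

test_that("segment tables sum to plane counts and follow the span rule", {
  g <- build_geometry("mmr")
  st1 <- segment_table(g, 1L)
  expect_equal(nrow(st1), 121L)
  expect_equal(sum(st1$n_planes), 4084L)
  expect_equal(sum(st1$n_planes[1:3]), 190L)       # 64 + 2 x 63
  expect_equal(st1$segment[1:5], c(0L, 1L, -1L, 2L, -2L))

  st11 <- segment_table(g, 11L)
  expect_equal(nrow(st11), 11L)
  expect_equal(sum(st11$n_planes), 837L)
  expect_equal(st11$d_min[st11$segment == 1L], 6L)
  expect_equal(st11$d_max[st11$segment == 5L], 60L)

  # conservation for several spans and geometries
  for (g2 in list(g, toy_geom(), tiny_geom())) {
    for (sp in list(1L, 3L, 5L)) {
      expect_equal(sum(segment_table(g2, sp)$n_planes), count_sinograms(g2, sp))
    }
  }
})

test_that("span grouping covers every span-1 plane once, sizes alternate 5/6", {
  g <- build_geometry("mmr")
  map <- span_group_map(g, 11L)
  expect_equal(length(map$group_of_plane1), 4084L)
  expect_equal(sum(map$group_size), 4084L)
  expect_equal(map$n_planes_out, 837L)
  # interior of segment 0 alternates groups of 5 and 6 span-1 planes
  interior <- map$group_size[6:122]
  expect_setequal(unique(interior), c(5L, 6L))
  expect_true(all(abs(diff(interior)) == 1L))
  # ssr grouping
  ms <- span_group_map(g, "ssr")
  expect_equal(ms$n_planes_out, 127L)
  expect_equal(sum(ms$group_size), 4084L)
})

test_that("ssr_plane follows the sum rule and validates input", {
  g <- build_geometry("mmr")
  expect_equal(ssr_plane(g, 0L, 0L), 0L)
  expect_equal(ssr_plane(g, 63L, 63L), 126L)
  expect_equal(ssr_plane(g, 10L, 12L), 22L)
  expect_error(ssr_plane(g, 0L, 64L), "out of range")
  expect_error(ssr_plane(g, 0L, 63L), "ring difference")
})

test_that("sinogram bin map is a bijection and reproduces brute-force counts", {
  # brute force: enumerate all live pairs, map each to a bin; every bin must
  # come from exactly one pair and the active count must match
  for (gp in c(0L, 1L)) {
    g <- toy_geom(n_rings = 2L, n_blocks_tx = 4L, crystals_per_block = 4L,
                  gaps_per_block = gp, n_radial_bins = 12L, max_ring_diff = 1L)
    bm <- build_sino_bin_map(g)
    N <- g$n_crystal_positions
    seen <- integer(g$n_radial_bins * g$n_angles)
    for (a in 0:(N - 2L)) for (b in (a + 1L):(N - 1L)) {
      bin <- bm$pair2bin[a + 1L, b + 1L]
      if (!is.na(bin)) {
        seen[bin + 1L] <- seen[bin + 1L] + 1L
        # round trip: the stored pair of that bin is {a, b}
        expect_equal(sort(c(bm$k1[bin + 1L], bm$k2[bin + 1L])), c(a, b))
      }
    }
    expect_true(all(seen == 1L))  # every in-FOV bin has exactly one pair
    live <- bm$live
    brute_active <- sum(live[bm$k1 + 1L] & live[bm$k2 + 1L])
    expect_equal(bm$n_active, brute_active)
    if (gp == 0L) expect_equal(bm$n_active, length(bm$k1))  # no gaps: all active
  }
})

test_that("mMR active transaxial bin count matches the published grid size", {
  bm <- build_sino_bin_map(build_geometry("mmr"))
  expect_equal(bm$n_active, 68516L)
})

test_that("michelogram plane ordering is segment-major and bijective", {
  g <- toy_geom()
  mi <- petquant:::michelogram_map(g)
  expect_equal(mi$n_planes, count_sinograms(g, 1L))
  # every allowed ring pair appears exactly once
  expect_equal(sort(unique(as.vector(mi$plane_of))), 0:(mi$n_planes - 1L))
  expect_equal(mi$segment[1:(g$n_rings)], rep(0L, g$n_rings))
  # within a segment ordered by r0 + r1
  for (s in unique(mi$segment)) {
    z <- (mi$r0 + mi$r1)[mi$segment == s]
    expect_true(!is.unsorted(z))
  }
})
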