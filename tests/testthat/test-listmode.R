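sim_small <- function(geom, seed = 42L, duration = 10, rf = 0.2) {
  ph <- make_phantom(geom, "uniform_cylinder", diameter_mm = 80, activity = 0.02,
                     dims = c(12L, 12L, 2L * geom$n_rings - 1L),
                     voxel_size = c(9, 9, geom$ring_pitch / 2))
  lm <- simulate_listmode(ph$emission, ph$mumap, NULL,
                          sim_config(duration_s = duration, randoms_fraction = rf,
                                     seed = seed), geom)
  list(lm = lm, ph = ph)
}

test_that("list-mode container round-trips losslessly and validates", {
  g <- tiny_geom()
  lm <- sim_small(g)$lm
  path <- file.path(tempdir(), "lm.bin")
  write_listmode(lm, path, g)
  lm2 <- read_listmode(path, g)
  expect_identical(lm$events, lm2$events)
  expect_equal(lm$singles, lm2$singles)
  expect_identical(lm$duration_ms, lm2$duration_ms)
  # byte-identical re-write
  path2 <- file.path(tempdir(), "lm2.bin")
  write_listmode(lm2, path2, g)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
  # empty event section is valid
  empty <- new_listmode(list(time_ms = integer(0), txa = integer(0),
                             ringa = integer(0), txb = integer(0),
                             ringb = integer(0), delayed = logical(0)),
                        data.frame(), 1000L, g)
  write_listmode(empty, path, g)
  expect_equal(petquant:::n_events(read_listmode(path, g)), 0L)
  # out-of-range ring is rejected
  expect_error(new_listmode(list(time_ms = 0L, txa = 0L, ringa = g$n_rings,
                                 txb = 1L, ringb = 0L, delayed = FALSE),
                            data.frame(), 1000L, g), "ring index")
  # wrong geometry is rejected on read
  expect_error(read_listmode(path, toy_geom()), "hash mismatch")
})

test_that("histogramming conserves counts and maps hand-computed events", {
  g <- tiny_geom()
  bm <- build_sino_bin_map(g)
  mi <- petquant:::michelogram_map(g)
  # three events with bins computed from the geometry mapping by hand
  pick <- c(5L, 40L, 100L)  # bin ids
  planes <- c(2L, 0L, 9L)
  ev <- list(time_ms = c(10L, 20L, 30L),
             txa = bm$k1[pick + 1L], ringa = mi$r0[planes + 1L],
             txb = bm$k2[pick + 1L], ringb = mi$r1[planes + 1L],
             delayed = rep(FALSE, 3))
  lm <- new_listmode(ev, data.frame(), 1000L, g)
  h <- histogram_listmode(lm, g, span = 1L)[[1]]
  expect_equal(sum(h$prompts), 3)
  nb <- g$n_radial_bins * g$n_angles
  for (i in 1:3) {
    expect_equal(h$prompts[pick[i] %% g$n_radial_bins + 1L,
                           pick[i] %/% g$n_radial_bins + 1L, planes[i] + 1L], 1)
  }
  # all-delayed stream gives an all-zero prompts sinogram
  ev$delayed <- rep(TRUE, 3)
  hd <- histogram_listmode(new_listmode(ev, data.frame(), 1000L, g), g, span = 1L)[[1]]
  expect_equal(sum(hd$prompts), 0)
  expect_equal(sum(hd$delayeds), 3)
})

test_that("histogram conservation and fan-sum identities hold on simulation", {
  g <- tiny_geom()
  lm <- sim_small(g)$lm
  h <- histogram_listmode(lm, g, span = 1L)[[1]]
  expect_equal(sum(h$prompts) + sum(h$delayeds) + h$discarded, petquant:::n_events(lm))
  expect_equal(sum(h$prompts), h$n_prompts - sum(lm$events$delayed == FALSE &
                                                   !petquant:::event_bins(lm, g)$valid))
  # fan sums: each valid delayed event contributes to both crystals
  expect_equal(sum(h$delayed_fansums), 2 * sum(h$delayeds))
  # head curve totals match event counts
  expect_equal(sum(h$head_curve$prompts), h$n_prompts)
  expect_equal(sum(h$head_curve$delayeds), h$n_delayeds)
  # overlapping frames rejected
  expect_error(histogram_listmode(lm, g, frames = list(c(0, 6000), c(5000, 9000))),
               "overlapping")
})

test_that("centre-of-mass trace is flat for a static source and sees a 20 mm step", {
  g <- toy_geom()
  ph <- make_phantom(g, "uniform_cylinder", diameter_mm = 60, activity = 0.01,
                     dims = c(12L, 12L, 15L), voxel_size = c(8, 8, 2))
  # a short axial source at -10 mm for 10 s, then stepped +20 mm for 10 s
  src_a <- ph$emission; src_a$values[] <- 0
  src_a$values[, , 1:5] <- ph$emission$values[, , 1:5]    # z centre -10 mm
  src_b <- ph$emission; src_b$values[] <- 0
  src_b$values[, , 11:15] <- ph$emission$values[, , 11:15]  # z centre +10 mm
  cfg1 <- sim_config(duration_s = 10, seed = 1)
  cfg2 <- sim_config(duration_s = 10, seed = 2)
  lm1 <- simulate_listmode(src_a, ph$mumap, NULL, cfg1, g)
  lm2 <- simulate_listmode(src_b, ph$mumap, NULL, cfg2, g, t_offset_ms = 10000L)
  ev <- Map(c, lm1$events, lm2$events)
  lm <- new_listmode(ev, data.frame(), 20000L, g)
  h <- histogram_listmode(lm, g, span = 1L)[[1]]
  com <- h$com_trace$com_mm
  expect_lt(max(abs(com[1:10] - mean(com[1:10]))), 2)     # static within Poisson noise
  expect_gt(mean(com[11:20]) - mean(com[1:10]), 10)       # 20 mm step detected
})

test_that("bootstrap resampling preserves counts, is seeded, and is unbiased", {
  g <- tiny_geom()
  lm <- sim_small(g, duration = 2)$lm
  r1 <- bootstrap_resample(lm, 7L)
  r2 <- bootstrap_resample(lm, 7L)
  expect_identical(r1$events, r2$events)
  expect_equal(petquant:::n_events(r1), petquant:::n_events(lm))
  expect_false(identical(r1$events, bootstrap_resample(lm, 8L)$events))
  expect_true(!is.unsorted(r1$events$time_ms))
  expect_identical(r1$singles, lm$singles)

  # multinomial expectation: mean replicate bin count ~ original within 3 SE
  h0 <- histogram_listmode(lm, g, span = 1L)[[1]]
  bin <- which(unclass(h0$prompts) > 2)[1]
  n0 <- unclass(h0$prompts)[bin]
  R <- 200
  vals <- vapply(seq_len(R), function(r) {
    hr <- histogram_listmode(bootstrap_resample(lm, 1000L + r), g, span = 1L)[[1]]
    unclass(hr$prompts)[bin]
  }, 1)
  se <- sd(vals) / sqrt(R)
  expect_lt(abs(mean(vals) - n0), 3 * se + 1e-9)
})
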