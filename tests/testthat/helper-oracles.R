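# Independent oracles: a sort-based 3-D grid ray tracer (different algorithm
# from the incremental traversal in the package core), a direct 3-D
# convolution, and a LUT-free evaluation of the single-scatter equations.

# All voxels crossed by the segment p1 -> p2 with parametric [t0, t1]:
# collect every grid-plane crossing, classify interval midpoints.
oracle_ray_cells <- function(p1, p2, dims, vox, corner) {
  d <- p2 - p1
  ts <- c(0, 1)
  for (a in 1:3) if (abs(d[a]) > 1e-12) {
    t <- (corner[a] + (0:dims[a]) * vox[a] - p1[a]) / d[a]
    ts <- c(ts, t[t > 0 & t < 1])
  }
  ts <- sort(unique(ts))
  out <- NULL
  for (i in seq_len(length(ts) - 1)) {
    pos <- p1 + (ts[i] + ts[i + 1]) / 2 * d
    ijk <- floor((pos - corner) / vox)
    if (all(ijk >= 0) && all(ijk < dims))
      out <- rbind(out, c(ijk, ts[i], ts[i + 1]))
  }
  out
}

oracle_line_integral <- function(img, p1, p2) {
  dm <- dim(img$values)
  corner <- img$origin - img$voxel_size / 2
  L <- sqrt(sum((p2 - p1)^2))
  cells <- oracle_ray_cells(p1, p2, dm, img$voxel_size, corner)
  if (is.null(cells)) return(0)
  sum(img$values[cells[, 1:3, drop = FALSE] + 1] * (cells[, 5] - cells[, 4]) * L)
}

# Forward-project one bin/plane by brute force 3-D Siddon.
oracle_forward_bin <- function(img, geom, bin_tx, plane) {
  bm <- build_sino_bin_map(geom)
  mi <- petquant:::michelogram_map(geom)
  xy <- petquant:::crystal_xy(geom)
  zr <- petquant:::ring_z(geom)
  k1 <- bm$k1[bin_tx + 1L]; k2 <- bm$k2[bin_tx + 1L]
  p1 <- c(xy[k1 + 1L, ], zr[mi$r0[plane + 1L] + 1L])
  p2 <- c(xy[k2 + 1L, ], zr[mi$r1[plane + 1L] + 1L])
  oracle_line_integral(img, p1, p2)
}

# Direct (non-separable) 3-D convolution with the outer-product kernel and
# reflective boundary.
oracle_convolve3d <- function(img, psf) {
  kx <- psf$kernels$x; ky <- psf$kernels$y; kz <- psf$kernels$z
  K <- outer(outer(kx, ky), kz)
  hw <- (c(length(kx), length(ky), length(kz)) - 1L) %/% 2L
  dm <- dim(img$values)
  refl <- function(j, n) {
    period <- 2L * n
    j <- ((j - 1L) %% period + period) %% period + 1L
    ifelse(j > n, period - j + 1L, j)
  }
  out <- array(0, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    xi <- refl(i + seq_len(dim(K)[1]) - 1L - hw[1], dm[1])
    yj <- refl(j + seq_len(dim(K)[2]) - 1L - hw[2], dm[2])
    zk <- refl(k + seq_len(dim(K)[3]) - 1L - hw[3], dm[3])
    out[i, j, k] <- sum(K * img$values[xi, yj, zk])
  }
  o <- img; o$values <- out
  o
}

# LUT-free direct evaluation of the three single-scatter equations over all
# detectors of a (tiny) geometry, binned like the package output.
oracle_vsm <- function(emission, mumap, geom, patch_threshold) {
  bm <- build_sino_bin_map(geom)
  mi <- petquant:::michelogram_map(geom)
  xy <- petquant:::crystal_xy(geom)
  zr <- petquant:::ring_z(geom)
  R <- geom$ring_diameter / 2
  area <- (pi * geom$ring_diameter / geom$n_crystal_positions) * geom$ring_pitch
  re2 <- (2.8179403e-13)^2
  kn <- function(ct) { P <- 1 / (2 - ct); 0.5 * re2 * P^2 * (P + 1 / P - (1 - ct^2)) }
  sig <- petquant:::kn_total_sigma(1)
  tab <- petquant:::water_cb_table()
  dm <- dim(mumap$values); vox <- mumap$voxel_size
  corner <- mumap$origin - vox / 2
  dets <- expand.grid(tx = which(bm$live) - 1L, ring = 0:(geom$n_rings - 1L))
  nb <- geom$n_radial_bins * geom$n_angles
  sino <- array(0, c(geom$n_radial_bins, geom$n_angles, mi$n_planes))
  esel <- which(emission$values > 0)
  for (ei in esel) {
    ijk <- arrayInd(ei, dim(emission$values))
    e <- emission$origin + (ijk - 1) * emission$voxel_size
    act <- emission$values[ei]
    for (ai in seq_len(nrow(dets))) {
      A <- c(xy[dets$tx[ai] + 1L, ], zr[dets$ring[ai] + 1L])
      ua <- A - e; rA <- sqrt(sum(ua^2)); ua <- ua / rA
      cosA <- abs(ua[1] * (-A[1] / R) + ua[2] * (-A[2] / R))
      epsA <- area * cosA / (4 * pi * rA^2)
      IA <- oracle_line_integral(mumap, e, A)
      d <- -ua
      cells <- oracle_ray_cells(e, e + d * 1000, dm, vox, corner)
      if (is.null(cells)) next
      cum <- 0
      for (ci in seq_len(nrow(cells))) {
        muv <- mumap$values[cells[ci, 1] + 1, cells[ci, 2] + 1, cells[ci, 3] + 1]
        seg <- (cells[ci, 5] - cells[ci, 4]) * 1000
        if (muv >= patch_threshold) {
          Pi <- epsA * exp(-(IA + cum) / 10)
          Ps <- Pi * (1 - exp(-muv * seg / 10))
          s <- mumap$origin + cells[ci, 1:3] * vox
          for (bi in seq_len(nrow(dets))) {
            if (dets$tx[bi] == dets$tx[ai] && dets$ring[bi] == dets$ring[ai]) next
            B <- c(xy[dets$tx[bi] + 1L, ], zr[dets$ring[bi] + 1L])
            sb <- B - s; rB <- sqrt(sum(sb^2)); sb <- sb / rB
            ct <- sum(d * sb)
            cosB <- abs(sb[1] * (-B[1] / R) + sb[2] * (-B[2] / R))
            omB <- area * cosB / rB^2
            cB <- approx(tab$eratio, tab$cb, 1 / (2 - ct), rule = 2)$y
            sv <- exp(-cB * oracle_line_integral(mumap, s, B) / 10)
            contrib <- act * Ps * (omB / sig) * kn(ct) * sv
            bin <- bm$pair2bin[dets$tx[ai] + 1L, dets$tx[bi] + 1L]
            if (is.na(bin)) next
            al <- bm$aligned[dets$tx[ai] + 1L, dets$tx[bi] + 1L]
            r0 <- if (al) dets$ring[ai] else dets$ring[bi]
            r1 <- if (al) dets$ring[bi] else dets$ring[ai]
            pl <- mi$plane_of[r0 + 1L, r1 + 1L]
            if (is.na(pl)) next
            sino[bin %% geom$n_radial_bins + 1L, bin %/% geom$n_radial_bins + 1L,
                 pl + 1L] <-
              sino[bin %% geom$n_radial_bins + 1L, bin %/% geom$n_radial_bins + 1L,
                   pl + 1L] + contrib
          }
        }
        cum <- cum + muv * seg
      }
    }
  }
  sino
}
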